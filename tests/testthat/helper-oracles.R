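# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths: loops instead of vectorization, their
# own DP instead of the aligner.

randomSeq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# mutate a sequence at a given per-base substitution rate; returns list with
# the mutated string (gapless, same length)
mutateSeq <- function(s, rate = 0.05) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# gapless equal-length pair -> PairwiseAln via the package ingester
gaplessAln <- function(ref, qry, refId = "ref", qryId = "qry") {
  recs <- c(ref, qry)
  names(recs) <- c(refId, qryId)
  ingestAlignedFasta(recs, refId)[[qryId]]
}

# brute-force per-position mismatch recount on a gapless pair
oracleMismatchCounts <- function(ref, qry) {
  rc <- strsplit(ref, "")[[1]]
  qc <- strsplit(qry, "")[[1]]
  counts <- integer(0)
  for (i in seq_along(rc)) {
    r <- rc[i]; q <- qc[i]
    if (r %in% c("A", "C", "G", "T") && q %in% c("A", "C", "G", "T") &&
        r != q) {
      key <- paste0(r, ">", q)
      counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
    }
  }
  counts
}

# brute-force window recount
oracleWindowCounts <- function(positions, len, window, step) {
  starts <- c()
  s <- 1
  while (s + window - 1 <= len) {
    starts <- c(starts, s)
    s <- s + step
  }
  sapply(starts, function(st) {
    n <- 0
    for (p in positions) if (p >= st && p <= st + window - 1) n <- n + 1
    n
  })
}

# independent global affine-gap DP (Gotoh); gap of length L costs
# open + L * ext; returns the optimal score only
oracleAlignScore <- function(a, b, match = 2, mismatch = -3,
                             open = 8, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m) + 1) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# minimal hand-built provirus template for targeted simulator tests
tinyTemplate <- function(seq, ltr5, ltr3) {
  methods::new("ProvirusTemplate",
    seq = seq, ltr5 = as.integer(ltr5), ltr3 = as.integer(ltr3),
    cds = data.frame(), seed = 0L
  )
}

revcompStr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# minus-strand base composition of a plus-strand sequence, as frequencies
minusBackground <- function(seq) {
  ch <- strsplit(revcompStr(seq), "")[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  stats::setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
}

extdata <- function(f) system.file("extdata", f, package = "hypermutR")
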