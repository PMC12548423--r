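# Minus-strand target-site context analysis of G>A sites.
#
# Coordinate convention: for a plus-strand G at reference position i, the
# deaminated C sits on the minus strand opposite i, and its -1 / -2
# minus-strand neighbors are the complements of plus-strand positions i+1 /
# i+2. Contexts are written 5'->3' on the minus strand as (-2, -1, C), i.e.
# the reverse complement of the plus-strand triplet (i, i+1, i+2): minus
# TTC corresponds to plus-strand GAA.

#' Extract minus-strand trinucleotide contexts of G>A sites
#'
#' For each G>A record, the (-2, -1, C) minus-strand 3-mer is read either
#' from the reference (`source = "reference"`, the classical assumption that
#' every edit saw the unmutated template) or with the -1/-2 neighbors taken
#' from the query (`source = "contemporaneous"`, modeling neighbors that had
#' already been edited when this site was deaminated; the third character is
#' still written `C`, the base the site carried before its own edit). Sites
#' within 2 nt of the 3' end of the reference, adjacent to gap columns, or
#' with `N` neighbors are dropped, with the count reported via `message()`.
#'
#' @param records G>A mismatch records (any other class is an error).
#' @param aln the \linkS4class{PairwiseAln} the records were called from.
#' @param source `"reference"` or `"contemporaneous"`.
#' @return data frame with columns `refPos`, `minusContext`, `source`.
#' @export
extractContexts <- function(records, aln,
                            source = c("reference", "contemporaneous")) {
  source <- match.arg(source)
  if (nrow(records) && any(records$klass != "G>A")) {
    stop("extractContexts expects G>A records only")
  }
  rc <- .chars(alignedRef(aln))
  qc <- .chars(alignedQry(aln))
  refLen <- sum(rc != "-")
  colOf <- integer(refLen)
  colOf[cumsum(rc != "-")[rc != "-"]] <- which(rc != "-")

  n <- nrow(records)
  ctx <- character(n)
  keep <- logical(n)
  for (k in seq_len(n)) {
    i <- records$refPos[k]
    if (i + 2L > refLen) next
    c0 <- colOf[i]; c1 <- colOf[i + 1L]; c2 <- colOf[i + 2L]
    # consecutive columns: no insertion (reference-gap) column between
    if (c1 != c0 + 1L || c2 != c0 + 2L) next
    refNb <- rc[c(c1, c2)]
    qryNb <- qc[c(c1, c2)]
    if (!all(refNb %in% DNA_BASES) || !all(qryNb %in% DNA_BASES)) next
    keep[k] <- TRUE
    ctx[k] <- if (source == "reference") {
      paste0(.COMP[[rc[c2]]], .COMP[[rc[c1]]], .COMP[[rc[c0]]])
    } else {
      paste0(.COMP[[qc[c2]]], .COMP[[qc[c1]]], "C")
    }
  }
  dropped <- n - sum(keep)
  if (dropped > 0L) {
    message("extractContexts: dropped ", dropped,
            " site(s) at sequence edges or adjacent to gaps/N")
  }
  data.frame(
    refPos = records$refPos[keep],
    minusContext = ctx[keep],
    source = rep(source, sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' Keep only standalone G>A sites
#'
#' A standalone site has no mutation at its -1 or -2 minus-strand context
#' positions (plus-strand `pos+1`, `pos+2`), so its reference-sequence
#' context equals its edit-time context. By default any mismatch class at a
#' neighbor removes the site; `exclude = "GA"` restricts the exclusion to
#' plus-strand G>A neighbors (minus-strand C>T), the narrower reading.
#'
#' @param sites context sites from [extractContexts()].
#' @param records all mismatch records from the same alignment.
#' @param exclude `"any"` (default) or `"GA"`.
#' @return the subset of `sites` passing the filter (idempotent).
#' @export
standaloneFilter <- function(sites, records, exclude = c("any", "GA")) {
  exclude <- match.arg(exclude)
  mutPos <- if (exclude == "any") {
    records$refPos
  } else {
    records$refPos[records$klass == "G>A"]
  }
  keep <- !((sites$refPos + 1L) %in% mutPos) &
    !((sites$refPos + 2L) %in% mutPos)
  sites[keep, , drop = FALSE]
}

#' Reference positions mutated in multiple queries
#'
#' Target-site specificity makes independent edits recur at the same
#' reference positions; intersecting profiles across proviruses removes weak
#' targets and mutations unrelated to deaminase editing.
#'
#' @param profiles named list of mismatch-record data frames, all on the
#'   same reference coordinates.
#' @param minShare minimum number of queries (>= 2) that must carry a G>A
#'   record at a position.
#' @return sorted integer vector of reference positions; empty when
#'   `minShare` exceeds the number of profiles.
#' @export
sharedSites <- function(profiles, minShare = 2L) {
  if (minShare < 2L) stop("minShare must be >= 2")
  if (minShare > length(profiles)) return(integer(0))
  posPerQry <- lapply(profiles, function(r) {
    unique(r$refPos[r$klass == "G>A"])
  })
  tab <- table(unlist(posPerQry, use.names = FALSE))
  sort(as.integer(names(tab)[tab >= minShare]))
}

#' Build a position frequency logo from context sites
#'
#' Per-position base frequencies over the (-2, -1, C) minus-strand contexts
#' and their information content, `2 - H` bits with Shannon entropy `H` and
#' no small-sample correction (matching default sequence-logo behavior at
#' these site counts).
#'
#' @param sites context sites from [extractContexts()] (>= 1 row).
#' @return a \linkS4class{LogoMatrix}.
#' @export
buildLogo <- function(sites) {
  n <- nrow(sites)
  if (is.null(n) || n < 1L) stop("buildLogo requires at least one site")
  m <- do.call(rbind, strsplit(sites$minusContext, "", fixed = TRUE))
  freqs <- vapply(seq_len(3L), function(j) {
    as.numeric(table(factor(m[, j], levels = DNA_BASES))) / n
  }, numeric(4L))
  dimnames(freqs) <- list(DNA_BASES, c("-2", "-1", "0"))
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  info <- 2 + colSums(plogp)
  info <- pmin(pmax(info, 0), 2)
  methods::new("LogoMatrix", freqs = freqs,
               infoBits = stats::setNames(info, colnames(freqs)),
               nSites = as.integer(n))
}

#' Call the deaminase target-site preference of an edit set
#'
#' Discriminates the two murine deaminase allele signatures: a B6-like
#' preference for T(T/C)C (T enriched at -2) versus a BALB-like preference
#' for XTC (-2 near-uniform, T required at -1). The discriminant score is
#' \deqn{score = \log_2\frac{f(T_{-2})}{b_T} - \log_2 \max_{B \ne T}
#' \frac{f(B_{-2})}{b_B}}
#' computed over sites with T or C at -1 when context sites are supplied
#' (given a bare \linkS4class{LogoMatrix} its -2 column is used as-is).
#' Labels: `B6-like` when score exceeds `scoreThreshold`; else `BALB-like`
#' when the -2 column is near-uniform (`infoBits < uniformInfoMax`) while
#' `f(T at -1) > 0.5`; else `indeterminate`. Fewer than `minSites` sites is
#' always `indeterminate`. The score and thresholds are numeric stand-ins
#' for what is classically a visual logo call, and are validated on
#' synthetic data only.
#'
#' @param x context sites (data frame from [extractContexts()]) or a
#'   \linkS4class{LogoMatrix}.
#' @param background background base frequencies on the minus strand, named
#'   `A,C,G,T` (default uniform); supply the reference minus-strand
#'   composition for composition-corrected scoring.
#' @param minSites minimum number of sites for a call (default 20).
#' @param scoreThreshold log2-odds dead zone for the B6-like call (default
#'   0.5).
#' @param uniformInfoMax information-content ceiling for "near-uniform" -2
#'   (default 0.3 bits).
#' @return a list of class `PreferenceCall`: `label`, `score`, `components`.
#' @export
classifyPreference <- function(x, background = NULL, minSites = 20L,
                               scoreThreshold = 0.5, uniformInfoMax = 0.3) {
  if (is.null(background)) {
    background <- stats::setNames(rep(0.25, 4L), DNA_BASES)
  }
  background <- background[DNA_BASES]
  if (any(is.na(background)) || any(background <= 0)) {
    stop("background must be positive frequencies named A,C,G,T")
  }
  background <- background / sum(background)

  if (is.data.frame(x)) {
    n <- nrow(x)
    full <- if (n >= 1L) buildLogo(x) else NULL
    sub <- x[substr(x$minusContext, 2L, 2L) %in% c("T", "C"), , drop = FALSE]
    scoreLogo <- if (nrow(sub) >= 1L) buildLogo(sub) else full
  } else if (methods::is(x, "LogoMatrix")) {
    n <- nSites(x)
    full <- x
    scoreLogo <- x
  } else {
    stop("x must be a context-site data frame or a LogoMatrix")
  }

  if (is.null(full) || n < minSites) {
    return(structure(
      list(label = "indeterminate", score = NA_real_,
           components = list(nSites = n)),
      class = "PreferenceCall"
    ))
  }

  f2 <- logoFreqs(scoreLogo)[, "-2"]
  fT2 <- f2[["T"]]
  maxOther <- max(f2[c("A", "C", "G")] / background[c("A", "C", "G")])
  score <- log2(fT2 / background[["T"]]) - log2(maxOther)
  fT1 <- logoFreqs(full)[["T", "-1"]]
  info2 <- infoBits(scoreLogo)[["-2"]]

  label <- if (!is.na(score) && score > scoreThreshold) {  # +Inf allowed
    "B6-like"
  } else if (info2 < uniformInfoMax && fT1 > 0.5) {
    "BALB-like"
  } else {
    "indeterminate"
  }
  structure(
    list(
      label = label, score = unname(score),
      components = list(freqsMinus2 = f2, fTminus1 = fT1,
                        infoMinus2 = info2, nSites = n,
                        background = background)
    ),
    class = "PreferenceCall"
  )
}

#' @export
print.PreferenceCall <- function(x, ...) {
  cat("PreferenceCall: ", x$label,
      " (score ", format(round(x$score, 3)),
      ", n = ", x$components$nSites, ")\n", sep = "")
  invisible(x)
}

#' Serialize a logo to JSON
#'
#' @param logo a \linkS4class{LogoMatrix}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLogoJson <- function(logo, path) {
  x <- list(
    positions = colnames(logoFreqs(logo)),
    freqs = apply(logoFreqs(logo), 2L, as.list),
    info_bits = as.list(infoBits(logo)),
    n_sites = nSites(logo)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
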