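# Synthetic provirus generation and minus-strand deamination simulation.
#
# The simulator states the world the analysis modules assume: a provirus
# with two identical LTRs, minus-strand C>U editing (plus-strand G>A) with
# trinucleotide-context-dependent rates, optional cascade target creation
# (fresh C>T edits at -1/-2 turning CCC tracts into preferred TTC/CTC/TCC
# targets), extra editing exposure of the nascent 3' LTR, and background
# neutral substitutions.

#' Editing configuration
#'
#' @param baseRate per-exposed-C deamination probability per pass, in
#'   `[0, 1]`. The default 0.02 with the default weights is a
#'   calibration-free choice that reaches mismatch densities comparable to
#'   heavily edited proviruses; absolute per-pass rates are not constrained
#'   by any observation.
#' @param contextWeights named nonnegative multipliers per minus-strand
#'   3-mer (5'->3', `(-2, -1, C)` form); defaults `TTC = 8, TCC = 4,
#'   CTC = 4`, everything else `defaultWeight`. Effective probabilities are
#'   capped at 1.
#' @param defaultWeight weight for 3-mers absent from `contextWeights`.
#' @param cascade when `TRUE`, context is read from the live edited sequence
#'   (already-edited neighbors create new preferred targets); when `FALSE`,
#'   from the immutable template.
#' @param passes number of sequential whole-genome scans (>= 1).
#' @param ltr3ExtraExposure additional passes applied to the 3' LTR interval
#'   only, modeling the second single-stranded exposure of the nascent 3'
#'   LTR during reverse transcription.
#' @param backgroundSubRate per-base probability of a random non-G>A
#'   substitution applied after editing.
#' @param allowBackgroundGA lift the G>A exclusion for background
#'   substitutions (stress testing only; the exclusion keeps mismatch
#'   classes attributable to their mechanism).
#' @param scanDirection `"minus3to5"` (default: ascending plus-strand
#'   coordinates, the order reverse transcription exposes the template) or
#'   `"minus5to3"`. Direction only matters when `cascade` is on.
#' @param seed integer seed; a single seeded generator drives all draws in
#'   scan order, so truth logs fully determine outputs.
#' @return a list of class `EditConfig`.
#' @export
editConfig <- function(baseRate = 0.02,
                       contextWeights = c(TTC = 8, TCC = 4, CTC = 4),
                       defaultWeight = 1,
                       cascade = FALSE,
                       passes = 1L,
                       ltr3ExtraExposure = 0L,
                       backgroundSubRate = 0,
                       allowBackgroundGA = FALSE,
                       scanDirection = c("minus3to5", "minus5to3"),
                       seed = 1L) {
  scanDirection <- match.arg(scanDirection)
  stopifnot(
    baseRate >= 0, baseRate <= 1,
    all(contextWeights >= 0), defaultWeight >= 0,
    passes >= 1L, ltr3ExtraExposure >= 0L,
    backgroundSubRate >= 0, backgroundSubRate <= 1
  )
  if (length(contextWeights) && is.null(names(contextWeights))) {
    stop("contextWeights must be named by minus-strand 3-mers")
  }
  structure(
    list(baseRate = baseRate, contextWeights = contextWeights,
         defaultWeight = defaultWeight, cascade = isTRUE(cascade),
         passes = as.integer(passes),
         ltr3ExtraExposure = as.integer(ltr3ExtraExposure),
         backgroundSubRate = backgroundSubRate,
         allowBackgroundGA = isTRUE(allowBackgroundGA),
         scanDirection = scanDirection, seed = as.integer(seed)),
    class = "EditConfig"
  )
}

#' Generate a ground-truth provirus template
#'
#' Builds a random provirus of i.i.d. composition whose 3' LTR is an exact
#' copy of its 5' LTR (flanking LTRs are identical when a provirus forms)
#' and seeds one internal CDS with an ATG start and at least `nTggCodons`
#' tryptophan (TGG) codons — the codons uniquely convertible to stops by
#' G>A editing. Defaults state the modeled world: an ~8 kb provirus with two
#' 1.3 kb LTRs (the unusually large LTR class) and the AT-rich composition
#' of the reference provirus family.
#'
#' @param totalLen total provirus length in bases.
#' @param ltrLen LTR length (`2 * ltrLen < totalLen`).
#' @param gcFraction G+C fraction in `(0, 1)`.
#' @param nTggCodons minimum number of TGG codons seeded into the CDS.
#' @param seed integer seed; output is deterministic under it.
#' @return a \linkS4class{ProvirusTemplate}.
#' @export
generateProvirus <- function(totalLen = 8000L, ltrLen = 1300L,
                             gcFraction = 0.42, nTggCodons = 20L,
                             seed = 1L) {
  totalLen <- as.integer(totalLen)
  ltrLen <- as.integer(ltrLen)
  nTggCodons <- as.integer(nTggCodons)
  if (!(2L * ltrLen < totalLen)) stop("require 2 * ltrLen < totalLen")
  if (!(gcFraction > 0 && gcFraction < 1)) stop("gcFraction must be in (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  chars <- sample(DNA_BASES, totalLen, replace = TRUE, prob = p[DNA_BASES])

  # CDS: margin of 100 nt after the 5' LTR and before the 3' LTR
  cdsStart <- ltrLen + 101L
  maxCdsEnd <- totalLen - ltrLen - 100L
  nCod <- min(500L, (maxCdsEnd - cdsStart + 1L) %/% 3L)
  if (nCod < nTggCodons + 2L) {
    stop("infeasible parameters: no room for a CDS with ", nTggCodons,
         " TGG codons")
  }
  nonStop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  codons <- sample(nonStop, nCod, replace = TRUE)
  codons[1L] <- "ATG"
  tggSlots <- sample(2:nCod, nTggCodons)
  codons[tggSlots] <- "TGG"
  cdsSeq <- .chars(paste(codons, collapse = ""))
  cdsEnd <- cdsStart + length(cdsSeq) - 1L
  chars[cdsStart:cdsEnd] <- cdsSeq

  # 3' LTR: exact copy of the 5' LTR (after CDS placement; no overlap)
  ltr5 <- c(1L, ltrLen)
  ltr3 <- c(totalLen - ltrLen + 1L, totalLen)
  chars[ltr3[1]:ltr3[2]] <- chars[ltr5[1]:ltr5[2]]

  methods::new("ProvirusTemplate",
    seq = paste(chars, collapse = ""),
    ltr5 = ltr5, ltr3 = ltr3,
    cds = data.frame(gene = "pol", start = cdsStart, end = cdsEnd,
                     frame = 0L, stringsAsFactors = FALSE),
    seed = as.integer(seed)
  )
}

# minus-strand (-2,-1,C)-form 3-mer seen by the minus-strand C opposite the
# plus-strand position i, read from the character vector `chars`; the third
# character is written "C" (the pre-edit base) regardless of current state
.minusContextAt <- function(chars, i, L) {
  if (i + 2L > L) return(NA_character_)
  paste0(.COMP[[chars[i + 2L]]], .COMP[[chars[i + 1L]]], "C")
}

.weightOf <- function(ctx, config) {
  if (is.na(ctx)) return(config$defaultWeight)
  w <- config$contextWeights[ctx]
  if (is.na(w)) config$defaultWeight else unname(w)
}

#' Simulate minus-strand deamination of a provirus
#'
#' Sequential scans of the minus-strand cytosines (plus-strand Gs). On each
#' pass every still-unedited site is edited with probability
#' `min(1, baseRate * weight(context))`, where the context is the
#' minus-strand 3-mer read from the template (`cascade = FALSE`) or the
#' live edited sequence (`cascade = TRUE`). After the global passes,
#' `ltr3ExtraExposure` additional passes are applied to the 3' LTR interval
#' only; finally background substitutions are drawn uniformly over positions
#' and non-self target bases (excluding G>A unless `allowBackgroundGA`, so
#' mismatch classes remain attributable). Every deamination is realized as
#' plus-strand G->A.
#'
#' @param template a \linkS4class{ProvirusTemplate}.
#' @param config an [editConfig()].
#' @return list with `edited` (length-1 named `DNAStringSet`), `truth`
#'   (list: `events` data frame `pos`, `pass`, `context` in edit order;
#'   `background` data frame `pos`, `fromBase`, `toBase`), and `config`.
#' @export
simulateEditing <- function(template, config = editConfig()) {
  stopifnot(methods::is(template, "ProvirusTemplate"),
            inherits(config, "EditConfig"))
  set.seed(config$seed)
  refChars <- .chars(templateSeq(template))
  L <- length(refChars)
  chars <- refChars
  ltr3 <- ltr3Range(template)

  evPos <- integer(0); evPass <- integer(0); evCtx <- character(0)

  runPass <- function(passIdx, interval) {
    sites <- which(chars == "G")
    sites <- sites[sites >= interval[1] & sites <= interval[2]]
    if (config$scanDirection == "minus5to3") sites <- rev(sites)
    for (i in sites) {
      ctxSrc <- if (config$cascade) chars else refChars
      ctx <- .minusContextAt(ctxSrc, i, L)
      pr <- min(1, config$baseRate * .weightOf(ctx, config))
      if (pr > 0 && stats::runif(1L) < pr) {
        chars[i] <<- "A"
        evPos <<- c(evPos, i)
        evPass <<- c(evPass, passIdx)
        evCtx <<- c(evCtx, if (is.na(ctx)) "" else ctx)
      }
    }
  }

  for (p in seq_len(config$passes)) runPass(p, c(1L, L))
  if (config$ltr3ExtraExposure > 0L) {
    for (e in seq_len(config$ltr3ExtraExposure)) {
      runPass(config$passes + e, ltr3)
    }
  }

  bgPos <- integer(0); bgFrom <- character(0); bgTo <- character(0)
  if (config$backgroundSubRate > 0) {
    hits <- which(stats::runif(L) < config$backgroundSubRate)
    for (i in hits) {
      from <- chars[i]
      targets <- setdiff(DNA_BASES, from)
      if (!config$allowBackgroundGA && from == "G") {
        targets <- setdiff(targets, "A")
      }
      to <- sample(targets, 1L)
      chars[i] <- to
      bgPos <- c(bgPos, i); bgFrom <- c(bgFrom, from); bgTo <- c(bgTo, to)
    }
  }

  edited <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(edited) <- "edited"
  list(
    edited = edited,
    truth = list(
      events = data.frame(pos = evPos, pass = evPass, context = evCtx,
                          stringsAsFactors = FALSE),
      background = data.frame(pos = bgPos, fromBase = bgFrom, toBase = bgTo,
                              stringsAsFactors = FALSE)
    ),
    config = config
  )
}

#' Copy the 3' LTR over the 5' LTR (retrotransposition signature)
#'
#' When a provirus transcript is reverse transcribed into a new provirus,
#' both new LTRs derive from the template's 3' LTR U3/U5: any mutations
#' unique to the 3' LTR become shared by both LTRs of the copy, and the
#' copy's LTRs are identical.
#'
#' @param x a \linkS4class{ProvirusTemplate}, or a sequence (character /
#'   `DNAStringSet` element) when `ltr5` and `ltr3` are given.
#' @param ltr5,ltr3 `c(start, end)` LTR intervals (taken from the template
#'   when `x` is one).
#' @return a length-1 named `DNAStringSet` with both LTR intervals carrying
#'   the 3'-LTR sequence and the body unchanged.
#' @export
simulateLtrCopy <- function(x, ltr5 = NULL, ltr3 = NULL) {
  if (methods::is(x, "ProvirusTemplate")) {
    if (is.null(ltr5)) ltr5 <- ltr5Range(x)
    if (is.null(ltr3)) ltr3 <- ltr3Range(x)
    s <- templateSeq(x)
  } else {
    if (is.null(ltr5) || is.null(ltr3)) {
      stop("ltr5 and ltr3 intervals are required for raw sequences")
    }
    s <- .asSeq(x)$seq
  }
  chars <- .chars(s)
  chars[ltr5[1]:ltr5[2]] <- chars[ltr3[1]:ltr3[2]]
  out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(out) <- "ltr_copy"
  out
}

#' Census of minus-strand contexts over the template's G sites
#'
#' Reference-context weights for every plus-strand G in `interval`; the
#' analytic substrate for edit-count expectations and rate tuning.
#'
#' @param template a \linkS4class{ProvirusTemplate}.
#' @param config an [editConfig()] (supplies weights).
#' @param interval optional `c(start, end)` restriction.
#' @return data frame with columns `pos`, `context`, `weight`.
#' @export
contextCensus <- function(template, config = editConfig(),
                          interval = NULL) {
  chars <- .chars(templateSeq(template))
  L <- length(chars)
  sites <- which(chars == "G")
  if (!is.null(interval)) {
    sites <- sites[sites >= interval[1] & sites <= interval[2]]
  }
  ctx <- vapply(sites, function(i) {
    v <- .minusContextAt(chars, i, L)
    if (is.na(v)) "" else v
  }, character(1L))
  w <- vapply(seq_along(sites), function(k) {
    .weightOf(if (nzchar(ctx[k])) ctx[k] else NA_character_, config)
  }, numeric(1L))
  data.frame(pos = sites, context = ctx, weight = w,
             stringsAsFactors = FALSE)
}

#' Tune the base editing rate to a target expected edit count
#'
#' Solves for `baseRate` such that the expected number of deamination events
#' under reference contexts equals `targetEdits`:
#' \eqn{\sum_i 1 - (1 - \min(1, r w_i))^{P_i} = target}, with `P_i` the
#' number of passes covering site i (global passes, plus the 3'-LTR extra
#' exposure inside that interval). Exact for `cascade = FALSE`; for cascade
#' simulations it is the matched-expectation rate under the reference
#' context, which is how matched-count comparisons are constructed.
#'
#' @param template a \linkS4class{ProvirusTemplate}.
#' @param config an [editConfig()] carrying weights, passes and exposure.
#' @param targetEdits desired expected number of deamination events.
#' @param interval optional restriction of the census.
#' @return the tuned `baseRate` (numeric).
#' @export
tuneEditRate <- function(template, config, targetEdits, interval = NULL) {
  census <- contextCensus(template, config, interval)
  if (!nrow(census)) stop("no G sites in the chosen interval")
  ltr3 <- ltr3Range(template)
  passesPer <- config$passes +
    ifelse(census$pos >= ltr3[1] & census$pos <= ltr3[2],
           config$ltr3ExtraExposure, 0L)
  expected <- function(r) {
    pr <- pmin(1, r * census$weight)
    sum(1 - (1 - pr)^passesPer) - targetEdits
  }
  upper <- 1  # per-site probabilities cap at 1, so baseRate itself may reach 1
  if (expected(upper) < 0) {
    stop("targetEdits unreachable: expected at most ",
         round(targetEdits + expected(upper), 1), " edits")
  }
  stats::uniroot(expected, c(0, upper), tol = 1e-10)$root
}

#' Write simulation truth as TSV
#'
#' @param truth the `truth` element of a [simulateEditing()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
  utils::write.table(truth$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
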