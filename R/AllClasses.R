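#' @import methods
NULL

#' Pairwise alignment of a query provirus to a reference
#'
#' Column-wise correspondence between an ungapped reference and a query,
#' stored as two equal-length gapped strings. All downstream coordinates are
#' 1-based positions on the ungapped reference plus strand.
#'
#' @slot refId,qryId sequence identifiers.
#' @slot refAln,qryAln aligned sequences (characters over \code{A,C,G,T,N,-}),
#'   equal length.
#' @slot score alignment score (\code{NA} for alignments ingested from an
#'   aligned FASTA rather than computed).
#'
#' @seealso [alignPairwise()], [ingestAlignedFasta()], [refPositions()]
#' @export
setClass("PairwiseAln",
  representation(
    refId = "character", qryId = "character",
    refAln = "character", qryAln = "character",
    score = "numeric"
  ),
  prototype(score = NA_real_)
)

setValidity("PairwiseAln", function(object) {
  msg <- character(0)
  if (length(object@refAln) != 1L || length(object@qryAln) != 1L) {
    msg <- c(msg, "refAln and qryAln must be single strings")
  } else {
    if (nchar(object@refAln) != nchar(object@qryAln)) {
      msg <- c(msg, "aligned strings must have equal length")
    }
    if (nchar(object@refAln) == 0L) msg <- c(msg, "alignment is empty")
    if (grepl("[^ACGTN-]", object@refAln) || grepl("[^ACGTN-]", object@qryAln)) {
      msg <- c(msg, "aligned strings restricted to {A,C,G,T,N,-}")
    }
    if (!grepl("[^-]", object@refAln)) {
      msg <- c(msg, "reference side must contain at least one base")
    }
  }
  if (!nzchar(object@refId) || !nzchar(object@qryId)) {
    msg <- c(msg, "refId and qryId must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' Hypermutation summary profile
#'
#' Classified substitution counts for one query-versus-reference comparison,
#' with the derived hypermutation statistics: percent G>A of all mismatches,
#' G>A per 1,000 reference bases, query base composition over the compared
#' span, and the histogram of runs of consecutive G>A mutations.
#'
#' @slot counts named integer, one entry per substitution class.
#' @slot total sum over all 12 classes.
#' @slot alignedRefLength reference bases in the compared span.
#' @slot pctGAofTotal percent G>A of total mismatches (\code{NA} when total 0).
#' @slot GAperKb G>A mismatches per 1,000 reference bases.
#' @slot pctG,pctA percent G / percent A in the query over the compared span
#'   (\code{NA} when no composition span was supplied).
#' @slot runHistogram named integer: run length (>= 2) to number of maximal
#'   runs of consecutive G>A mutations.
#' @slot indelColumns alignment columns holding a gap in exactly one of the
#'   two sequences; reported, never counted as mismatches.
#'
#' @seealso [summarizeProfile()], [profileAlignment()]
#' @export
setClass("MismatchProfile",
  representation(
    counts = "integer", total = "integer", alignedRefLength = "integer",
    pctGAofTotal = "numeric", GAperKb = "numeric",
    pctG = "numeric", pctA = "numeric",
    runHistogram = "integer", indelColumns = "integer"
  )
)

setValidity("MismatchProfile", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@counts)), sort(MISMATCH_CLASSES))) {
    msg <- c(msg, "counts must be named by the 12 substitution classes")
  }
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@total) == 1L && object@total != sum(object@counts)) {
    msg <- c(msg, "total must equal the sum of class counts")
  }
  if (length(object@alignedRefLength) == 1L && object@alignedRefLength <= 0L) {
    msg <- c(msg, "alignedRefLength must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Position frequency matrix of minus-strand target-site contexts
#'
#' Aggregated per-position base frequencies for the (-2, -1, C) minus-strand
#' trinucleotide contexts of G>A sites, with per-position information content
#' in bits (2 minus the Shannon entropy, no small-sample correction).
#'
#' @slot freqs 4 x 3 matrix (rows A,C,G,T; columns -2, -1, 0), each column
#'   summing to 1.
#' @slot infoBits information content per position, in [0, 2].
#' @slot nSites number of context sites aggregated.
#'
#' @seealso [buildLogo()], [classifyPreference()]
#' @export
setClass("LogoMatrix",
  representation(freqs = "matrix", infoBits = "numeric", nSites = "integer")
)

setValidity("LogoMatrix", function(object) {
  msg <- character(0)
  if (!identical(dim(object@freqs), c(4L, 3L))) {
    msg <- c(msg, "freqs must be a 4 x 3 matrix")
  } else {
    if (!identical(rownames(object@freqs), DNA_BASES)) {
      msg <- c(msg, "freqs rows must be A,C,G,T")
    }
    if (any(object@freqs < 0)) msg <- c(msg, "frequencies must be nonnegative")
    if (any(abs(colSums(object@freqs) - 1) > 1e-9)) {
      msg <- c(msg, "each column must sum to 1")
    }
  }
  if (any(object@infoBits < -1e-9 | object@infoBits > 2 + 1e-9)) {
    msg <- c(msg, "information content must lie in [0, 2]")
  }
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Comparison of a provirus's two LTRs against a reference LTR
#'
#' Substitutions relative to the reference LTR classified as shared by both
#' LTRs (same base at the same reference position), 5'-specific, or
#' 3'-specific. Single-base indels are reported separately and never counted
#' among the substitution classes.
#'
#' @slot shared,fiveSpecific,threeSpecific data frames with columns
#'   \code{refPos}, \code{klass}, \code{qryBase}.
#' @slot threeSpecificGACount number of 3'-specific G>A substitutions.
#' @slot indelPositions list with elements \code{five} and \code{three}:
#'   reference positions adjacent to indels in each LTR alignment.
#'
#' @seealso [compareLTRs()]
#' @export
setClass("LTRComparison",
  representation(
    shared = "data.frame", fiveSpecific = "data.frame",
    threeSpecific = "data.frame", threeSpecificGACount = "integer",
    indelPositions = "list"
  )
)

setValidity("LTRComparison", function(object) {
  msg <- character(0)
  key <- function(d) paste(d$refPos, d$klass)
  ks <- key(object@shared); k5 <- key(object@fiveSpecific); k3 <- key(object@threeSpecific)
  if (length(intersect(ks, k5)) || length(intersect(ks, k3))) {
    msg <- c(msg, "shared and specific lists must be disjoint by (refPos, class)")
  }
  n3 <- sum(object@threeSpecific$klass == "G>A")
  if (object@threeSpecificGACount != n3) {
    msg <- c(msg, "threeSpecificGACount inconsistent with threeSpecific")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth provirus template for deamination simulation
#'
#' A synthetic provirus: random-composition body flanked by two identical
#' LTRs (proviral LTRs are identical at integration) with one internal CDS
#' seeded with an ATG start and tryptophan (TGG) codons, the codons uniquely
#' convertible to stops by G>A editing.
#'
#' @slot seq plus-strand sequence (character).
#' @slot ltr5,ltr3 integer \code{c(start, end)} intervals, 1-based inclusive.
#' @slot cds data frame of CDS annotations (gene, start, end, frame).
#' @slot seed the seed the template was generated under.
#'
#' @seealso [generateProvirus()], [simulateEditing()]
#' @export
setClass("ProvirusTemplate",
  representation(
    seq = "character", ltr5 = "integer", ltr3 = "integer",
    cds = "data.frame", seed = "integer"
  )
)

setValidity("ProvirusTemplate", function(object) {
  msg <- character(0)
  L <- nchar(object@seq)
  iv <- function(x) length(x) == 2L && x[1] >= 1L && x[2] <= L && x[1] <= x[2]
  if (!iv(object@ltr5) || !iv(object@ltr3)) {
    msg <- c(msg, "LTR intervals must be valid c(start, end) within the sequence")
  } else {
    if (object@ltr5[2] >= object@ltr3[1]) {
      msg <- c(msg, "LTR intervals must be non-overlapping and in order")
    }
    s5 <- substring(object@seq, object@ltr5[1], object@ltr5[2])
    s3 <- substring(object@seq, object@ltr3[1], object@ltr3[2])
    if (!identical(s5, s3)) {
      msg <- c(msg, "the two LTR subsequences must be identical at generation")
    }
  }
  if (length(msg)) msg else TRUE
})
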