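# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @rdname PairwiseAln-class
#' @param x,object a \linkS4class{PairwiseAln}.
#' @export
setGeneric("refId", function(x) standardGeneric("refId"))
#' @rdname PairwiseAln-class
#' @export
setGeneric("qryId", function(x) standardGeneric("qryId"))
#' @rdname PairwiseAln-class
#' @export
setGeneric("alignedRef", function(x) standardGeneric("alignedRef"))
#' @rdname PairwiseAln-class
#' @export
setGeneric("alignedQry", function(x) standardGeneric("alignedQry"))
#' @rdname PairwiseAln-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' Ungapped reference coordinate of every alignment column
#'
#' Returns one value per alignment column: the 1-based position on the
#' ungapped reference, or \code{NA} for reference-gap (insertion) columns.
#'
#' @param x a \linkS4class{PairwiseAln}.
#' @return integer vector, length = number of alignment columns.
#' @export
setGeneric("refPositions", function(x) standardGeneric("refPositions"))

#' @rdname refPositions
#' @export
setGeneric("qryPositions", function(x) standardGeneric("qryPositions"))

setMethod("refId", "PairwiseAln", function(x) x@refId)
setMethod("qryId", "PairwiseAln", function(x) x@qryId)
setMethod("alignedRef", "PairwiseAln", function(x) x@refAln)
setMethod("alignedQry", "PairwiseAln", function(x) x@qryAln)
setMethod("alignmentScore", "PairwiseAln", function(x) x@score)

setMethod("refPositions", "PairwiseAln", function(x) {
  rc <- .chars(x@refAln)
  pos <- cumsum(rc != "-")
  pos[rc == "-"] <- NA_integer_
  as.integer(pos)
})

setMethod("qryPositions", "PairwiseAln", function(x) {
  qc <- .chars(x@qryAln)
  pos <- cumsum(qc != "-")
  pos[qc == "-"] <- NA_integer_
  as.integer(pos)
})

#' @export
setMethod("show", "PairwiseAln", function(object) {
  n <- nchar(object@refAln)
  rc <- .chars(object@refAln); qc <- .chars(object@qryAln)
  nmm <- sum(rc != qc & rc %in% DNA_BASES & qc %in% DNA_BASES)
  ngap <- sum(rc == "-" | qc == "-")
  cat("PairwiseAln: ", object@qryId, " vs ", object@refId, "\n", sep = "")
  cat("  columns: ", n, "  mismatches: ", nmm, "  gap columns: ", ngap,
      "  score: ", format(object@score), "\n", sep = "")
})

#' @rdname MismatchProfile-class
#' @param x,object a \linkS4class{MismatchProfile}.
#' @export
setGeneric("mismatchCounts", function(x) standardGeneric("mismatchCounts"))
#' @rdname MismatchProfile-class
#' @export
setGeneric("runHistogram", function(x) standardGeneric("runHistogram"))
#' @rdname MismatchProfile-class
#' @export
setGeneric("pctGAofTotal", function(x) standardGeneric("pctGAofTotal"))
#' @rdname MismatchProfile-class
#' @export
setGeneric("GAperKb", function(x) standardGeneric("GAperKb"))
#' @rdname MismatchProfile-class
#' @export
setGeneric("alignedRefLength", function(x) standardGeneric("alignedRefLength"))

setMethod("mismatchCounts", "MismatchProfile", function(x) x@counts)
setMethod("runHistogram", "MismatchProfile", function(x) x@runHistogram)
setMethod("pctGAofTotal", "MismatchProfile", function(x) x@pctGAofTotal)
setMethod("GAperKb", "MismatchProfile", function(x) x@GAperKb)
setMethod("alignedRefLength", "MismatchProfile", function(x) x@alignedRefLength)

#' @export
setMethod("show", "MismatchProfile", function(object) {
  cat("MismatchProfile over ", object@alignedRefLength, " reference bases\n",
      sep = "")
  top <- object@counts[c("G>A", "C>T", "A>G")]
  cat("  G>A: ", top[1], "  C>T: ", top[2], "  A>G: ", top[3],
      "  total: ", object@total, "\n", sep = "")
  cat("  %G>A/total: ",
      ifelse(is.na(object@pctGAofTotal), "-",
             format(roundHalfUp(object@pctGAofTotal, 1), nsmall = 1)),
      "  G>A per kb: ", format(roundHalfUp(object@GAperKb, 1), nsmall = 1),
      "\n", sep = "")
  if (length(object@runHistogram)) {
    cat("  runs of G>A: ",
        paste(names(object@runHistogram), object@runHistogram,
              sep = "x", collapse = ", "), "\n", sep = "")
  }
})

#' @rdname LogoMatrix-class
#' @param x,object a \linkS4class{LogoMatrix}.
#' @export
setGeneric("logoFreqs", function(x) standardGeneric("logoFreqs"))
#' @rdname LogoMatrix-class
#' @export
setGeneric("infoBits", function(x) standardGeneric("infoBits"))
#' @rdname LogoMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

setMethod("logoFreqs", "LogoMatrix", function(x) x@freqs)
setMethod("infoBits", "LogoMatrix", function(x) x@infoBits)
setMethod("nSites", "LogoMatrix", function(x) x@nSites)

#' @export
setMethod("show", "LogoMatrix", function(object) {
  cat("LogoMatrix from ", object@nSites, " minus-strand context sites\n",
      sep = "")
  m <- rbind(round(object@freqs, 3), info = round(object@infoBits, 3))
  print(m)
})

#' @rdname LTRComparison-class
#' @param x,object an \linkS4class{LTRComparison}.
#' @export
setGeneric("sharedSubs", function(x) standardGeneric("sharedSubs"))
#' @rdname LTRComparison-class
#' @export
setGeneric("fiveSpecific", function(x) standardGeneric("fiveSpecific"))
#' @rdname LTRComparison-class
#' @export
setGeneric("threeSpecific", function(x) standardGeneric("threeSpecific"))
#' @rdname LTRComparison-class
#' @export
setGeneric("threeSpecificGACount", function(x) standardGeneric("threeSpecificGACount"))
#' @rdname LTRComparison-class
#' @export
setGeneric("indelPositions", function(x) standardGeneric("indelPositions"))

setMethod("sharedSubs", "LTRComparison", function(x) x@shared)
setMethod("fiveSpecific", "LTRComparison", function(x) x@fiveSpecific)
setMethod("threeSpecific", "LTRComparison", function(x) x@threeSpecific)
setMethod("threeSpecificGACount", "LTRComparison", function(x) x@threeSpecificGACount)
setMethod("indelPositions", "LTRComparison", function(x) x@indelPositions)

#' @export
setMethod("show", "LTRComparison", function(object) {
  cat("LTRComparison\n")
  cat("  shared substitutions:      ", nrow(object@shared), "\n", sep = "")
  cat("  5'-specific substitutions: ", nrow(object@fiveSpecific), "\n", sep = "")
  cat("  3'-specific substitutions: ", nrow(object@threeSpecific),
      " (G>A: ", object@threeSpecificGACount, ")\n", sep = "")
  ni <- vapply(object@indelPositions, length, 0L)
  cat("  indel positions: 5' ", ni[["five"]], ", 3' ", ni[["three"]], "\n",
      sep = "")
})

#' @rdname ProvirusTemplate-class
#' @param x,object a \linkS4class{ProvirusTemplate}.
#' @export
setGeneric("templateSeq", function(x) standardGeneric("templateSeq"))
#' @rdname ProvirusTemplate-class
#' @export
setGeneric("ltr5Range", function(x) standardGeneric("ltr5Range"))
#' @rdname ProvirusTemplate-class
#' @export
setGeneric("ltr3Range", function(x) standardGeneric("ltr3Range"))
#' @rdname ProvirusTemplate-class
#' @export
setGeneric("cdsTable", function(x) standardGeneric("cdsTable"))

setMethod("templateSeq", "ProvirusTemplate", function(x) x@seq)
setMethod("ltr5Range", "ProvirusTemplate", function(x) x@ltr5)
setMethod("ltr3Range", "ProvirusTemplate", function(x) x@ltr3)
setMethod("cdsTable", "ProvirusTemplate", function(x) x@cds)

#' @export
setMethod("show", "ProvirusTemplate", function(object) {
  cat("ProvirusTemplate: ", nchar(object@seq), " bp, LTRs [",
      object@ltr5[1], "-", object@ltr5[2], "] and [",
      object@ltr3[1], "-", object@ltr3[2], "] (identical), ",
      nrow(object@cds), " CDS, seed ", object@seed, "\n", sep = "")
})
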