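# Substitution classification and hypermutation summary statistics.

#' Classify substitutions relative to the reference
#'
#' One record per alignment column where both characters are proper bases
#' (A, C, G, T) and differ. Columns containing a gap or `N` contribute
#' nothing: indels are never counted as mismatches. Records are ordered by
#' reference position. A clear excess of G>A over C>T (plus-strand) is the
#' signature of minus-strand cytidine deaminase editing.
#'
#' @param aln a \linkS4class{PairwiseAln}.
#' @param region optional `c(start, end)` interval on the ungapped reference;
#'   only columns within it are classified. An empty overlap yields an empty
#'   frame, not an error.
#' @return data frame with columns `refPos`, `refBase`, `qryBase`, `klass`
#'   (factor over the 12 substitution classes).
#' @export
classifyMismatches <- function(aln, region = NULL) {
  rc <- .chars(alignedRef(aln))
  qc <- .chars(alignedQry(aln))
  refPos <- cumsum(rc != "-")
  ok <- rc %in% DNA_BASES & qc %in% DNA_BASES & rc != qc
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] <= region[2])
    ok <- ok & refPos >= region[1] & refPos <= region[2]
  }
  if (!any(ok)) return(.emptyMismatchFrame())
  data.frame(
    refPos = as.integer(refPos[ok]),
    refBase = rc[ok],
    qryBase = qc[ok],
    klass = factor(paste0(rc[ok], ">", qc[ok]), levels = MISMATCH_CLASSES),
    stringsAsFactors = FALSE
  )
}

#' Base composition of a sequence
#'
#' Percent G and percent A over the non-`N`, non-gap characters. Massive
#' deaminase editing depresses %G and inflates %A relative to the reference.
#'
#' @param seq a sequence (character string, `DNAString`, or `DNAStringSet`
#'   element).
#' @return named numeric `c(pctG =, pctA =)`.
#' @export
baseComposition <- function(seq) {
  s <- .asSeq(seq)$seq
  if (!nzchar(s)) stop("sequence must be nonempty")
  ch <- .chars(s)
  ch <- ch[ch %in% DNA_BASES]
  if (!length(ch)) stop("no non-N bases in sequence")
  c(pctG = 100 * mean(ch == "G"), pctA = 100 * mean(ch == "A"))
}

#' Runs of consecutive G>A mutations
#'
#' A maximal set of k adjacent reference positions each carrying a G>A
#' record counts once under key k, for k >= 2 (consecutive minus-strand
#' cytosines — C tracts — sustain such runs under deaminase editing).
#' Non-G>A records and position gaps break runs; lengths above 5 are kept
#' under their own exact key, not truncated.
#'
#' @param records mismatch records as from [classifyMismatches()], sorted by
#'   `refPos`.
#' @return named integer vector: run length -> number of maximal runs.
#' @export
findRuns <- function(records) {
  pos <- sort(unique(records$refPos[records$klass == "G>A"]))
  if (length(pos) < 2L) return(stats::setNames(integer(0), character(0)))
  grp <- cumsum(c(1L, diff(pos) != 1L))
  lens <- tabulate(grp)
  lens <- lens[lens >= 2L]
  if (!length(lens)) return(stats::setNames(integer(0), character(0)))
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Summarize mismatch records into a hypermutation profile
#'
#' Computes the per-class counts, total, percent G>A of total mismatches,
#' G>A per 1,000 reference bases, query base composition over the compared
#' span, and the run histogram. Percent values are carried at full
#' precision; presentation rounding belongs to the reporting layer.
#'
#' @param records mismatch records from [classifyMismatches()].
#' @param alignedRefLength reference bases in the compared span (> 0).
#' @param qrySpan optional query sequence over the compared span, used for
#'   the composition percentages.
#' @param indelColumns number of single-gap alignment columns, carried for
#'   reporting only.
#' @return a \linkS4class{MismatchProfile}.
#' @export
summarizeProfile <- function(records, alignedRefLength, qrySpan = NULL,
                             indelColumns = 0L) {
  stopifnot(alignedRefLength > 0)
  counts <- table(factor(records$klass, levels = MISMATCH_CLASSES))
  counts <- stats::setNames(as.integer(counts), MISMATCH_CLASSES)
  total <- sum(counts)
  comp <- c(pctG = NA_real_, pctA = NA_real_)
  if (!is.null(qrySpan)) comp <- baseComposition(qrySpan)
  methods::new("MismatchProfile",
    counts = counts,
    total = as.integer(total),
    alignedRefLength = as.integer(alignedRefLength),
    pctGAofTotal = if (total > 0) 100 * counts[["G>A"]] / total else NA_real_,
    GAperKb = 1000 * counts[["G>A"]] / alignedRefLength,
    pctG = unname(comp["pctG"]), pctA = unname(comp["pctA"]),
    runHistogram = findRuns(records),
    indelColumns = as.integer(indelColumns)
  )
}

#' Profile an alignment in one step
#'
#' Convenience wrapper: classifies mismatches over `region` (default: the
#' whole reference span of the alignment), extracts the query bases aligned
#' to that span for composition, counts single-gap columns, and summarizes.
#'
#' @inheritParams classifyMismatches
#' @return a \linkS4class{MismatchProfile}.
#' @export
profileAlignment <- function(aln, region = NULL) {
  rc <- .chars(alignedRef(aln))
  qc <- .chars(alignedQry(aln))
  refPos <- cumsum(rc != "-")
  refLen <- max(refPos)
  if (is.null(region)) region <- c(1L, refLen)
  inSpan <- rc != "-" & refPos >= region[1] & refPos <= region[2]
  spanLen <- sum(inSpan)
  if (spanLen == 0L) stop("region does not overlap the reference span")
  qryChars <- qc[inSpan & qc != "-"]
  indels <- sum(xor(rc == "-", qc == "-") &
                  refPos >= region[1] & refPos <= region[2])
  summarizeProfile(
    classifyMismatches(aln, region = region),
    alignedRefLength = spanLen,
    qrySpan = if (length(qryChars)) paste(qryChars, collapse = "") else NULL,
    indelColumns = indels
  )
}

#' Write mismatch records as TSV
#'
#' @param records mismatch records from [classifyMismatches()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMismatchTsv <- function(records, path) {
  out <- records
  out$klass <- as.character(out$klass)
  names(out) <- c("ref_pos", "ref_base", "qry_base", "class")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a profile to JSON
#'
#' @param profile a \linkS4class{MismatchProfile}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileJson <- function(profile, path) {
  x <- list(
    counts = as.list(mismatchCounts(profile)),
    total = profile@total,
    aligned_ref_length = alignedRefLength(profile),
    pct_GA_of_total = pctGAofTotal(profile),
    GA_per_kb = GAperKb(profile),
    pct_G = profile@pctG, pct_A = profile@pctA,
    run_histogram = as.list(runHistogram(profile)),
    indel_columns = profile@indelColumns
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
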