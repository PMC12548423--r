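#' Read nucleotide FASTA with normalization
#'
#' Reads a FASTA file into a named [Biostrings::DNAStringSet]. Sequences are
#' uppercased, RNA `U` is mapped to `T`, and IUPAC ambiguity codes other than
#' `N` (R, Y, S, W, K, M, B, D, H, V) are normalized to `N` with a warning;
#' `N` never participates in downstream mismatch counting. Gaps (`-`) are
#' preserved so aligned FASTA can be ingested. Any other character is an
#' error.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .usageError("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA records must have nonempty ids")
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  amb <- "RYSWKMBDHV"
  nAmb <- sum(nchar(gsub(sprintf("[^%s]", amb), "", seqs)))
  if (nAmb > 0L) {
    warning(nAmb, " IUPAC ambiguity code(s) normalized to N")
    seqs <- chartr(amb, strrep("N", nchar(amb)), seqs)
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param x a `DNAStringSet` or named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("character input must be named")
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Majority-rule consensus of aligned sequences
#'
#' Per-column majority base over pre-aligned, equal-length sequences. Columns
#' whose majority character is a gap are dropped from the consensus. `N` is
#' ignored in the vote unless a column is all-`N`. Ties are broken by the
#' character the first record carries at that column when it is among the
#' tied winners, otherwise alphabetically — a deterministic, documented rule
#' (used e.g. to build a group consensus reference for proviruses lacking a
#' close nondefective relative).
#'
#' @param records a `DNAStringSet` or named character vector, >= 2 records.
#' @param preAligned assert that the input is already aligned (equal
#'   lengths). Alignment itself must be done upstream; `preAligned = FALSE`
#'   is an error.
#' @param name id of the returned consensus record.
#' @return a length-1 named `DNAStringSet`.
#' @export
buildConsensus <- function(records, preAligned = TRUE, name = "consensus") {
  seqs <- .asSeqs(records)
  if (length(seqs) < 2L) stop("consensus requires at least 2 records")
  if (!isTRUE(preAligned)) {
    stop("input must be pre-aligned (preAligned = TRUE); ",
         "alignment must be done upstream")
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("pre-aligned records must have equal lengths")
  }
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cons <- apply(m, 2L, function(col) {
    voting <- col[col != "N"]
    if (!length(voting)) return("N")
    tab <- table(voting)
    winners <- names(tab)[tab == max(tab)]
    if (col[1L] %in% winners) col[1L] else sort(winners)[1L]
  })
  cons <- cons[cons != "-"]
  out <- Biostrings::DNAStringSet(paste(cons, collapse = ""))
  names(out) <- name
  out
}

#' Alignment scoring parameters
#'
#' Affine gap scoring: a gap of length L costs `gapOpen + L * gapExtend`.
#' Defaults are deliberately gap-averse (match 2, mismatch -3, open 8,
#' extend 2) so that isolated substitutions are not absorbed into indels —
#' the analysis counts substitutions, not indels.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gapOpen,gapExtend gap penalties, `gapOpen >= gapExtend >= 0`.
#' @return a list of class `AlignParams`.
#' @export
alignParams <- function(match = 2, mismatch = -3, gapOpen = 8, gapExtend = 2) {
  if (!(gapOpen >= gapExtend && gapExtend >= 0)) {
    stop("require gapOpen >= gapExtend >= 0")
  }
  structure(
    list(match = match, mismatch = mismatch,
         gapOpen = gapOpen, gapExtend = gapExtend),
    class = "AlignParams"
  )
}

#' Global pairwise alignment of a query against a reference
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring,
#' computed with [Biostrings::pairwiseAlignment()]. A desk-scale stand-in
#' for external multiple aligners when only one query is compared to one
#' reference.
#'
#' @param ref,qry reference and query sequences (`DNAStringSet` element,
#'   `DNAString`, or named character).
#' @param params an [alignParams()] object.
#' @return a \linkS4class{PairwiseAln}.
#' @examples
#' aln <- alignPairwise(c(ref = "ACGT"), c(q = "AGT"),
#'                      alignParams(1, -1, 2, 1))
#' alignedQry(aln)  # "A-GT"
#' @export
alignPairwise <- function(ref, qry, params = alignParams()) {
  r <- .asSeq(ref, "ref"); q <- .asSeq(qry, "qry")
  if (!nzchar(r$seq) || !nzchar(q$seq)) stop("sequences must be nonempty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch,
    baseOnly = FALSE, type = "DNA"
  )
  pa <- Biostrings::pairwiseAlignment(
    pattern = q$seq, subject = r$seq, type = "global",
    substitutionMatrix = mat,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend
  )
  methods::new("PairwiseAln",
    refId = r$id, qryId = q$id,
    refAln = as.character(Biostrings::alignedSubject(pa)),
    qryAln = as.character(Biostrings::alignedPattern(pa)),
    score = Biostrings::score(pa)
  )
}

#' Ingest a multiple alignment as reference-anchored pairwise alignments
#'
#' Splits an aligned FASTA (e.g. MUSCLE or ClustalW output) into one
#' \linkS4class{PairwiseAln} per non-reference record, all sharing the
#' reference coordinate frame. Columns gapped in both the reference and a
#' given query are dropped from that pair.
#'
#' @param records equal-length aligned sequences (`DNAStringSet` or named
#'   character).
#' @param refId id of the reference record; must be present.
#' @return a named list of \linkS4class{PairwiseAln}, one per query; empty
#'   list when only the reference is supplied.
#' @export
ingestAlignedFasta <- function(records, refId) {
  seqs <- .asSeqs(records)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned records must have equal lengths")
  }
  if (!refId %in% names(seqs)) stop("reference id not found: ", refId)
  refChars <- .chars(seqs[[refId]])
  qryIds <- setdiff(names(seqs), refId)
  out <- lapply(qryIds, function(id) {
    qc <- .chars(seqs[[id]])
    keep <- !(refChars == "-" & qc == "-")
    methods::new("PairwiseAln",
      refId = refId, qryId = id,
      refAln = paste(refChars[keep], collapse = ""),
      qryAln = paste(qc[keep], collapse = "")
    )
  })
  names(out) <- qryIds
  out
}

#' Export a pairwise alignment as aligned FASTA
#'
#' @param aln a \linkS4class{PairwiseAln}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(aln, path) {
  seqs <- Biostrings::DNAStringSet(c(alignedRef(aln), alignedQry(aln)))
  names(seqs) <- c(refId(aln), qryId(aln))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
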