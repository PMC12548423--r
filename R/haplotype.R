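# Diagnostic-site haplotype enumeration for deaminase coding sequences.

#' Read a diagnostic-site table
#'
#' TSV with columns `column` (1-based alignment column or codon index),
#' `residueA`, `residueB` — the residues carried by the two named reference
#' alleles. The packaged default
#' (`inst/extdata/ma3_diagnostic_sites_synthetic.tsv`) is a synthetic
#' placeholder: the published diagnostic positions are figure-only, so real
#' analyses must supply their own table.
#'
#' @param path TSV path.
#' @return data frame with the three columns, validated.
#' @export
readDiagnosticSites <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("column", "residueA", "residueB")
  if (!all(need %in% names(d))) {
    stop("diagnostic site table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) < 1L) stop("diagnostic site set must contain >= 1 site")
  if (any(d$residueA == d$residueB)) {
    stop("residues must differ at every diagnostic site")
  }
  d
}

#' Genotype aligned sequences at diagnostic sites and enumerate haplotypes
#'
#' Extracts the residue vector of every sample at the diagnostic columns and
#' partitions samples into haplotypes: vectors equal to allele A or B get
#' those names; other complete vectors get deterministic ids `H1`, `H2`, ...
#' in order of first appearance. Samples with a gap, `N`, or `X` at a
#' diagnostic site are flagged incomplete, reported with their partial
#' vector (missing residues as `.`), and excluded from the distinct
#' haplotype count. Residues outside both reference alleles at a site raise
#' the `novelResidue` flag.
#'
#' To analyse samples covering only part of the gene (e.g. only the exons of
#' the active deaminase domain), pass the corresponding subset of `sites`;
#' calls are then compatibility classes over that subset rather than full
#' haplotypes.
#'
#' @param aln equal-length aligned sequences (nucleotide or translated;
#'   `XStringSet` or named character).
#' @param sites diagnostic site table ([readDiagnosticSites()] format).
#' @param alleleAName,alleleBName labels for the two reference alleles.
#' @param missingChars characters treated as missing data at a diagnostic
#'   site. The default suits nucleotide input; for translated input drop
#'   `"N"` (asparagine) and possibly `"X"` from the set.
#' @return list with `calls` (data frame: `sampleId`, `vector`, `label`,
#'   `incomplete`, `novelResidue`) and `nNovel`, the number of distinct
#'   complete non-reference haplotypes.
#' @export
callHaplotypes <- function(aln, sites, alleleAName = "alleleA",
                           alleleBName = "alleleB",
                           missingChars = c("-", "N", "X", ".", "?")) {
  if (methods::is(aln, "XStringSet")) {
    seqs <- toupper(as.character(aln))
  } else {
    seqs <- toupper(aln)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all samples must be named")
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("samples must be aligned to equal lengths")
  }
  width <- nchar(seqs[[1L]])
  if (any(sites$column < 1L | sites$column > width)) {
    stop("diagnostic site column outside the alignment")
  }
  refA <- paste(toupper(sites$residueA), collapse = "")
  refB <- paste(toupper(sites$residueB), collapse = "")

  n <- length(seqs)
  vecs <- character(n); incomplete <- logical(n); novel <- logical(n)
  for (i in seq_len(n)) {
    res <- .chars(seqs[[i]])[sites$column]
    miss <- res %in% missingChars
    incomplete[i] <- any(miss)
    novel[i] <- any(!miss & res != toupper(sites$residueA) &
                      res != toupper(sites$residueB))
    res[miss] <- "."
    vecs[i] <- paste(res, collapse = "")
  }

  labels <- rep(NA_character_, n)
  novelIds <- character(0)
  for (i in seq_len(n)) {
    if (incomplete[i]) next
    labels[i] <- if (vecs[i] == refA) {
      alleleAName
    } else if (vecs[i] == refB) {
      alleleBName
    } else {
      j <- match(vecs[i], novelIds)
      if (is.na(j)) {
        novelIds <- c(novelIds, vecs[i])
        j <- length(novelIds)
      }
      paste0("H", j)
    }
  }
  list(
    calls = data.frame(
      sampleId = names(seqs), vector = vecs, label = labels,
      incomplete = incomplete, novelResidue = novel,
      stringsAsFactors = FALSE
    ),
    nNovel = length(novelIds)
  )
}
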