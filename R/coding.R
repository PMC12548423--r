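# Coding-impact scanning: premature stops, start loss, nonsynonymous
# fraction of G>A changes. Standard nuclear genetic code throughout.

.translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

.checkCds <- function(cds) {
  need <- c("gene", "start", "end", "frame")
  if (!all(need %in% names(cds))) {
    stop("CDS annotation needs fields: ", paste(need, collapse = ", "))
  }
  if (cds$end - cds$start + 1L < 3L) stop("CDS shorter than one codon")
  if (!cds$frame %in% 0:2) stop("frame must be 0, 1 or 2")
  cds
}

# Reference/query codons for every complete codon of a CDS within an
# alignment. Query codons are read off the ungapped query bases aligned to
# the reference codon positions; codons touching a gap or N on either side
# are marked unusable.
.cdsCodons <- function(aln, cds) {
  cds <- .checkCds(as.list(cds))
  rc <- .chars(alignedRef(aln))
  qc <- .chars(alignedQry(aln))
  refLen <- sum(rc != "-")
  if (cds$start < 1L || cds$end > refLen) {
    stop("CDS [", cds$start, ", ", cds$end, "] outside the alignment's ",
         "reference span (", refLen, " bases)")
  }
  colOf <- integer(refLen)
  colOf[cumsum(rc != "-")[rc != "-"]] <- which(rc != "-")
  codStart <- cds$start + cds$frame
  nCod <- (cds$end - codStart + 1L) %/% 3L
  if (nCod < 1L) stop("no complete codon in CDS after frame offset")
  idx <- seq_len(nCod)
  firstPos <- codStart + 3L * (idx - 1L)
  refCod <- character(nCod); qryCod <- character(nCod); usable <- logical(nCod)
  for (k in idx) {
    cols <- colOf[firstPos[k] + 0:2]
    r3 <- rc[cols]; q3 <- qc[cols]
    usable[k] <- all(r3 %in% DNA_BASES) && all(q3 %in% DNA_BASES)
    refCod[k] <- paste(r3, collapse = "")
    qryCod[k] <- paste(q3, collapse = "")
  }
  nSkip <- sum(!usable)
  if (nSkip > 0L) {
    warning(nSkip, " codon(s) skipped (gap or N within codon)")
  }
  list(gene = cds$gene, codonIndex = idx, refCodon = refCod,
       qryCodon = qryCod, usable = usable, codStart = codStart)
}

#' Scan a CDS for premature stop codons gained in the query
#'
#' Emits one event per codon whose query translation is a stop (TAA, TAG,
#' TGA) while the reference codon is not. `causedByGAOnly` is `TRUE` when
#' every differing base within the codon is a plus-strand G>A change —
#' exhaustive scanning of the codon table shows tryptophan TGG is the only
#' non-stop codon reachable to a stop by G>A changes alone, so deaminase
#' editing leaves a distinctive all-TGG stop-gain signature.
#'
#' @param aln a \linkS4class{PairwiseAln}.
#' @param cds a one-row CDS annotation (`gene`, `start`, `end`, `frame`);
#'   codons are addressed 1-based from the frame-adjusted start. A CDS
#'   outside the alignment's reference span is an error; codons containing
#'   gaps are skipped with a warning.
#' @return data frame with columns `gene`, `codonIndex`, `refCodon`,
#'   `qryCodon`, `causedByGAOnly`.
#' @export
scanStopGains <- function(aln, cds) {
  cc <- .cdsCodons(aln, cds)
  hit <- cc$usable & cc$qryCodon %in% STOP_CODONS &
    !(cc$refCodon %in% STOP_CODONS)
  gaOnly <- vapply(which(hit), function(k) {
    r <- .chars(cc$refCodon[k]); q <- .chars(cc$qryCodon[k])
    d <- which(r != q)
    all(r[d] == "G" & q[d] == "A")
  }, logical(1L))
  data.frame(
    gene = rep(cc$gene, sum(hit)),
    codonIndex = cc$codonIndex[hit],
    refCodon = cc$refCodon[hit],
    qryCodon = cc$qryCodon[hit],
    causedByGAOnly = as.logical(gaOnly),
    stringsAsFactors = FALSE
  )
}

#' Check whether the annotated ATG start codon is lost in the query
#'
#' @inheritParams scanStopGains
#' @return list with `startLost` (`TRUE`/`FALSE`, or `NA` with
#'   `note = "no annotated start"` when the reference codon 1 is not ATG),
#'   `refCodon`, `qryCodon`.
#' @export
scanStartLoss <- function(aln, cds) {
  cc <- .cdsCodons(aln, cds)
  refCod <- cc$refCodon[1L]; qryCod <- cc$qryCodon[1L]
  if (refCod != "ATG") {
    return(list(startLost = NA, refCodon = refCod, qryCodon = qryCod,
                note = "no annotated start"))
  }
  list(startLost = !cc$usable[1L] || qryCod != "ATG",
       refCodon = refCod, qryCodon = qryCod, note = NA_character_)
}

#' Fraction of in-CDS G>A changes that are nonsynonymous
#'
#' Each G>A record inside the CDS is evaluated independently against the
#' reference codon (no compounding of multiple edits within a codon): the
#' single base is flipped G->A and the encoded amino acids compared under
#' the standard code.
#'
#' @param records mismatch records restricted to class G>A.
#' @param cds CDS annotation (`gene`, `start`, `end`, `frame`).
#' @param ref the ungapped reference sequence (character, `DNAString`, or
#'   `DNAStringSet` element).
#' @return fraction in `[0, 1]`, or `NA` when no G>A record falls in the
#'   CDS.
#' @export
nonsynFraction <- function(records, cds, ref) {
  cds <- .checkCds(as.list(cds))
  refSeq <- .asSeq(ref)$seq
  recs <- records[records$klass == "G>A", , drop = FALSE]
  codStart <- cds$start + cds$frame
  nCod <- (cds$end - codStart + 1L) %/% 3L
  lastBase <- codStart + 3L * nCod - 1L
  recs <- recs[recs$refPos >= codStart & recs$refPos <= lastBase, ,
               drop = FALSE]
  if (nrow(recs) == 0L) return(NA_real_)
  nonsyn <- vapply(recs$refPos, function(pos) {
    off <- (pos - codStart) %% 3L
    cpos <- pos - off
    refCod <- substring(refSeq, cpos, cpos + 2L)
    if (grepl("[^ACGT]", refCod)) return(NA)
    mut <- .chars(refCod)
    mut[off + 1L] <- "A"
    mutCod <- paste(mut, collapse = "")
    .translateCodon(refCod) != .translateCodon(mutCod)
  }, logical(1L))
  mean(nonsyn, na.rm = TRUE)
}

#' Enumerate codons convertible to stops by G>A changes alone
#'
#' Exhausts all 64 codons and all non-empty subsets of their G positions,
#' substituting A at each subset; returns the non-stop codons from which a
#' stop is reachable. The result is exactly `TGG`: the observation that
#' every deaminase-induced premature stop is a mutated tryptophan codon is a
#' theorem of the code, not a coincidence of any dataset.
#'
#' @return character vector of source codons (sorted).
#' @export
gaStopConvertibleCodons <- function() {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  codons <- sort(codons)
  hits <- vapply(codons, function(cod) {
    if (cod %in% STOP_CODONS) return(FALSE)
    ch <- .chars(cod)
    gpos <- which(ch == "G")
    if (!length(gpos)) return(FALSE)
    for (m in seq_len(2^length(gpos) - 1L)) {
      pick <- gpos[bitwAnd(m, 2^(seq_along(gpos) - 1L)) > 0L]
      mut <- ch
      mut[pick] <- "A"
      if (paste(mut, collapse = "") %in% STOP_CODONS) return(TRUE)
    }
    FALSE
  }, logical(1L))
  names(hits)[hits]
}
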