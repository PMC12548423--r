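# 5'-versus-3' LTR comparison against a reference LTR.

# reference positions adjacent to indels in one alignment: deletions report
# the deleted reference position, insertions the preceding reference
# position (0 for a leading insertion)
.indelRefPositions <- function(aln) {
  rc <- .chars(alignedRef(aln))
  qc <- .chars(alignedQry(aln))
  refPos <- cumsum(rc != "-")
  del <- refPos[qc == "-" & rc != "-"]
  ins <- refPos[rc == "-"]
  sort(unique(as.integer(c(del, ins))))
}

#' Compare a provirus's 5' and 3' LTRs against a reference LTR
#'
#' Both LTRs are aligned to the reference LTR on a common coordinate frame
#' and every substitution is classified as shared (both LTRs carry the same
#' substituted base at the same reference position), 5'-specific, or
#' 3'-specific. Proviral LTRs are identical at integration, so 3'-specific
#' G>A substitutions diagnose deaminase editing of the transiently
#' single-stranded nascent 3' LTR during the late stage of reverse
#' transcription.
#'
#' @param five,three the provirus's 5' and 3' LTR sequences.
#' @param refLtr the reference LTR.
#' @param params alignment parameters ([alignParams()]).
#' @param mask optional `c(start, end)` reference interval excluded from
#'   classification (e.g. a hypervariable segment where mismatches cannot be
#'   reliably identified).
#' @return an \linkS4class{LTRComparison}.
#' @export
compareLTRs <- function(five, three, refLtr, params = alignParams(),
                        mask = NULL) {
  a5 <- alignPairwise(refLtr, five, params)
  a3 <- alignPairwise(refLtr, three, params)
  checkIdentity <- function(a, which) {
    rc <- .chars(alignedRef(a)); qc <- .chars(alignedQry(a))
    ident <- mean(rc == qc & rc %in% DNA_BASES)
    if (ident < 0.5) {
      stop("not homologous: ", which,
           " LTR aligns at identity ", round(ident, 3), " < 0.5")
    }
  }
  checkIdentity(a5, "5'")
  checkIdentity(a3, "3'")

  recs <- function(a) {
    r <- classifyMismatches(a)
    if (!is.null(mask)) {
      r <- r[!(r$refPos >= mask[1] & r$refPos <= mask[2]), , drop = FALSE]
    }
    r
  }
  r5 <- recs(a5); r3 <- recs(a3)
  k5 <- paste(r5$refPos, r5$klass)
  k3 <- paste(r3$refPos, r3$klass)
  # same reference implies same refBase at a position, so an equal
  # (refPos, class) key implies the same substituted base in both LTRs
  sharedKeys <- intersect(k5, k3)
  take <- function(r, keys, keep) {
    out <- r[if (keep) paste(r$refPos, r$klass) %in% keys
             else !(paste(r$refPos, r$klass) %in% keys), , drop = FALSE]
    out <- out[, c("refPos", "klass", "qryBase")]
    rownames(out) <- NULL
    out
  }
  shared <- take(r5, sharedKeys, TRUE)
  fiveSp <- take(r5, sharedKeys, FALSE)
  threeSp <- take(r3, sharedKeys, FALSE)
  methods::new("LTRComparison",
    shared = shared, fiveSpecific = fiveSp, threeSpecific = threeSp,
    threeSpecificGACount = sum(threeSp$klass == "G>A"),
    indelPositions = list(five = .indelRefPositions(a5),
                          three = .indelRefPositions(a3))
  )
}

#' Serialize an LTR comparison to JSON
#'
#' @param x an \linkS4class{LTRComparison}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLtrJson <- function(x, path) {
  asRecs <- function(d) {
    lapply(seq_len(nrow(d)), function(i) {
      list(ref_pos = d$refPos[i], class = as.character(d$klass[i]),
           qry_base = d$qryBase[i])
    })
  }
  out <- list(
    shared = asRecs(sharedSubs(x)),
    five_specific = asRecs(fiveSpecific(x)),
    three_specific = asRecs(threeSpecific(x)),
    three_specific_GA_count = threeSpecificGACount(x),
    indel_positions = indelPositions(x)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
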