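# Sliding-window substitution density track.

#' Sliding-window mutation counts
#'
#' Counts G>A, A>G, and C>T records in windows of `window` reference bases
#' advanced by `step` (defaults 400/100, the construction used for
#' genome-wide hypermutation gradient plots). Window starts form the
#' arithmetic sequence 1, 1+step, ... and only full windows lying entirely
#' within `[1, alignedRefLength]` are emitted; a trailing partial window is
#' not.
#'
#' @param records mismatch records from [classifyMismatches()].
#' @param alignedRefLength length of the compared reference span.
#' @param window window width in bases (must not exceed
#'   `alignedRefLength`).
#' @param step step size in bases (>= 1).
#' @return a data frame with columns `start`, `end`, `GA`, `AG`, `CT`, with
#'   `window` and `step` recorded as attributes.
#' @export
windowCounts <- function(records, alignedRefLength, window = 400L,
                         step = 100L) {
  if (step < 1L) stop("step must be >= 1")
  if (window > alignedRefLength) {
    stop("window (", window, ") exceeds reference length (",
         alignedRefLength, ")")
  }
  starts <- seq.int(1L, alignedRefLength - window + 1L, by = step)
  countClass <- function(kl) {
    pos <- records$refPos[records$klass == kl]
    vapply(starts, function(s) sum(pos >= s & pos <= s + window - 1L), 0L)
  }
  out <- data.frame(
    start = starts,
    end = starts + window - 1L,
    GA = countClass("G>A"),
    AG = countClass("A>G"),
    CT = countClass("C>T")
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  out
}

#' Write a window track as TSV
#'
#' @param track a track from [windowCounts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackTsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
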