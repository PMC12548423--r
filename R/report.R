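# Summary-table assembly and comparison against expected (published-style)
# tables.

#' Assemble a summary row from a profile
#'
#' Derived fields are recomputed from the counts (never trusted from
#' input). Display values are rounded half-up at `decimals` decimal places;
#' full-precision values are retained alongside in `*Full` columns.
#'
#' @param profile a \linkS4class{MismatchProfile}.
#' @param name row label.
#' @param decimals display decimals for the percent column (1, or 2 where
#'   the expected table prints 2).
#' @return a one-row data frame: `name`, `length`, `pctG`, `pctA`, `GA`,
#'   `CT`, `AG`, `total`, `pctGA`, `pctGAFull`, `GAperKb`, `GAperKbFull`,
#'   `runs` (formatted `len:count` pairs).
#' @export
makeRow <- function(profile, name, decimals = 1L) {
  cts <- mismatchCounts(profile)
  total <- sum(cts)
  len <- alignedRefLength(profile)
  pctFull <- if (total > 0) 100 * cts[["G>A"]] / total else NA_real_
  kbFull <- 1000 * cts[["G>A"]] / len
  rh <- runHistogram(profile)
  data.frame(
    name = name,
    length = len,
    pctG = roundHalfUp(profile@pctG, 1),
    pctA = roundHalfUp(profile@pctA, 1),
    GA = cts[["G>A"]], CT = cts[["C>T"]], AG = cts[["A>G"]],
    total = total,
    pctGA = roundHalfUp(pctFull, decimals),
    pctGAFull = pctFull,
    GAperKb = roundHalfUp(kbFull, 1),
    GAperKbFull = kbFull,
    runs = if (length(rh)) {
      paste(names(rh), rh, sep = ":", collapse = ";")
    } else "",
    stringsAsFactors = FALSE
  )
}

#' Build a summary row directly from counts
#'
#' For checking the arithmetic of an already-printed table: reconstructs the
#' derived cells (percent G>A of mismatches, G>A per 1,000 bp) from raw
#' counts and length.
#'
#' @param name row label.
#' @param GA,total G>A count and total mismatch count.
#' @param length reference span in bases.
#' @param decimals display decimals for the percent cell.
#' @return a one-row data frame as in [makeRow()] (composition and runs
#'   empty).
#' @export
rowFromCounts <- function(name, GA, total, length, decimals = 1L) {
  pctFull <- if (total > 0) 100 * GA / total else NA_real_
  kbFull <- 1000 * GA / length
  data.frame(
    name = name, length = length,
    pctG = NA_real_, pctA = NA_real_,
    GA = GA, CT = NA_integer_, AG = NA_integer_, total = total,
    pctGA = roundHalfUp(pctFull, decimals), pctGAFull = pctFull,
    GAperKb = roundHalfUp(kbFull, 1), GAperKbFull = kbFull,
    runs = "", stringsAsFactors = FALSE
  )
}

#' Read an expected summary table
#'
#' TSV fixtures with a `#` provenance header. Required columns: `name`,
#' `length`, `GA`, `total`, `printedPct`, `decPct`, `printedPerKb`,
#' `decPerKb`, `inconsPct`, `inconsPerKb`. `NA` in a printed cell means the
#' source table does not print that cell; `incons*` flags mark cells known
#' to disagree with their own row's counts (kept, flagged, never silently
#' absorbed).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
readExpectedTable <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Compare recomputed rows against an expected table
#'
#' Per-cell comparison at the printed precision: tolerance defaults to half
#' a unit in the last printed decimal place (0.05 for 1-decimal cells,
#' 0.005 for 2-decimal, 0.5 for integer cells). Cells flagged
#' `known_inconsistent` in the expected table are reported with
#' `flagged = TRUE` and excluded from the overall pass verdict; rows missing
#' on either side are listed, not fatal.
#'
#' @param rows data frame of recomputed rows ([makeRow()] /
#'   [rowFromCounts()] format, rbind-ed).
#' @param expected expected table ([readExpectedTable()] format).
#' @param tolerance optional fixed absolute tolerance overriding the
#'   per-precision default.
#' @return list with `cells` (data frame: `name`, `cell`, `recomputed`,
#'   `printed`, `tol`, `pass`, `flagged`), `missing` (row names absent from
#'   `rows`), and `ok` (all unflagged cells pass).
#' @export
checkAgainstExpected <- function(rows, expected, tolerance = NULL) {
  cells <- list()
  missing <- character(0)
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    j <- match(e$name, rows$name)
    if (is.na(j)) {
      missing <- c(missing, e$name)
      next
    }
    r <- rows[j, ]
    addCell <- function(cellName, recomputed, printed, dec, flagged) {
      if (is.na(printed)) return(NULL)
      tol <- if (!is.null(tolerance)) tolerance else 0.5 * 10^(-dec)
      data.frame(
        name = e$name, cell = cellName,
        recomputed = recomputed, printed = printed, tol = tol,
        pass = !is.na(recomputed) && abs(recomputed - printed) <= tol,
        flagged = isTRUE(flagged), stringsAsFactors = FALSE
      )
    }
    cells[[length(cells) + 1L]] <-
      addCell("pctGA", r$pctGAFull, e$printedPct, e$decPct, e$inconsPct)
    cells[[length(cells) + 1L]] <-
      addCell("GAperKb", r$GAperKbFull, e$printedPerKb, e$decPerKb,
              e$inconsPerKb)
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells)) {
    cells <- data.frame(name = character(0), cell = character(0),
                        recomputed = numeric(0), printed = numeric(0),
                        tol = numeric(0), pass = logical(0),
                        flagged = logical(0))
  }
  list(cells = cells, missing = missing,
       ok = all(cells$pass[!cells$flagged]))
}

#' Render summary rows as a Markdown table
#'
#' @param rows summary rows ([makeRow()] format). `NA` percent cells render
#'   as `-` (the no-call convention).
#' @return character vector of Markdown lines.
#' @export
renderMarkdown <- function(rows) {
  hdr <- c("name", "length", "GA", "CT", "AG", "total", "pctGA", "GAperKb")
  fmt <- function(x) {
    ifelse(is.na(x), "-", as.character(x))
  }
  lines <- c(
    paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|")
  )
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lines <- c(lines, paste0(
      "| ", paste(fmt(c(r$name, r$length, r$GA, r$CT, r$AG, r$total,
                        r$pctGA, r$GAperKb)), collapse = " | "), " |"
    ))
  }
  lines
}
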