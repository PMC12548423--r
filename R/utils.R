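# Shared constants and small helpers.

# The 12 substitution classes, reference base > query base. G>A, C>T and A>G
# lead because they are the diagnostic classes for strand-specific deaminase
# editing; the remainder follow in a fixed documented order.
MISMATCH_CLASSES <- c(
  "G>A", "C>T", "A>G", "T>C",
  "G>T", "G>C", "C>A", "C>G",
  "A>C", "A>T", "T>A", "T>G"
)

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

.compChars <- function(x) unname(.COMP[x])

.revcomp <- function(s) {
  paste(rev(.compChars(strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# round half away from zero at `digits` decimals (presentation rounding;
# base::round() rounds half to even, which does not reproduce printed tables)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Coerce the various sequence inputs (DNAStringSet element, DNAString,
# named/unnamed character) into list(id=, seq=) with an uppercase sequence.
.asSeq <- function(x, default_id = "seq") {
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence, got ", length(x))
    id <- if (is.null(names(x))) default_id else names(x)[1L]
    return(list(id = id, seq = toupper(as.character(x[[1L]]))))
  }
  if (methods::is(x, "XString")) {
    return(list(id = default_id, seq = toupper(as.character(x))))
  }
  if (is.character(x) && length(x) == 1L) {
    id <- if (is.null(names(x)) || !nzchar(names(x))) default_id else names(x)
    return(list(id = unname(id), seq = toupper(unname(x))))
  }
  stop("cannot interpret input of class '", class(x)[1L], "' as a sequence")
}

# Coerce a collection of sequences to a named uppercase character vector.
.asSeqs <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- toupper(as.character(x))
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("expected a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("all sequences must be named")
  }
  out
}

.emptyMismatchFrame <- function() {
  data.frame(
    refPos = integer(0), refBase = character(0), qryBase = character(0),
    klass = factor(character(0), levels = MISMATCH_CLASSES),
    stringsAsFactors = FALSE
  )
}

.usageError <- function(...) {
  stop(structure(
    class = c("hypermut_usage_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
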