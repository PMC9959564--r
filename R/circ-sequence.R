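#' Circular RNA sequence
#'
#' Construct an immutable circular nucleotide sequence. Indexing is 1-based
#' and modular: position `N + 1` is position 1 again. The alphabet is
#' strictly A/C/G/U after normalization (`T` is read as `U`, case is
#' folded).
#'
#' @param x A character scalar (e.g. `"GGGAAACCC"`) or character vector of
#'   single bases.
#' @param name Optional sequence name.
#' @param cap Maximum allowed length (default 500 nt).
#' @return An object of class `circ_sequence` with elements `bases`
#'   (character vector), `codes` (integer codes A=1, C=2, G=3, U=4), `n`
#'   (length) and `name`.
#' @examples
#' circ_sequence("ggGAAAccc")
#' @export
circ_sequence <- function(x, name = "circRNA", cap = 500L) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  if (!is.character(x) || length(x) < 1L)
    stop("sequence must be a non-empty character string", call. = FALSE)
  b <- toupper(x)
  b[b == "T"] <- "U"
  bad <- which(!b %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at sequence position %d",
                 x[bad[1L]], bad[1L]), call. = FALSE)
  n <- length(b)
  if (n > cap)
    stop(sprintf("sequence length %d exceeds the maximum of %d nt", n, cap),
         call. = FALSE)
  structure(list(bases = b,
                 codes = match(b, c("A", "C", "G", "U")),
                 n = n, name = name),
            class = "circ_sequence")
}

#' Parse a circular RNA sequence from text
#'
#' Accepts plain text or a single-record FASTA. Whitespace and digits are
#' stripped, `T` is converted to `U` and case is folded; any other
#' character is an error naming its position. Exactly one sequence is
#' accepted per job.
#'
#' @param raw Character: the raw input text (may contain newlines), or a
#'   character vector of lines.
#' @param cap Maximum sequence length (default 500 nt).
#' @return A [circ_sequence()] object.
#' @examples
#' parse_sequence("acgu\nACGT")
#' @export
parse_sequence <- function(raw, cap = 500L) {
  if (!is.character(raw) || length(raw) < 1L || all(!nzchar(raw)))
    stop("empty sequence input", call. = FALSE)
  lines <- unlist(strsplit(paste(raw, collapse = "\n"), "\n"))
  name <- "circRNA"
  headers <- grepl("^>", lines)
  if (any(headers)) {
    if (sum(headers) > 1L)
      stop("multiple FASTA records found; provide exactly one circular sequence per job",
           call. = FALSE)
    if (!headers[1L])
      stop("malformed FASTA: header is not the first line", call. = FALSE)
    name <- sub("^>\\s*", "", lines[1L])
    if (!nzchar(name)) name <- "circRNA"
    lines <- lines[-1L]
  }
  body <- paste(lines, collapse = "")
  body <- gsub("[0-9[:space:]]", "", body)
  if (!nzchar(body)) stop("no sequence characters found", call. = FALSE)
  circ_sequence(body, name = name, cap = cap)
}

#' @export
print.circ_sequence <- function(x, ...) {
  cat(sprintf("Circular RNA sequence '%s' (%d nt)\n", x$name, x$n))
  s <- paste(x$bases, collapse = "")
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' @export
as.character.circ_sequence <- function(x, ...) paste(x$bases, collapse = "")

#' @export
length.circ_sequence <- function(x) x$n

#' Rotate a circular sequence
#'
#' Returns the sequence renumbered so that old position `s + 1` becomes
#' position 1. Any consecutive numbering of a circle is equivalent; this
#' helper exposes that relabeling (used heavily in rotational-invariance
#' checks).
#'
#' @param seq A [circ_sequence()].
#' @param s Integer shift (0 leaves the numbering untouched).
#' @return The rotated `circ_sequence`.
#' @export
rotate_sequence <- function(seq, s) {
  stopifnot(inherits(seq, "circ_sequence"))
  s <- ((s %% seq$n) + seq$n) %% seq$n
  if (s == 0) return(seq)
  idx <- c((s + 1):seq$n, 1:s)
  circ_sequence(seq$bases[idx], name = seq$name, cap = seq$n)
}

# modular position helper: map any integer to 1..n
.cpos <- function(p, n) ((p - 1L) %% n) + 1L

# canonical pair test on base codes (A=1,C=2,G=3,U=4)
.canonical_code <- function(x, y) {
  (x == 1L & y == 4L) | (x == 4L & y == 1L) |
  (x == 3L & y == 2L) | (x == 2L & y == 3L) |
  (x == 3L & y == 4L) | (x == 4L & y == 3L)
}
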