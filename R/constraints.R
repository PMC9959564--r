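# User structural constraints: forcing base pairs (HELIX i j k) and
# forcing unpaired stretches (LOOP i k), in the grammar printed by the
# server interface this package reimplements. Coordinates are 1-based on
# the circle; k counts base pairs for HELIX and unpaired nucleotides for
# LOOP.

#' Build a structural constraint
#'
#' @param kind `"forced_helix"` or `"forced_loop"`.
#' @param i 1-based start position (5' base of the first forced pair for a
#'   helix; first unpaired nucleotide for a loop).
#' @param j 1-based position of the 3' base of the first forced pair
#'   (helix only).
#' @param k Length: base pairs (helix) or unpaired nucleotides (loop).
#' @return A `circfold_constraint`.
#' @export
constraint <- function(kind = c("forced_helix", "forced_loop"), i, j = NULL,
                       k) {
  kind <- match.arg(kind)
  i <- as.integer(i); k <- as.integer(k)
  if (kind == "forced_helix") {
    j <- as.integer(j)
    if (anyNA(c(i, j, k)) || i < 1L || j < 1L || k < 1L)
      stop("HELIX constraint needs positive integers i, j, k", call. = FALSE)
  } else {
    if (anyNA(c(i, k)) || i < 1L || k < 1L)
      stop("LOOP constraint needs positive integers i, k", call. = FALSE)
    j <- NULL
  }
  structure(list(kind = kind, i = i, j = j, k = k),
            class = "circfold_constraint")
}

#' Parse constraint strings
#'
#' Accepts the textual grammar `"HELIX i j k"` (force the k base pairs
#' `(i+m, j-m)`) and `"LOOP i k"` (force positions `i..i+k-1` unpaired).
#'
#' @param x Character vector of constraint strings.
#' @return A list of [constraint()] objects.
#' @examples
#' parse_constraints(c("HELIX 1 12 4", "LOOP 5 3"))
#' @export
parse_constraints <- function(x) {
  lapply(x, function(s) {
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    if (length(toks) == 4L && toupper(toks[1]) == "HELIX")
      return(constraint("forced_helix", toks[2], toks[3], k = toks[4]))
    if (length(toks) == 3L && toupper(toks[1]) == "LOOP")
      return(constraint("forced_loop", toks[2], k = toks[3]))
    stop(sprintf("cannot parse constraint '%s' (expected 'HELIX i j k' or 'LOOP i k')",
                 s), call. = FALSE)
  })
}

#' @export
print.circfold_constraint <- function(x, ...) {
  cat(.constraint_label(x), "\n")
  invisible(x)
}

.constraint_label <- function(cn) {
  if (cn$kind == "forced_helix") sprintf("HELIX %d %d %d", cn$i, cn$j, cn$k)
  else sprintf("LOOP %d %d", cn$i, cn$k)
}

# positions claimed by a constraint, on the circle
.constraint_positions <- function(cn, n) {
  if (cn$kind == "forced_helix") as.vector(helix_pairs(helix(cn$i, cn$j, cn$k), n))
  else .cpos(cn$i + seq_len(cn$k) - 1L, n)
}

#' Validate a constraint set against a sequence
#'
#' Checks that every forced base pair is canonical (A-U, G-C, G-U), that
#' all indices are within `(1, N)`, that no nucleotide is claimed by two
#' constraints, and that no two forced helices cross on the circle. Each
#' violation raises a distinct error; improper constraint sets never fold
#' silently to an empty prediction.
#'
#' @param constraints List of [constraint()] objects (or strings, which are
#'   parsed first).
#' @param seq A [circ_sequence()].
#' @return The validated constraint list (invisibly classed
#'   `circfold_constraints`).
#' @export
validate_constraints <- function(constraints, seq) {
  stopifnot(inherits(seq, "circ_sequence"))
  if (is.character(constraints)) constraints <- parse_constraints(constraints)
  if (length(constraints) == 0L)
    return(structure(list(), class = "circfold_constraints"))
  n <- seq$n
  for (cn in constraints) {
    if (!inherits(cn, "circfold_constraint"))
      stop("constraints must be built with constraint() or parse_constraints()",
           call. = FALSE)
    if (cn$i > n || (!is.null(cn$j) && cn$j > n))
      stop(sprintf("%s: position out of range for a %d-nt circle",
                   .constraint_label(cn), n), call. = FALSE)
    if (cn$kind == "forced_helix") {
      if (2L * cn$k > n)
        stop(sprintf("%s: helix longer than the circle allows",
                     .constraint_label(cn), n), call. = FALSE)
      pr <- helix_pairs(helix(cn$i, cn$j, cn$k), n)
      if (anyDuplicated(as.vector(pr)) > 0L)
        stop(sprintf("%s: helix overlaps itself", .constraint_label(cn)),
             call. = FALSE)
      for (r in seq_len(nrow(pr)))
        if (!.canonical_code(seq$codes[pr[r, 1]], seq$codes[pr[r, 2]]))
          stop(sprintf("%s: forced pair (%d, %d) is %s-%s, not canonical (A-U, G-C, G-U)",
                       .constraint_label(cn), pr[r, 1], pr[r, 2],
                       seq$bases[pr[r, 1]], seq$bases[pr[r, 2]]),
               call. = FALSE)
    } else {
      if (cn$k > n)
        stop(sprintf("%s: loop longer than the circle",
                     .constraint_label(cn)), call. = FALSE)
    }
  }
  # pairwise: shared nucleotides and crossing forced helices
  m <- length(constraints)
  if (m > 1L) for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    ca <- constraints[[a]]; cb <- constraints[[b]]
    shared <- intersect(.constraint_positions(ca, n),
                        .constraint_positions(cb, n))
    if (length(shared) > 0L)
      stop(sprintf("constraints %s and %s both claim position %d",
                   .constraint_label(ca), .constraint_label(cb), shared[1]),
           call. = FALSE)
    if (ca$kind == "forced_helix" && cb$kind == "forced_helix" &&
        !helices_compatible(helix(ca$i, ca$j, ca$k),
                            helix(cb$i, cb$j, cb$k), n))
      stop(sprintf("forced helices %s and %s cross on the circle",
                   .constraint_label(ca), .constraint_label(cb)),
           call. = FALSE)
  }
  structure(constraints, class = "circfold_constraints")
}
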