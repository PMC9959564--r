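# Deterministic toy-sequence generation with known planted helices, for
# constraint and recovery testing. All randomness is seeded locally and
# the global RNG state is left untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an annotated test circle
#'
#' Builds deterministic circular sequences with known planted helices:
#'
#' * `hairpin_circle`: one GC stem of `floor((N-8)/2)` pairs with two
#'   flanking loops (for `N = 16` this is `GGGGAAAACCCCAAAA` with planted
#'   helix `(1, 12, 4)`). The planted stem is the only stable helix by
#'   construction; it dominates the landscape once the stem is long
#'   enough for its stacks to outweigh the two loop penalties (N of
#'   roughly 22 and up).
#' * `two_helix`: two mutually compatible GC stems side by side on the
#'   circle (requires `N >= 22`).
#' * `random`: a seeded uniform A/C/G/U sequence.
#'
#' @param kind `"hairpin_circle"`, `"two_helix"` or `"random"`.
#' @param n Circle length.
#' @param seed Integer seed (`random` only; the constructed kinds are
#'   seed-independent).
#' @return A [circ_sequence()]; constructed kinds carry the planted
#'   [helix()] list as attribute `"annotation"`.
#' @examples
#' generate_fixture("hairpin_circle", 16)
#' @export
generate_fixture <- function(kind = c("hairpin_circle", "two_helix",
                                      "random"), n, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (kind == "random") {
    b <- .with_seed(seed, sample(c("A", "C", "G", "U"), n, replace = TRUE))
    return(circ_sequence(b, name = sprintf("random_%d_seed%d", n, seed)))
  }
  if (kind == "hairpin_circle") {
    if (n < 12L) stop("hairpin_circle needs N >= 12", call. = FALSE)
    k <- (n - 8L) %/% 2L
    inner <- n - 2L * k - 4L
    b <- c(rep("G", k), rep("A", inner), rep("C", k), rep("A", 4L))
    seq <- circ_sequence(b, name = sprintf("hairpin_circle_%d", n))
    attr(seq, "annotation") <- list(helix(1L, 2L * k + inner, k))
    return(seq)
  }
  # two_helix
  if (n < 23L) stop("two_helix needs N >= 23", call. = FALSE)
  k <- max(2L, (n - 15L) %/% 4L)
  rest <- n - (4L * k + 15L)
  if (rest < 0L) { k <- k - 1L; rest <- n - (4L * k + 15L) }
  b <- c(rep("G", k), rep("A", 4L), rep("C", k),      # stem 1
         rep("A", 3L),
         rep("G", k), rep("A", 4L), rep("C", k),      # stem 2
         rep("A", 4L + rest))
  seq <- circ_sequence(b, name = sprintf("two_helix_%d", n))
  p2 <- 2L * k + 8L
  attr(seq, "annotation") <- list(helix(1L, 2L * k + 4L, k),
                                  helix(p2, p2 + 2L * k + 3L, k))
  return(seq)
}
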