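# Saturated-helix enumeration, ranking and compatibility on the circle.
#
# A helix (i, j, k) is the run of k stacked canonical pairs
# (i+m, j-m) mod N, m = 0..k-1. It is saturated when it cannot be extended
# on either side: the flanking candidate pair is noncanonical, or
# extension would shrink a flanking loop below the 3-nt steric minimum or
# make the helix overlap itself. A helix and its strand-flipped
# description denote the same chord set; the lexicographically smaller
# (i, j) representation is the canonical one.

#' Helix triple
#'
#' @param i 1-based position of the first pair's 5' base.
#' @param j 1-based position of the first pair's 3' base.
#' @param k Number of consecutive canonical pairs.
#' @return A `circfold_helix`.
#' @export
helix <- function(i, j, k) {
  i <- as.integer(i); j <- as.integer(j); k <- as.integer(k)
  if (anyNA(c(i, j, k)) || i < 1L || j < 1L || k < 1L)
    stop("helix (i, j, k) must be positive integers", call. = FALSE)
  structure(list(i = i, j = j, k = k), class = "circfold_helix")
}

.as_helix <- function(h) {
  if (inherits(h, "circfold_helix")) return(h)
  if (is.numeric(h) && length(h) == 3L) return(helix(h[1], h[2], h[3]))
  stop("expected a helix (i, j, k)", call. = FALSE)
}

#' @export
print.circfold_helix <- function(x, ...) {
  g <- attr(x, "dG")
  cat(sprintf("helix (%d, %d, %d)%s\n", x$i, x$j, x$k,
              if (is.null(g)) "" else sprintf("  dG = %.2f kcal/mol", g)))
  invisible(x)
}

#' Base pairs of a helix on a circle of length N
#'
#' @param h A [helix()].
#' @param n Circle length.
#' @return A `k x 2` integer matrix of 1-based circle positions, each row
#'   ordered `(min, max)`.
#' @export
helix_pairs <- function(h, n) {
  h <- .as_helix(h)
  m <- seq_len(h$k) - 1L
  p <- .cpos(h$i + m, n)
  q <- .cpos(h$j - m, n)
  cbind(pmin(p, q), pmax(p, q))
}

# unpaired gaps flanking a pair on the circle (arc i->j is "inner")
.gap_in <- function(i, j, n) ((j - i - 1L) %% n)
.gap_out <- function(i, j, n) ((i - j - 1L) %% n)

#' Enumerate saturated helices on a circular sequence
#'
#' Scans the modular pair matrix for maximal runs of stacked canonical
#' pairs. Runs are trimmed so that both flanking loops keep at least 3
#' unpaired nt where they would close a hairpin, and so that the helix
#' never claims a position twice. Each physical helix is reported once, in
#' its lexicographically smallest `(i, j)` description.
#'
#' @param seq A [circ_sequence()].
#' @param min_helix_len Minimum number of pairs to report (default 2: a
#'   lone pair has no stack and cannot be ranked by stacking stability).
#' @return A list of [helix()] objects, ordered by `(i, j, k)`.
#' @examples
#' enumerate_saturated_helices(circ_sequence("GGGGAAAACCCCAAAA"))
#' @export
enumerate_saturated_helices <- function(seq, min_helix_len = 2L) {
  stopifnot(inherits(seq, "circ_sequence"))
  if (min_helix_len < 1L) stop("min_helix_len must be >= 1", call. = FALSE)
  n <- seq$n
  codes <- seq$codes
  canon <- function(p, q) .canonical_code(codes[p], codes[q])
  seen <- new.env(hash = TRUE)
  out <- list()
  for (i0 in seq_len(n)) for (j0 in seq_len(n)) {
    if (i0 == j0 || !canon(i0, j0)) next
    # chain start: predecessor pair (i0-1, j0+1) must not continue the run
    pi <- .cpos(i0 - 1L, n); pj <- .cpos(j0 + 1L, n)
    if (pi != j0 && pj != i0 && pi != pj && canon(pi, pj)) next
    # walk inward while canonical and positions stay distinct
    used <- c(i0, j0)
    run_i <- i0; run_j <- j0
    repeat {
      ni <- .cpos(run_i[length(run_i)] + 1L, n)
      nj <- .cpos(run_j[length(run_j)] - 1L, n)
      if (ni %in% used || nj %in% used || ni == nj || !canon(ni, nj)) break
      run_i <- c(run_i, ni); run_j <- c(run_j, nj)
      used <- c(used, ni, nj)
    }
    k <- length(run_i)
    # trim the outer end until the outer loop keeps >= 3 nt
    first <- 1L
    while (first <= k && .gap_out(run_i[first], run_j[first], n) < 3L)
      first <- first + 1L
    # trim the inner end until the inner loop keeps >= 3 nt
    last <- k
    while (last >= first && .gap_in(run_i[last], run_j[last], n) < 3L)
      last <- last - 1L
    kk <- last - first + 1L
    if (kk < min_helix_len || kk < 1L) next
    hi <- run_i[first]; hj <- run_j[first]
    # canonical description: compare with the strand-flipped form
    fi <- run_j[last]; fj <- run_i[last]
    if (fi < hi || (fi == hi && fj < hj)) { tmp <- hi; hi <- fi; hj <- fj }
    key <- paste(hi, hj, kk, sep = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- helix(hi, hj, kk)
  }
  ord <- order(vapply(out, `[[`, 1L, "i"),
               vapply(out, `[[`, 1L, "j"),
               vapply(out, `[[`, 1L, "k"))
  out[ord]
}

#' Rank helices by free energy
#'
#' Orders helices ascending by their stacking free energy (most stable
#' first); ties break deterministically by `(i, j, k)`. Helices with
#' non-negative free energy are dropped from the stable pool.
#'
#' @param helices List of [helix()] objects (typically from
#'   [enumerate_saturated_helices()]).
#' @param seq A [circ_sequence()].
#' @param model A [load_parameters()] energy model.
#' @return The ranked list; each helix carries its `dG` as an attribute.
#' @export
rank_helices <- function(helices, seq, model) {
  if (length(helices) == 0L) return(list())
  g <- vapply(helices, function(h) helix_free_energy(model, h, seq),
              numeric(1))
  keep <- g < 0
  helices <- helices[keep]; g <- g[keep]
  if (length(helices) == 0L) return(list())
  ord <- order(g,
               vapply(helices, `[[`, 1L, "i"),
               vapply(helices, `[[`, 1L, "j"),
               vapply(helices, `[[`, 1L, "k"))
  helices <- helices[ord]; g <- g[ord]
  for (t in seq_along(helices)) attr(helices[[t]], "dG") <- g[t]
  helices
}

#' Serialize helices to a table
#'
#' @param helices List of helices (ranked or not).
#' @param seq,model Optional; if given, a `dG` column is computed.
#' @return A data.frame with columns `i`, `j`, `k` (and `dG`).
#' @export
helix_table <- function(helices, seq = NULL, model = NULL) {
  df <- data.frame(i = vapply(helices, `[[`, 1L, "i"),
                   j = vapply(helices, `[[`, 1L, "j"),
                   k = vapply(helices, `[[`, 1L, "k"))
  if (!is.null(seq) && !is.null(model))
    df$dG <- vapply(helices, function(h) helix_free_energy(model, h, seq),
                    numeric(1))
  else {
    g <- lapply(helices, attr, "dG")
    if (length(g) > 0L && !any(vapply(g, is.null, logical(1))))
      df$dG <- unlist(g)
  }
  df
}

# do chords {a1,b1} and {a2,b2} cross on a circle of length n?
.chords_cross <- function(a1, b1, a2, b2, n) {
  arc <- (b1 - a1) %% n
  t1 <- (a2 - a1) %% n
  t2 <- (b2 - a1) %% n
  in1 <- t1 > 0 & t1 < arc
  in2 <- t2 > 0 & t2 < arc
  xor(in1, in2)
}

#' Are two helices compatible?
#'
#' Helices are incompatible when they overlap (share a nucleotide) or
#' cross (any chord of one interleaves with any chord of the other around
#' the circle). The test is performed on the circle, so origin-spanning
#' helices are handled correctly.
#'
#' @param h1,h2 [helix()] objects.
#' @param n Circle length.
#' @return `TRUE` when the helices can coexist in one structure.
#' @export
helices_compatible <- function(h1, h2, n) {
  p1 <- helix_pairs(.as_helix(h1), n)
  p2 <- helix_pairs(.as_helix(h2), n)
  if (length(intersect(as.vector(p1), as.vector(p2))) > 0L) return(FALSE)
  for (r in seq_len(nrow(p1))) for (t in seq_len(nrow(p2)))
    if (.chords_cross(p1[r, 1], p1[r, 2], p2[t, 1], p2[t, 2], n))
      return(FALSE)
  TRUE
}
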