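#' Predict circular RNA secondary structures and folding stabilities
#'
#' The main entry point. For a circular RNA sequence the folding landscape
#' is partitioned through its top-stable saturated helices: helices are
#' enumerated on the circle, ranked by stacking free energy, and added to
#' a pool (most stable first) until the inclusion/exclusion signatures
#' over the pool reach the requested number of partitions. For each
#' partition the conditional partition function of the circle is computed
#' over the two-linear-fragment decomposition, the closing pair minimizing
#' `-kB T ln Q` is selected, and the partition's MFE structure is
#' recovered by backtracking. Results are deduplicated and ranked by free
#' energy; any two reported structures differ in the inclusion of at
#' least one pool helix.
#'
#' @param x Sequence input: a [circ_sequence()], a raw sequence string, or
#'   FASTA text (single record). `T` is read as `U`.
#' @param temperature Folding temperature in degrees Celsius (default 37).
#' @param max_structures Maximum number of predicted structures
#'   (default 5).
#' @param constraints Optional constraints: character vector in the
#'   `"HELIX i j k"` / `"LOOP i k"` grammar, or a list from
#'   [parse_constraints()]. Forced helices are injected as permanently
#'   included; contradictory or crossing constraints raise an error.
#' @param parameters Energy parameter set: built-in tag `"turner2004"` or
#'   a file path (see [load_parameters()]).
#' @param max_length Sequence length cap (default 500 nt).
#' @param control A [fold_control()].
#' @return An object of class `circfold`: the ranked structures with free
#'   energies (kcal/mol), the helix pool, the landscape signatures, and
#'   the sequence. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @examples
#' fit <- circfold("GGGGGGAAAACCCCCCAAAAGGGGAAAACCCCAA", max_structures = 3)
#' fit
#' as.data.frame(fit)
#' @export
circfold <- function(x, temperature = 37, max_structures = 5L,
                     constraints = NULL, parameters = "turner2004",
                     max_length = 500L, control = fold_control()) {
  seq <- if (inherits(x, "circ_sequence")) x
         else parse_sequence(x, cap = max_length)
  if (max_structures < 1L) stop("max_structures must be >= 1", call. = FALSE)
  model <- load_parameters(parameters, temperature)
  cons <- validate_constraints(if (is.null(constraints)) list()
                               else constraints, seq)
  n <- seq$n

  helices <- enumerate_saturated_helices(seq, control$min_helix_len)
  # helices conflicting with a constraint leave the pool; forced helices
  # are handled as permanent inclusions, not pool members
  if (length(cons) > 0L && length(helices) > 0L) {
    loop_pos <- unlist(lapply(Filter(function(cn) cn$kind == "forced_loop",
                                     cons), .constraint_positions, n = n))
    forced <- integer(n)            # forced partner per position, 0 = free
    for (cn in cons) {
      if (cn$kind != "forced_helix") next
      pr <- helix_pairs(helix(cn$i, cn$j, cn$k), n)
      forced[pr[, 1]] <- pr[, 2]
      forced[pr[, 2]] <- pr[, 1]
    }
    fhel <- Filter(function(cn) cn$kind == "forced_helix", cons)
    ok <- vapply(helices, function(h) {
      hp <- helix_pairs(h, n)
      if (length(intersect(as.vector(hp), loop_pos)) > 0L) return(FALSE)
      # pairing a forced position differently contradicts the constraint
      for (r in seq_len(nrow(hp))) {
        p <- hp[r, 1]; q <- hp[r, 2]
        if ((forced[p] != 0L && forced[p] != q) ||
            (forced[q] != 0L && forced[q] != p)) return(FALSE)
      }
      for (cn in fhel) {
        fh <- helix(cn$i, cn$j, cn$k)
        fp <- helix_pairs(fh, n)
        for (r in seq_len(nrow(hp))) for (t in seq_len(nrow(fp)))
          if (.chords_cross(hp[r, 1], hp[r, 2], fp[t, 1], fp[t, 2], n))
            return(FALSE)
      }
      TRUE
    }, logical(1))
    helices <- helices[ok]
  }
  ranked <- rank_helices(helices, seq, model)
  grown <- grow_pool_until(max_structures, ranked, n, control$pool_cap)

  results <- list()
  dropped <- 0L
  for (sig in grown$signatures) {
    r <- predict_partition_mfe(seq, sig, model, constraints = cons,
                               control = control, helices = helices)
    if (is.null(r)) { dropped <- dropped + 1L; next }
    results[[length(results) + 1L]] <- r
  }
  # deduplicate identical structures, keep first (signature order)
  keys <- vapply(results, function(r) dot_bracket(r$structure), character(1))
  results <- results[!duplicated(keys)]
  ord <- order(vapply(results, `[[`, numeric(1), "free_energy"))
  results <- results[ord]
  results <- utils::head(results, max_structures)

  structure(list(sequence = seq, model = model, constraints = cons,
                 helices = ranked, pool = grown$pool,
                 signatures = grown$signatures,
                 under_target = grown$under_target,
                 dropped_signatures = dropped,
                 results = results,
                 max_structures = as.integer(max_structures),
                 control = control, call = match.call()),
            class = "circfold")
}

#' @export
print.circfold <- function(x, ...) {
  cat(sprintf("Circular RNA folding: '%s', %d nt at %.1f C\n",
              x$sequence$name, x$sequence$n, x$model$temperature_celsius))
  if (length(x$constraints) > 0L)
    cat("  constraints:",
        paste(vapply(x$constraints, .constraint_label, character(1)),
              collapse = "; "), "\n")
  cat(sprintf("  %d structure(s) from %d landscape partition(s) over %d pool helices\n",
              length(x$results), length(x$signatures), length(x$pool)))
  s <- as.character(x$sequence)
  cat("\n  ", s, "\n", sep = "")
  for (r in seq_along(x$results)) {
    res <- x$results[[r]]
    cat(sprintf("%2d %s  %7.2f kcal/mol  %s\n", r,
                dot_bracket(res$structure), res$free_energy,
                signature_label(res$signature)))
  }
  if (any(vapply(x$results, function(r) origin_spanning(r$structure),
                 logical(1))))
    cat("  note: some helices span the sequence origin (circular pairing)\n")
  invisible(x)
}

#' @export
summary.circfold <- function(object, ...) {
  x <- object
  cat(sprintf("circfold prediction for '%s' (%d nt, %.1f C)\n",
              x$sequence$name, x$sequence$n, x$model$temperature_celsius))
  cat(sprintf("saturated helices ranked stable: %d; pool size: %d; signatures: %d%s\n",
              length(x$helices), length(x$pool), length(x$signatures),
              if (x$under_target) " (under requested target)" else ""))
  if (length(x$pool) > 0L) {
    cat("helix pool (most stable first):\n")
    tb <- helix_table(x$pool)
    for (r in seq_len(nrow(tb)))
      cat(sprintf("  h%d: (%d, %d, %d)  dG = %.2f kcal/mol\n", r, tb$i[r],
                  tb$j[r], tb$k[r], tb$dG[r]))
  }
  if (x$dropped_signatures > 0L)
    cat(sprintf("%d signature(s) had empty ensembles and were dropped\n",
                x$dropped_signatures))
  for (r in seq_along(x$results)) {
    res <- x$results[[r]]
    cat(sprintf("structure %d: G = %.2f kcal/mol (ensemble G = %.2f), %d pairs, %s\n",
                r, res$free_energy, res$ensemble_free_energy,
                nrow(res$structure$pairs), signature_label(res$signature)))
  }
  invisible(x)
}

#' @export
as.data.frame.circfold <- function(x, ...) {
  data.frame(
    rank = seq_along(x$results),
    free_energy = vapply(x$results, `[[`, numeric(1), "free_energy"),
    ensemble_free_energy = vapply(x$results, `[[`, numeric(1),
                                  "ensemble_free_energy"),
    n_pairs = vapply(x$results, function(r) nrow(r$structure$pairs),
                     integer(1)),
    dot_bracket = vapply(x$results, function(r) dot_bracket(r$structure),
                         character(1)),
    signature = vapply(x$results, function(r) signature_label(r$signature),
                       character(1)),
    stringsAsFactors = FALSE)
}

#' Arc-diagram plot of predicted structures
#'
#' Draws the circle as a horizontal axis with base pairs as arcs (base
#' graphics). Pairs through the origin are drawn like any other chord;
#' the circular topology means no pair is special.
#'
#' @param x A `circfold` fit.
#' @param rank Which structure to draw (default 1, the most stable).
#' @param ... Passed to `plot.default`.
#' @export
plot.circfold <- function(x, rank = 1L, ...) {
  if (length(x$results) == 0L) stop("no structures to plot", call. = FALSE)
  res <- x$results[[rank]]
  n <- x$sequence$n
  pr <- res$structure$pairs
  hmax <- if (nrow(pr) > 0L) max(pr[, 2] - pr[, 1]) / 2 else 1
  graphics::plot(NULL, xlim = c(1, n), ylim = c(-0.15 * hmax, hmax * 1.05),
                 xlab = "position (circular, 1..N)", ylab = "",
                 yaxt = "n", bty = "n",
                 main = sprintf("%s: structure %d, %.2f kcal/mol",
                                x$sequence$name, rank, res$free_energy), ...)
  graphics::segments(1, 0, n, 0)
  if (nrow(pr) > 0L) {
    th <- seq(0, pi, length.out = 60)
    for (r in seq_len(nrow(pr))) {
      cx <- (pr[r, 1] + pr[r, 2]) / 2
      rad <- (pr[r, 2] - pr[r, 1]) / 2
      graphics::lines(cx + rad * cos(th), rad * sin(th), col = "steelblue")
    }
  }
  invisible(x)
}
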