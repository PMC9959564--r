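# Landscape partitioning: inclusion/exclusion signatures over a pool of
# top-stable helices. A signature (+h1, -h2, ...) names the structural
# ensemble that contains every base pair of each included helix and no
# base pair of any excluded helix; included helices must be mutually
# compatible (no shared nucleotides, no crossing chords).

#' Enumerate inclusion/exclusion signatures over a helix pool
#'
#' All `2^|pool|` flag vectors are generated by binary counting with the
#' most stable helix (pool position 1) as the lowest bit, and those whose
#' included set is internally incompatible are deleted. The all-excluded
#' signature is always first.
#'
#' @param pool Ordered list of [helix()] objects (most stable first).
#' @param n Circle length.
#' @param cap Hard cap on the pool size (default 12, i.e. at most 4096
#'   signatures).
#' @return A list of `circfold_signature` objects, each with fields `pool`
#'   and logical `flags` (`TRUE` = included).
#' @export
enumerate_signatures <- function(pool, n, cap = 12L) {
  m <- length(pool)
  if (m > cap)
    stop(sprintf("helix pool of %d exceeds the cap of %d; request fewer structures",
                 m, cap), call. = FALSE)
  if (m == 0L)
    return(list(structure(list(pool = list(), flags = logical(0)),
                          class = "circfold_signature")))
  compat <- matrix(TRUE, m, m)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    ok <- helices_compatible(pool[[a]], pool[[b]], n)
    compat[a, b] <- ok; compat[b, a] <- ok
  }
  out <- list()
  for (code in 0:(2L^m - 1L)) {
    flags <- as.logical(bitwAnd(code, 2L^(seq_len(m) - 1L)))
    inc <- which(flags)
    ok <- TRUE
    if (length(inc) > 1L) {
      for (a in seq_along(inc)[-1L]) {
        if (!all(compat[inc[a], inc[seq_len(a - 1L)]])) { ok <- FALSE; break }
      }
    }
    if (ok)
      out[[length(out) + 1L]] <- structure(list(pool = pool, flags = flags),
                                           class = "circfold_signature")
  }
  out
}

#' @export
print.circfold_signature <- function(x, ...) {
  cat(signature_label(x), "\n")
  invisible(x)
}

#' Compact label of a signature, e.g. "+h1 -h2 +h3"
#'
#' @param sig A `circfold_signature`.
#' @return A character scalar ("(open landscape)" for an empty pool).
#' @export
signature_label <- function(sig) {
  if (length(sig$flags) == 0L) return("(open landscape)")
  paste(ifelse(sig$flags, "+", "-"), "h", seq_along(sig$flags),
        sep = "", collapse = " ")
}

#' Grow the helix pool until enough partitions exist
#'
#' Adds ranked helices from most to least stable, re-enumerating
#' signatures after each addition, and stops as soon as the signature
#' count reaches `target_count`, the ranked helices are exhausted, or the
#' pool cap is hit. Returning fewer signatures than requested is a valid
#' outcome and is flagged.
#'
#' @param target_count Requested number of partitions (>= 1).
#' @param ranked_helices Output of [rank_helices()].
#' @param n Circle length.
#' @param cap Pool size cap (default 12).
#' @return A list with `pool`, `signatures` and logical `under_target`.
#' @export
grow_pool_until <- function(target_count, ranked_helices, n, cap = 12L) {
  if (target_count < 1L) stop("target_count must be >= 1", call. = FALSE)
  pool <- list()
  sigs <- enumerate_signatures(pool, n, cap)
  idx <- 0L
  while (length(sigs) < target_count && idx < length(ranked_helices) &&
         length(pool) < cap) {
    idx <- idx + 1L
    pool[[length(pool) + 1L]] <- ranked_helices[[idx]]
    sigs <- enumerate_signatures(pool, n, cap)
  }
  list(pool = pool, signatures = sigs,
       under_target = length(sigs) < target_count)
}

# fold rules (hard constraints handed to the DP core) derived from a
# signature plus any user constraints; NULL when the combination is
# internally contradictory
.fold_rules <- function(n, include = list(), exclude = list(),
                        unpaired = integer(0), forbidden = NULL) {
  partner <- integer(n)
  for (h in include) {
    pr <- helix_pairs(h, n)
    for (r in seq_len(nrow(pr))) {
      p <- pr[r, 1]; q <- pr[r, 2]
      if ((partner[p] != 0L && partner[p] != q) ||
          (partner[q] != 0L && partner[q] != p)) return(NULL)
      partner[p] <- q; partner[q] <- p
    }
  }
  unpair <- integer(n)
  if (length(unpaired) > 0L) {
    if (any(partner[unpaired] != 0L)) return(NULL)
    unpair[unpaired] <- 1L
  }
  forb <- matrix(integer(0), 0, 2)
  for (h in exclude) forb <- rbind(forb, helix_pairs(h, n))
  if (!is.null(forbidden) && nrow(forbidden) > 0L)
    forb <- rbind(forb, forbidden)
  # a forced pair that is also forbidden is a contradiction
  if (nrow(forb) > 0L)
    for (r in seq_len(nrow(forb)))
      if (partner[forb[r, 1]] == forb[r, 2]) return(NULL)
  list(partner = partner, unpair = unpair,
       forbidden = matrix(as.integer(forb), ncol = 2))
}

.rules_from_signature <- function(sig, n, constraints = NULL) {
  include <- sig$pool[sig$flags]
  exclude <- sig$pool[!sig$flags]
  unpaired <- integer(0)
  if (!is.null(constraints)) {
    for (cn in constraints) {
      if (cn$kind == "forced_helix")
        include <- c(include, list(helix(cn$i, cn$j, cn$k)))
      else
        unpaired <- c(unpaired, .cpos(cn$i + seq_len(cn$k) - 1L, n))
    }
  }
  .fold_rules(n, include = include, exclude = exclude, unpaired = unpaired)
}
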