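# Independent brute-force oracles used across the suite. These
# deliberately share no algorithmic code with the package internals: the
# helix oracle scans all (i, j, k) triples against the saturation
# definition, and the bitmask oracle filters every subset of the canonical
# pair list.

.canon_chr <- function(x, y)
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")

.modpos <- function(p, n) ((p - 1) %% n) + 1

# dumb quadratic helix oracle: a helix (i, j, k) is valid when all its
# pairs are canonical, its 2k positions are distinct and both flanking
# gaps keep >= 3 nt; it is saturated when neither one-pair extension is
# itself part of a valid helix of k + 1 pairs
brute_saturated_helices <- function(seq, min_len = 2) {
  n <- seq$n
  b <- seq$bases
  valid <- function(i, j, k) {
    if (k < 1 || 2 * k > n) return(FALSE)
    ps <- .modpos(i + 0:(k - 1), n)
    qs <- .modpos(j - 0:(k - 1), n)
    if (anyDuplicated(c(ps, qs)) > 0) return(FALSE)
    if (!all(.canon_chr(b[ps], b[qs]))) return(FALSE)
    gin <- (j - k + 1 - (i + k - 1) - 1) %% n
    gout <- (i - j - 1) %% n
    gin >= 3 && gout >= 3
  }
  out <- list()
  seen <- character(0)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    for (k in 1:(n %/% 2)) {
      if (!valid(i, j, k)) next
      if (valid(i - 1, j + 1, k + 1)) next   # extensible outward
      if (valid(i, j, k + 1)) next           # extensible inward
      if (k < min_len) next
      # canonical description: lexicographically smaller of the two reps
      i2 <- .modpos(j - k + 1, n); j2 <- .modpos(i + k - 1, n)
      ii <- .modpos(i, n); jj <- .modpos(j, n)
      if (i2 < ii || (i2 == ii && j2 < jj)) { ii <- i2; jj <- j2 }
      key <- paste(ii, jj, k)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- c(ii, jj, k)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# second structure oracle: filter all subsets of the canonical pair list
# (small N only). Legality: disjoint positions, non-crossing in linear
# order, every hairpin face (a pair with nothing inside, or an exterior
# face with a single branch) keeps >= 3 unpaired nt.
bitmask_structures <- function(seq) {
  n <- seq$n
  b <- seq$bases
  pl <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (.canon_chr(b[i], b[j])) pl[[length(pl) + 1]] <- c(i, j)
  np <- length(pl)
  stopifnot(np <= 20)
  P <- if (np > 0) do.call(rbind, pl) else matrix(integer(0), 0, 2)
  res <- list()
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    pm <- P[sel, , drop = FALSE]
    if (nrow(pm) > 0) {
      if (anyDuplicated(as.vector(pm)) > 0) next
      bad <- FALSE
      if (nrow(pm) > 1) {
        for (a in 1:(nrow(pm) - 1)) for (c2 in (a + 1):nrow(pm)) {
          i1 <- pm[a, 1]; j1 <- pm[a, 2]; i2 <- pm[c2, 1]; j2 <- pm[c2, 2]
          if ((i1 < i2 && i2 < j1 && j1 < j2) ||
              (i2 < i1 && i1 < j2 && j2 < j1)) bad <- TRUE
        }
      }
      if (bad) next
      # hairpin faces: pair with no pair inside needs >= 3 nt inside
      for (a in seq_len(nrow(pm))) {
        inside <- pm[, 1] > pm[a, 1] & pm[, 2] < pm[a, 2]
        inside[a] <- FALSE
        if (!any(inside) && pm[a, 2] - pm[a, 1] - 1 < 3) bad <- TRUE
      }
      # exterior face with a single branch is a hairpin too
      top <- rep(TRUE, nrow(pm))
      for (a in seq_len(nrow(pm)))
        if (any(pm[, 1] < pm[a, 1] & pm[, 2] > pm[a, 2])) top[a] <- FALSE
      if (sum(top) == 1) {
        sp <- pm[top, , drop = FALSE]
        if (n - (sp[1, 2] - sp[1, 1] + 1) < 3) bad <- TRUE
      }
      if (bad) next
    }
    res[[length(res) + 1]] <- pm
  }
  res
}

# engine global MFE in the exact configuration (all canonical closing
# pairs, pure-MFE closing selection, empty signature)
engine_global_mfe <- function(seq, model, constraints = NULL) {
  sig <- enumerate_signatures(list(), seq$n)[[1]]
  predict_partition_mfe(seq, sig, model, constraints = constraints,
                        control = fold_control(closing = "all",
                                               closing_rule = "mfe"))
}

# seeded random circle, optionally GC-biased so that non-trivial minima
# appear at small N
random_circle <- function(n, seed, gc = FALSE) {
  prob <- if (gc) c(.15, .35, .35, .15) else rep(.25, 4)
  b <- circfold:::.with_seed(seed,
    sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob))
  circ_sequence(b, name = sprintf("rnd%d_%d", n, seed))
}

# does a structure contain every pair of a helix?
contains_helix <- function(st, h, n) {
  hp <- helix_pairs(h, n)
  all(apply(hp, 1, function(r)
    any(st$pairs[, 1] == r[1] & st$pairs[, 2] == r[2])))
}

# brute-force fragment ensemble: all structures of the 5'->3' fragment
# a..b (circle coordinates, wrapping allowed) with terminal pair (a, b)
# forced; returns the energy of each structure (faces closed by (a, b)
# and everything inside; no exterior face)
fragment_enum <- function(seq, a, b, model, forbidden = NULL) {
  n <- seq$n
  idx <- if (b > a) a:b else c(a:n, 1:b)
  L <- length(idx)
  bs <- seq$bases[idx]
  gen <- function(lo, hi) {
    if (lo >= hi) return(list(matrix(integer(0), 0, 2)))
    out <- gen(lo + 1, hi)
    for (q in (lo + 1):hi) {
      if (!.canon_chr(bs[lo], bs[q])) next
      for (x in gen(lo + 1, q - 1)) for (y in gen(q + 1, hi))
        out[[length(out) + 1]] <- rbind(c(lo, q), x, y)
    }
    out
  }
  mats <- lapply(gen(2, L - 1), function(pm) rbind(c(1L, L), pm))
  if (!is.null(forbidden)) {
    keepf <- vapply(mats, function(pm) {
      circ <- cbind(idx[pm[, 1]], idx[pm[, 2]])
      circ <- cbind(pmin(circ[, 1], circ[, 2]), pmax(circ[, 1], circ[, 2]))
      !any(apply(circ, 1, function(p)
        any(forbidden[, 1] == p[1] & forbidden[, 2] == p[2])))
    }, logical(1))
    mats <- mats[keepf]
  }
  en <- vapply(mats, function(pm) frag_energy(pm, bs, model), numeric(1))
  keep <- en < 1e5
  list(energies = en[keep], pairs = mats[keep])
}

# linear loop-sum energy for a fragment structure (pair (1, L) included)
frag_energy <- function(pm, bs, model) {
  total <- 0
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]; j <- pm[r, 2]
    kids <- which(pm[, 1] > i & pm[, 2] < j)
    if (length(kids) > 1) {
      drop <- logical(length(kids))
      for (t in seq_along(kids)) for (u in seq_along(kids))
        if (t != u && pm[kids[u], 1] < pm[kids[t], 1] &&
            pm[kids[t], 2] < pm[kids[u], 2]) drop[t] <- TRUE
      kids <- kids[!drop]
    }
    kids <- kids[order(pm[kids, 1])]
    if (length(kids) == 0) {
      g <- loop_free_energy(model, loop_descriptor("hairpin", j - i - 1))
    } else if (length(kids) == 1) {
      p <- pm[kids, 1]; q <- pm[kids, 2]
      s1 <- p - i - 1; s2 <- j - q - 1
      g <- if (s1 == 0 && s2 == 0)
        stack_free_energy(model, c(bs[i], bs[j]), c(bs[p], bs[q]))
      else loop_free_energy(model,
        loop_descriptor(if (min(s1, s2) == 0) "bulge" else "internal",
                        s1 + s2, sizes = c(s1, s2)))
    } else {
      unp <- (j - i - 1) - sum(pm[kids, 2] - pm[kids, 1] + 1)
      g <- loop_free_energy(model,
        loop_descriptor("multiloop", unp, length(kids) + 1L))
    }
    total <- total + g
    if (total >= 1e5) return(1e6)
  }
  total
}
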