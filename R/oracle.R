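# Exhaustive enumeration oracle for small circles: every pseudoknot-free
# canonical structure is generated by interval recursion and scored by an
# independent direct-sum evaluator that walks the nesting forest (no code
# shared with the engine's face-walk evaluator or the DP core; only the
# sequence/structure types and the parameter file are common ground).

#' Enumerate all legal circular secondary structures (small N)
#'
#' Generates every set of non-crossing canonical base pairs on the circle
#' by interval recursion, scores each with an independent loop-sum
#' evaluator and drops structures containing an illegal face (hairpin
#' below 3 unpaired nt, on either side of the circle). Intended as ground
#' truth for engine tests; refuses circles above 18 nt.
#'
#' @param seq A [circ_sequence()] with `N <= 18`.
#' @param model A [load_parameters()] energy model.
#' @param min_helix_len Structures containing a helix run shorter than
#'   this are dropped (default 1: lone pairs allowed, matching the engine
#'   universe).
#' @return A list with `structures` (list of [secondary_structure()]),
#'   `energies`, `Q` (Boltzmann sum), `mfe_index`, `kT`.
#' @export
enumerate_all_structures <- function(seq, model = load_parameters(),
                                     min_helix_len = 1L) {
  stopifnot(inherits(seq, "circ_sequence"))
  n <- seq$n
  if (n > 18L)
    stop("exhaustive enumeration is capped at N = 18", call. = FALSE)
  codes <- seq$codes

  # all non-crossing canonical matchings of the linear order 1..n
  # (chords on a circle cross iff they interleave linearly)
  memo <- new.env(hash = TRUE)
  gen <- function(lo, hi) {
    if (lo >= hi) return(list(matrix(integer(0), 0, 2)))
    key <- paste(lo, hi)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- gen(lo + 1L, hi)                     # lo unpaired
    for (q in (lo + 1L):hi) {
      if (!.canonical_code(codes[lo], codes[q])) next
      inner <- gen(lo + 1L, q - 1L)
      outer <- gen(q + 1L, hi)
      for (x in inner) for (y in outer)
        out[[length(out) + 1L]] <- rbind(c(lo, q), x, y)
    }
    memo[[key]] <- out
    out
  }
  all_pairs <- gen(1L, n)

  energies <- vapply(all_pairs, function(pm)
    .oracle_energy(pm, codes, seq$bases, model), numeric(1))
  keep <- energies < .EINF / 2
  if (min_helix_len > 1L) {
    keep <- keep & vapply(all_pairs, function(pm)
      .oracle_min_run(pm, n) >= min_helix_len, logical(1))
  }
  all_pairs <- all_pairs[keep]
  energies <- energies[keep]
  kT <- model$kB * model$temperature
  structure(list(
    structures = lapply(all_pairs, secondary_structure, n = n),
    energies = energies,
    Q = sum(exp(-energies / kT)),
    mfe_index = which.min(energies),
    kT = kT, n = n), class = "circfold_oracle")
}

# shortest helix run present in a structure (Inf for the open circle)
.oracle_min_run <- function(pm, n) {
  if (nrow(pm) == 0L) return(Inf)
  key <- paste(pm[, 1], pm[, 2])
  runs <- integer(0)
  seen <- character(0)
  for (r in seq_len(nrow(pm))) {
    # only start counting at a run's outer end
    po <- .cpos(pm[r, 1] - 1L, n); qo <- .cpos(pm[r, 2] + 1L, n)
    kout <- paste(min(po, qo), max(po, qo))
    if (kout %in% key) next
    len <- 1L
    pi <- .cpos(pm[r, 1] + 1L, n); qi <- .cpos(pm[r, 2] - 1L, n)
    while (paste(min(pi, qi), max(pi, qi)) %in% key) {
      len <- len + 1L
      pi <- .cpos(pi + 1L, n); qi <- .cpos(qi - 1L, n)
    }
    runs <- c(runs, len)
  }
  if (length(runs) == 0L) return(Inf)
  min(runs)
}

# independent direct-sum energy: nesting forest + per-loop scoring computed
# straight from the parsed parameter tables
.oracle_energy <- function(pm, codes, bases, model) {
  n <- length(codes)
  if (nrow(pm) > 0L &&
      !all(.canonical_code(codes[pm[, 1]], codes[pm[, 2]]))) return(.EINF)
  TT <- model$temperature
  sc <- TT / 310.15
  kB <- model$kB
  tabE <- function(tab, size, minsz) {
    if (size < minsz) return(.EINF)
    m <- model$max_tabulated_loop
    if (size <= m) return(sc * tab[size])
    sc * tab[m] + 1.75 * kB * TT * log(size / m)
  }
  stackE <- function(o5, o3, i5, i3)
    model$stack_dH[o5, o3, i5, i3] - TT * model$stack_dS[o5, o3, i5, i3]
  mlE <- function(branches, unpaired) {
    ml <- model$multiloop
    sc * (ml[1] + ml[2] * branches + ml[3] * unpaired)
  }
  if (nrow(pm) == 0L) return(0)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  m <- nrow(pm)
  # parent of each pair = tightest enclosing pair (linear nesting)
  parent <- integer(m)
  for (r in seq_len(m)) {
    best <- 0L
    for (t in seq_len(m)) {
      if (t == r) next
      if (pm[t, 1] < pm[r, 1] && pm[r, 2] < pm[t, 2] &&
          (best == 0L || pm[t, 1] > pm[best, 1])) best <- t
    }
    parent[r] <- best
  }
  total <- 0
  score_face <- function(closing, kids, gaps, unpaired) {
    nb <- length(kids) + (if (is.na(closing)) 0L else 1L)
    if (nb == 0L) return(0)
    if (nb == 1L) {
      return(tabE(model$hairpin_g37, unpaired, 3L))
    }
    if (nb == 2L) {
      if (all(gaps == 0L)) {
        if (is.na(closing)) {
          # helix continues through the exterior face
          a <- kids[1]; b2 <- kids[2]
          return(stackE(bases[pm[a, 2]], bases[pm[a, 1]],
                        bases[pm[b2, 1]], bases[pm[b2, 2]]))
        }
        k <- kids[1]
        return(stackE(bases[pm[closing, 1]], bases[pm[closing, 2]],
                      bases[pm[k, 1]], bases[pm[k, 2]]))
      }
      sz <- sum(gaps)
      if (min(gaps) == 0L) return(tabE(model$bulge_g37, sz, 1L))
      return(tabE(model$internal_g37, sz, 2L))
    }
    mlE(nb, unpaired)
  }
  for (r in seq_len(m)) {
    kids <- which(parent == r)
    kids <- kids[order(pm[kids, 1])]
    span <- pm[r, 2] - pm[r, 1] - 1L
    ksp <- if (length(kids) > 0L) sum(pm[kids, 2] - pm[kids, 1] + 1L) else 0L
    unpaired <- span - ksp
    gaps <- integer(0)
    if (length(kids) == 1L)
      gaps <- c(pm[kids, 1] - pm[r, 1] - 1L, pm[r, 2] - pm[kids, 2] - 1L)
    total <- total + score_face(r, kids, gaps, unpaired)
    if (total >= .EINF) return(.EINF)
  }
  top <- which(parent == 0L)
  top <- top[order(pm[top, 1])]
  unpaired <- n - sum(pm[top, 2] - pm[top, 1] + 1L)
  gaps <- integer(0)
  if (length(top) == 2L) {
    a <- top[1]; b2 <- top[2]
    gaps <- c(pm[b2, 1] - pm[a, 2] - 1L, (pm[a, 1] - 1L) + (n - pm[b2, 2]))
  }
  if (length(top) == 1L) {
    total <- total + score_face(NA, top, integer(0), unpaired)
  } else if (length(top) >= 2L) {
    total <- total + score_face(NA, top, gaps, unpaired)
  }
  min(total, .EINF)
}

#' Conditional Boltzmann sum from an oracle enumeration
#'
#' @param enumeration Result of [enumerate_all_structures()].
#' @param i,j A base pair (1-based circle positions).
#' @return Sum of Boltzmann weights over the enumerated structures that
#'   contain the pair `(i, j)`.
#' @export
oracle_conditional_Q <- function(enumeration, i, j) {
  stopifnot(inherits(enumeration, "circfold_oracle"))
  lo <- min(i, j); hi <- max(i, j)
  w <- vapply(enumeration$structures, function(st)
    any(st$pairs[, 1] == lo & st$pairs[, 2] == hi), logical(1))
  sum(exp(-enumeration$energies[w] / enumeration$kT))
}

#' @export
print.circfold_oracle <- function(x, ...) {
  cat(sprintf("oracle enumeration: %d structures on %d nt, Q = %.6g, MFE = %.3f kcal/mol\n",
              length(x$structures), x$n, x$Q, x$energies[x$mfe_index]))
  invisible(x)
}

#' Dump an oracle enumeration as text
#'
#' One structure per line: dot-bracket plus energy, sorted by energy.
#'
#' @param enumeration Result of [enumerate_all_structures()].
#' @return Character vector of lines.
#' @export
oracle_dump <- function(enumeration) {
  ord <- order(enumeration$energies)
  vapply(ord, function(t)
    sprintf("%s %10.4f", dot_bracket(enumeration$structures[[t]]),
            enumeration$energies[t]), character(1))
}
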