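# Folding engine: conditional fragment partition functions, the circular
# two-fragment decomposition Q^{i-j} = Qfrag(i,j) * Qfrag(j,i), MFE
# backtracking per landscape partition, and loop-decomposition energy
# evaluation of complete circular structures.
#
# Energy-ownership convention of the decomposition: all energy lives in
# stacks and loops (faces of the chord diagram); a fragment's conditional
# quantities cover the loop closed by its terminal pair and everything
# nested inside, and the closing pair itself carries no standalone term.
# The internal fragment (i, j) therefore owns the face inside (i, j) and
# the external fragment (j, i) owns the face outside it; every face of the
# circular structure is counted exactly once.

#' Pseudoknot-free circular secondary structure
#'
#' @param pairs Integer matrix with two columns (1-based circle
#'   positions), or a 2k-long vector; each row one base pair. May be
#'   empty (the open circle).
#' @param n Circle length.
#' @return A `circfold_structure` with rows ordered `(min, max)` and
#'   sorted by 5' position.
#' @export
secondary_structure <- function(pairs, n) {
  if (is.null(pairs) || length(pairs) == 0L)
    pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0L) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    if (any(pairs < 1L) || any(pairs > n))
      stop("pair positions out of range", call. = FALSE)
    v <- as.vector(pairs)
    if (anyDuplicated(v) > 0L) {
      d <- v[duplicated(v)][1]
      stop(sprintf("position %d participates in more than one pair", d),
           call. = FALSE)
    }
    # chords on the circle cross iff they interleave in linear order
    m <- nrow(pairs)
    if (m > 1L) for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      i1 <- pairs[a, 1]; j1 <- pairs[a, 2]
      i2 <- pairs[b, 1]; j2 <- pairs[b, 2]
      if (i1 < i2 && i2 < j1 && j1 < j2)
        stop(sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknots are outside the model)",
                     i1, j1, i2, j2), call. = FALSE)
    }
  }
  structure(list(pairs = pairs, n = as.integer(n)),
            class = "circfold_structure")
}

#' @export
print.circfold_structure <- function(x, ...) {
  cat(sprintf("circular secondary structure, %d nt, %d pairs\n", x$n,
              nrow(x$pairs)))
  cat(" ", dot_bracket(x), "\n")
  invisible(x)
}

#' Dot-bracket rendering of a circular structure
#'
#' Chords of a pseudoknot-free circular structure never interleave in the
#' linear 1..N numbering, so the rendering is always well nested. Helices
#' that continue across the sequence origin show up as base pairs stacked
#' through the exterior face; [origin_spanning()] flags them.
#'
#' @param structure A [secondary_structure()].
#' @return A length-N character scalar of `(`, `)` and `.`.
#' @export
dot_bracket <- function(structure) {
  db <- rep(".", structure$n)
  if (nrow(structure$pairs) > 0L) {
    db[structure$pairs[, 1]] <- "("
    db[structure$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation
#'
#' @param x Dot-bracket string.
#' @return A [secondary_structure()].
#' @export
parse_dot_bracket <- function(x) {
  ch <- strsplit(x, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("dot-bracket may only contain '(', ')' and '.'", call. = FALSE)
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (p in seq_along(ch)) {
    if (ch[p] == "(") stack <- c(stack, p)
    else if (ch[p] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket", call. = FALSE)
  secondary_structure(pairs, length(ch))
}

#' Does a structure carry helices across the sequence origin?
#'
#' @param structure A [secondary_structure()].
#' @return `TRUE` when two pairs stack through the exterior face, i.e. a
#'   helix continues across the N -> 1 boundary.
#' @export
origin_spanning <- function(structure) {
  pr <- structure$pairs
  n <- structure$n
  if (nrow(pr) < 2L) return(FALSE)
  for (a in seq_len(nrow(pr))) for (b in seq_len(nrow(pr))) {
    if (a == b) next
    # pairs (i1,j1), (i2,j2) stacked through the exterior:
    # j1 + 1 == i2 and j2 + 1 == i1 (mod n)
    if (.cpos(pr[a, 2] + 1L, n) == pr[b, 1] &&
        .cpos(pr[b, 2] + 1L, n) == pr[a, 1]) return(TRUE)
  }
  FALSE
}

#' Loop-decomposition energy of a circular structure
#'
#' Decomposes the chord diagram into its faces, scores each face (stack,
#' hairpin, bulge/internal, multiloop) and sums. The face enclosed by no
#' pair - the circular exterior face - is classified by its branch degree:
#' one branch scores as a hairpin, two as internal/bulge (or a stack when
#' both gaps are empty, i.e. a helix runs across the origin), three or
#' more as a multiloop; the bare circle scores 0.
#'
#' @param structure A [secondary_structure()].
#' @param seq A [circ_sequence()].
#' @param model A [load_parameters()] energy model.
#' @return Free energy in kcal/mol (the forbidden sentinel `1e6` appears
#'   when a hairpin face has fewer than 3 unpaired nt).
#' @export
evaluate_structure_energy <- function(structure, seq, model) {
  stopifnot(inherits(structure, "circfold_structure"),
            inherits(seq, "circ_sequence"),
            inherits(model, "circfold_energy"))
  n <- seq$n
  if (structure$n != n)
    stop("structure and sequence lengths differ", call. = FALSE)
  pr <- structure$pairs
  if (nrow(pr) == 0L) return(0)
  bad <- which(!.canonical_code(seq$codes[pr[, 1]], seq$codes[pr[, 2]]))
  if (length(bad) > 0L)
    stop(sprintf("noncanonical pair(s): %s",
                 paste(sprintf("(%d,%d)", pr[bad, 1], pr[bad, 2]),
                       collapse = " ")), call. = FALSE)
  partner <- integer(n)
  partner[pr[, 1]] <- pr[, 2]
  partner[pr[, 2]] <- pr[, 1]
  b <- seq$bases

  face_energy <- function(ci, cj, branches, unpaired) {
    # face closed by pair (ci, cj) (NULL for the exterior face) with the
    # given branch pairs (rows (p, q), p the 5' side seen from this face)
    nb <- nrow(branches) + (if (is.null(ci)) 0L else 1L)
    if (nb == 0L) return(0)
    if (is.null(ci)) {
      # exterior face: emulate a closing pair by its branch degree
      if (nb == 1L)
        return(loop_free_energy(model, loop_descriptor("hairpin", unpaired)))
      if (nb == 2L) {
        p1 <- branches[1, 1]; q1 <- branches[1, 2]
        p2 <- branches[2, 1]; q2 <- branches[2, 2]
        g1 <- (p2 - q1 - 1L) %% n
        g2 <- (p1 - q2 - 1L) %% n
        if (g1 == 0L && g2 == 0L)
          return(stack_free_energy(model, c(b[q1], b[p1]), c(b[p2], b[q2])))
        return(loop_free_energy(model,
          loop_descriptor("circular_exterior", unpaired, 2L,
                          sizes = c(g1, g2))))
      }
      return(loop_free_energy(model,
        loop_descriptor("circular_exterior", unpaired, nb)))
    }
    if (nb == 1L)
      return(loop_free_energy(model, loop_descriptor("hairpin", unpaired)))
    if (nb == 2L) {
      p <- branches[1, 1]; q <- branches[1, 2]
      s1 <- p - ci - 1L
      s2 <- cj - q - 1L
      if (s1 == 0L && s2 == 0L)
        return(stack_free_energy(model, c(b[ci], b[cj]), c(b[p], b[q])))
      kind <- if (min(s1, s2) == 0L) "bulge" else "internal"
      return(loop_free_energy(model,
        loop_descriptor(kind, s1 + s2, sizes = c(s1, s2))))
    }
    loop_free_energy(model,
      loop_descriptor("multiloop", unpaired, nb))
  }

  total <- 0
  # interior faces: walk the inside of each pair
  for (r in seq_len(nrow(pr))) {
    ci <- pr[r, 1]; cj <- pr[r, 2]
    branches <- matrix(integer(0), 0, 2)
    unpaired <- 0L
    p <- ci + 1L
    while (p < cj) {
      if (partner[p] == 0L) { unpaired <- unpaired + 1L; p <- p + 1L }
      else { branches <- rbind(branches, c(p, partner[p])); p <- partner[p] + 1L }
    }
    total <- total + face_energy(ci, cj, branches, unpaired)
  }
  # exterior face: cyclic walk over top-level elements
  branches <- matrix(integer(0), 0, 2)
  unpaired <- 0L
  p <- 1L
  while (p <= n) {
    if (partner[p] == 0L) { unpaired <- unpaired + 1L; p <- p + 1L }
    else { branches <- rbind(branches, c(p, partner[p])); p <- partner[p] + 1L }
  }
  total <- total + face_energy(NULL, NULL, branches, unpaired)
  min(total, .EINF)
}

# shared setup for the DP core
.dp_inputs <- function(seq, model, rules = NULL) {
  n <- seq$n
  if (is.null(rules)) rules <- .fold_rules(n)
  list(codes = c(seq$codes, seq$codes), n = n,
       par = .engine_par(model, n), rules = rules)
}

.frag_window <- function(a, b, n) {
  if (a < 1L || a > n || b < 1L || b > n || a == b)
    stop("fragment ends must be two distinct positions in 1..N", call. = FALSE)
  c(a, if (b > a) b else b + n)
}

#' Conditional partition function of a linear fragment
#'
#' Boltzmann-weighted sum over all pseudoknot-free structures of the
#' fragment read 5'->3' along the circle from `a` to `b`, in which the
#' terminal nucleotides `a` and `b` are paired with each other and all
#' constraint rules hold. Returns 0 when the constrained ensemble is
#' empty.
#'
#' @param seq A [circ_sequence()].
#' @param a,b Fragment terminal positions (1-based circle positions; the
#'   fragment wraps the origin when `b < a`).
#' @param constraints Optional list of [constraint()] objects, or a
#'   signature via [circular_conditional_Q()].
#' @param model A [load_parameters()] energy model.
#' @return The conditional partition function (dimensionless), with the
#'   natural logarithm attached as attribute `"log"`.
#' @export
conditional_fragment_Q <- function(seq, a, b, constraints = NULL,
                                   model = load_parameters()) {
  stopifnot(inherits(seq, "circ_sequence"))
  w <- .frag_window(a, b, seq$n)
  if (!.canonical_code(seq$codes[a], seq$codes[b]))
    stop(sprintf("terminal pair (%d, %d) is %s-%s, not canonical", a, b,
                 seq$bases[a], seq$bases[b]), call. = FALSE)
  rules <- .rules_for(seq$n, constraints)
  inp <- .dp_inputs(seq, model, rules)
  tb <- .cf_tables(inp$codes, inp$n, inp$par, inp$rules, TRUE)
  lq <- tb$logQb[w[1], w[2]]
  structure(exp(lq), log = lq)
}

# accept NULL, a constraint list, or a signature
.rules_for <- function(n, constraints) {
  if (is.null(constraints)) return(.fold_rules(n))
  if (inherits(constraints, "circfold_signature"))
    return(.rules_from_signature(constraints, n))
  if (inherits(constraints, "circfold_constraint"))
    constraints <- list(constraints)
  r <- .rules_from_signature(
    structure(list(pool = list(), flags = logical(0)),
              class = "circfold_signature"), n, constraints)
  if (is.null(r)) stop("contradictory constraints", call. = FALSE)
  r
}

#' Conditional partition function of the circle given a closing pair
#'
#' Implements the two-fragment decomposition of the circle: the partition
#' function of the ensemble conditioned on formation of the `i-j` base
#' pair is the product of the conditional partition functions of the
#' internal fragment `(i, j)` and the external fragment `(j, i)`, each
#' with its terminal nucleotides paired. The shared closing pair
#' contributes no double-counted energy: the stacks straddling it belong
#' to the fragment whose loop contains them.
#'
#' @param seq A [circ_sequence()].
#' @param i,j Closing pair positions (1-based, canonical).
#' @param signature Optional `circfold_signature` (or constraint list)
#'   restricting the ensemble.
#' @param model A [load_parameters()] energy model.
#' @return The conditional partition function, log attached as `"log"`.
#' @export
circular_conditional_Q <- function(seq, i, j, signature = NULL,
                                   model = load_parameters()) {
  stopifnot(inherits(seq, "circ_sequence"))
  n <- seq$n
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  if (i < 1L || j > n || i == j)
    stop("closing pair must be two distinct positions in 1..N", call. = FALSE)
  if (!.canonical_code(seq$codes[i], seq$codes[j]))
    stop(sprintf("closing pair (%d, %d) is %s-%s, not canonical", i, j,
                 seq$bases[i], seq$bases[j]), call. = FALSE)
  rules <- .rules_for(n, signature)
  if (is.null(rules)) return(structure(0, log = -Inf))
  inp <- .dp_inputs(seq, model, rules)
  tb <- .cf_tables(inp$codes, inp$n, inp$par, inp$rules, TRUE)
  lq <- tb$logQb[i, j] + tb$logQb[j, i + n]
  structure(exp(lq), log = lq)
}

#' MFE structure of a constrained fragment
#'
#' Minimum-free-energy constrained structure of the fragment `a..b` with
#' terminal pair `(a, b)`, recovered by deterministic backtracking
#' through the MFE tables (co-optimal ties resolve to the branch with the
#' smaller 5' index, then the smaller 3' index).
#'
#' @inheritParams conditional_fragment_Q
#' @return A list with `pairs` (circle positions), `energy` (kcal/mol)
#'   and `feasible`; `feasible = FALSE` flags an empty ensemble.
#' @export
fragment_mfe_backtrack <- function(seq, a, b, constraints = NULL,
                                   model = load_parameters()) {
  stopifnot(inherits(seq, "circ_sequence"))
  w <- .frag_window(a, b, seq$n)
  rules <- .rules_for(seq$n, constraints)
  inp <- .dp_inputs(seq, model, rules)
  bt <- .cf_backtrack(inp$codes, inp$n, inp$par, inp$rules, w[1], w[2])
  if (!bt$feasible)
    return(list(pairs = matrix(integer(0), 0, 2), energy = NA_real_,
                feasible = FALSE))
  pm <- bt$pairs
  pm <- cbind(.cpos(pm[, 1], seq$n), .cpos(pm[, 2], seq$n))
  pm <- cbind(pmin(pm[, 1], pm[, 2]), pmax(pm[, 1], pm[, 2]))
  list(pairs = pm[order(pm[, 1]), , drop = FALSE], energy = bt$energy,
       feasible = TRUE)
}

# candidate closing pairs for one signature under the given rules
.closing_candidates <- function(seq, rules, closing = "helix",
                                min_helix_len = 2L, helices = NULL) {
  n <- seq$n
  forced <- which(rules$partner != 0L & seq_len(n) < rules$partner)
  forced_pairs <- cbind(forced, rules$partner[forced])
  if (closing == "all") {
    idx <- which(outer(seq$codes, seq$codes, .canonical_code) &
                 upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    cand <- idx[, c(1, 2), drop = FALSE]
  } else {
    if (is.null(helices))
      helices <- enumerate_saturated_helices(seq, min_helix_len)
    cand <- matrix(integer(0), 0, 2)
    for (h in helices) cand <- rbind(cand, helix_pairs(h, n))
    cand <- rbind(cand, forced_pairs)
  }
  if (nrow(cand) == 0L) return(cand)
  cand <- unique(cand)
  # drop candidates the rules already rule out
  keep <- rep(TRUE, nrow(cand))
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, 1]; q <- cand[r, 2]
    if (rules$unpair[p] == 1L || rules$unpair[q] == 1L ||
        (rules$partner[p] != 0L && rules$partner[p] != q) ||
        (rules$partner[q] != 0L && rules$partner[q] != p)) {
      keep[r] <- FALSE
      next
    }
    if (nrow(rules$forbidden) > 0L &&
        any(rules$forbidden[, 1] == p & rules$forbidden[, 2] == q |
            rules$forbidden[, 1] == q & rules$forbidden[, 2] == p)) {
      keep[r] <- FALSE
      next
    }
    if (nrow(forced_pairs) > 0L) {
      for (t in seq_len(nrow(forced_pairs)))
        if (.chords_cross(p, q, forced_pairs[t, 1], forced_pairs[t, 2], n)) {
          keep[r] <- FALSE
          break
        }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
}

#' Engine control settings
#'
#' @param closing Candidate closing pairs for the decomposition scan:
#'   `"helix"` (default; pairs participating in a saturated helix of
#'   `min_helix_len` or more, plus all forced pairs) or `"all"` (every
#'   canonical pair - the exact setting, used by the validation suite).
#' @param closing_rule How the closing pair is selected: `"ensemble"`
#'   (default; minimize the partition free energy `-kB T ln Q`, as the
#'   method defines) or `"mfe"` (minimize the backtracked structure
#'   energy).
#' @param min_helix_len Minimum saturated-helix length for the stable
#'   pool (default 2).
#' @param pool_cap Hard cap on the helix pool (default 12).
#' @return A `circfold_control` list.
#' @export
fold_control <- function(closing = c("helix", "all"),
                         closing_rule = c("ensemble", "mfe"),
                         min_helix_len = 2L, pool_cap = 12L) {
  structure(list(closing = match.arg(closing),
                 closing_rule = match.arg(closing_rule),
                 min_helix_len = as.integer(min_helix_len),
                 pool_cap = as.integer(pool_cap)),
            class = "circfold_control")
}

#' MFE structure of one landscape partition
#'
#' Scans candidate closing pairs `(i, j)`, selects the one minimizing the
#' partition free energy `-kB T ln Q^{i-j}` (or the fragment MFE sum under
#' `closing_rule = "mfe"`), backtracks both fragments and assembles the
#' circular structure. When the signature includes no helix and no pair
#' is forced, the open circle (no pairs, G = 0) competes as a candidate.
#'
#' @param seq A [circ_sequence()].
#' @param signature A `circfold_signature` (use the empty signature for
#'   the unpartitioned landscape).
#' @param model A [load_parameters()] energy model.
#' @param constraints Optional validated user constraints.
#' @param control A [fold_control()].
#' @param helices Optional precomputed saturated helix list (speeds up
#'   repeated calls).
#' @return A `circfold_result` (structure, free energy, ensemble free
#'   energy, signature, closing pair) or `NULL` when the ensemble is
#'   empty.
#' @export
predict_partition_mfe <- function(seq, signature, model,
                                  constraints = NULL,
                                  control = fold_control(),
                                  helices = NULL) {
  stopifnot(inherits(seq, "circ_sequence"),
            inherits(signature, "circfold_signature"))
  n <- seq$n
  rules <- .rules_from_signature(signature, n, constraints)
  if (is.null(rules)) return(NULL)            # contradictory -> empty ensemble
  cand <- .closing_candidates(seq, rules, control$closing,
                              control$min_helix_len, helices)
  has_forced <- any(rules$partner != 0L)
  open_allowed <- !has_forced
  res <- NULL
  if (nrow(cand) > 0L) {
    inp <- .dp_inputs(seq, model, rules)
    pr <- .cf_predict(inp$codes, inp$n, inp$par, inp$rules,
                      matrix(as.integer(cand), ncol = 2),
                      as.integer(control$closing_rule == "mfe"))
    if (pr$feasible) {
      best <- pr$best
      res <- list(pairs = pr$pairs, mfe = pr$mfe,
                  logQ = pr$logQ[best],
                  closing = c(cand[best, 1], cand[best, 2]))
    }
  }
  kT <- model$kB * model$temperature
  use_open <- FALSE
  if (is.null(res)) {
    if (!open_allowed) return(NULL)
    use_open <- TRUE
  } else if (open_allowed) {
    score <- if (control$closing_rule == "mfe") res$mfe else -kT * res$logQ
    if (score >= 0) use_open <- TRUE        # the bare circle, G = 0, wins
  }
  if (use_open) {
    st <- secondary_structure(NULL, n)
    return(structure(list(structure = st, free_energy = 0,
                          ensemble_free_energy = 0, signature = signature,
                          closing_pair = NULL),
                     class = "circfold_result"))
  }
  st <- secondary_structure(res$pairs, n)
  fe <- evaluate_structure_energy(st, seq, model)
  structure(list(structure = st, free_energy = fe,
                 ensemble_free_energy = -kT * res$logQ,
                 signature = signature, closing_pair = res$closing),
            class = "circfold_result")
}

#' @export
print.circfold_result <- function(x, ...) {
  cat(sprintf("partition MFE: %.2f kcal/mol (ensemble G = %.2f), %s\n",
              x$free_energy, x$ensemble_free_energy,
              signature_label(x$signature)))
  cat(" ", dot_bracket(x$structure), "\n")
  invisible(x)
}

#' Full circular partition function via the decomposition
#'
#' Sums the structure ensemble exactly once by conditioning on the
#' smallest-index paired position: `Q = 1 + sum over canonical (p, q) of
#' Q^{p-q}` with positions `1..p-1` forced unpaired. Intended for
#' validation at small N (one dynamic program per 5' position).
#'
#' @param seq A [circ_sequence()].
#' @param model A [load_parameters()] energy model.
#' @param constraints Optional constraint list.
#' @return The partition function (the open circle contributes 1).
#' @export
circular_total_Q <- function(seq, model = load_parameters(),
                             constraints = NULL) {
  stopifnot(inherits(seq, "circ_sequence"))
  n <- seq$n
  base_rules <- .rules_for(n, constraints)
  total <- if (any(base_rules$partner != 0L)) 0 else 1  # open circle
  for (p in seq_len(n - 1L)) {
    rules <- base_rules
    if (p > 1L) {
      pre <- seq_len(p - 1L)
      if (any(rules$partner[pre] != 0L)) next  # forced pair before p: no term
      rules$unpair[pre] <- 1L
    }
    inp <- .dp_inputs(seq, model, rules)
    tb <- .cf_tables(inp$codes, inp$n, inp$par, inp$rules, TRUE)
    for (q in (p + 1L):n) {
      if (!.canonical_code(seq$codes[p], seq$codes[q])) next
      lq <- tb$logQb[p, q] + tb$logQb[q, p + n]
      if (is.finite(lq)) total <- total + exp(lq)
    }
  }
  total
}
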