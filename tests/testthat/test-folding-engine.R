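m_global <- load_parameters()

test_that("fragment conditional Q matches brute-force enumeration", {
  m <- m_global
  kT <- m$kB * m$temperature
  # one-structure fragment: single closing pair over a hairpin loop
  sq <- circ_sequence("GAAAACAAAA")
  q <- conditional_fragment_Q(sq, 1, 6, model = m)
  expect_equal(as.numeric(q),
               exp(-loop_free_energy(m, loop_descriptor("hairpin", 4)) / kT),
               tolerance = 1e-12)
  # random fragments vs exhaustive enumeration
  for (seed in 1:12) {
    sq <- random_circle(10 + seed %% 5, 100 + seed, gc = TRUE)
    n <- sq$n
    ends <- which(outer(sq$codes, sq$codes, circfold:::.canonical_code),
                  arr.ind = TRUE)
    ends <- ends[ends[, 1] != ends[, 2], , drop = FALSE]
    if (nrow(ends) == 0) next
    pick <- ends[circfold:::.with_seed(seed, sample(nrow(ends), 1)), ]
    a <- pick[1]; b <- pick[2]
    or <- fragment_enum(sq, a, b, m)
    want <- sum(exp(-or$energies / kT))
    got <- as.numeric(conditional_fragment_Q(sq, a, b, model = m))
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("fragment (%d,%d) of %s", a, b,
                                 as.character(sq)))
    # MFE backtracking agrees with the enumerated minimum
    bt <- fragment_mfe_backtrack(sq, a, b, model = m)
    if (length(or$energies) > 0) {
      expect_true(bt$feasible)
      expect_equal(bt$energy, min(or$energies), tolerance = 1e-6)
    } else {
      expect_false(bt$feasible)
    }
  }
})

test_that("an excluded helix covering the only closing pair empties the fragment ensemble", {
  m <- m_global
  sq <- circ_sequence("GAAAACAAAA")
  sig <- structure(list(pool = list(helix(1, 6, 1)), flags = FALSE),
                   class = "circfold_signature")
  q <- circular_conditional_Q(sq, 1, 6, sig, m)
  expect_equal(as.numeric(q), 0)
})

test_that("circular conditional Q obeys the two-fragment decomposition and rotation", {
  m <- m_global
  for (seed in 1:6) {
    sq <- random_circle(10 + seed, 200 + seed, gc = TRUE)
    n <- sq$n
    or <- enumerate_all_structures(sq, m)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!circfold:::.canonical_code(sq$codes[i], sq$codes[j])) next
      qo <- oracle_conditional_Q(or, i, j)
      qe <- as.numeric(circular_conditional_Q(sq, i, j, NULL, m))
      if (qo == 0 && qe == 0) next
      expect_equal(qe, qo, tolerance = 1e-9,
                   label = sprintf("Q(%d,%d) on %s", i, j, as.character(sq)))
    }
    # total Q via the decomposition, counting each structure once
    expect_equal(circular_total_Q(sq, m), or$Q, tolerance = 1e-9)
  }
  # rotational invariance of a conditional Q
  sq <- circ_sequence("GGGGGAAACCCCCAAA")
  q0 <- as.numeric(circular_conditional_Q(sq, 1, 13, NULL, m))
  for (s in c(3, 9)) {
    rq <- rotate_sequence(sq, s)
    i2 <- circfold:::.cpos(1 - s, 16); j2 <- circfold:::.cpos(13 - s, 16)
    expect_equal(as.numeric(circular_conditional_Q(rq, i2, j2, NULL, m)),
                 q0, tolerance = 1e-12)
  }
})

test_that("structure energy evaluation decomposes helices and both faces", {
  m <- m_global
  sq <- circ_sequence("GGGGGAAACCCCCAAA")
  expect_equal(evaluate_structure_energy(secondary_structure(NULL, 16), sq, m),
               0)
  # single helix on the circle: (k-1) stacks + inner hairpin + exterior face
  st <- secondary_structure(rbind(c(1, 13), c(2, 12), c(3, 11), c(4, 10),
                                  c(5, 9)), 16)
  want <- 4 * stack_free_energy(m, "GC", "GC") +
    loop_free_energy(m, loop_descriptor("hairpin", 3)) +
    loop_free_energy(m, loop_descriptor("hairpin", 3))
  expect_equal(evaluate_structure_energy(st, sq, m), want, tolerance = 1e-12)
  # agreement with the oracle's independent evaluator on every structure
  or <- enumerate_all_structures(sq, m)
  for (t in seq_along(or$structures))
    expect_equal(evaluate_structure_energy(or$structures[[t]], sq, m),
                 or$energies[t], tolerance = 1e-9)
  expect_error(secondary_structure(rbind(c(1, 5), c(3, 8)), 10), "cross")
  expect_error(secondary_structure(rbind(c(1, 5), c(5, 9)), 10),
               "more than one pair")
})

test_that("partition MFE prediction honors signatures and falls back to the open circle", {
  m <- m_global
  sq <- circ_sequence("AAAAAAAAAAAA")
  r <- engine_global_mfe(sq, m)
  expect_equal(r$free_energy, 0)
  expect_equal(nrow(r$structure$pairs), 0)
  # global MFE equals the oracle minimum (all-excluded signature, empty pool)
  for (seed in 1:10) {
    sq <- random_circle(12 + seed %% 5, 300 + seed, gc = TRUE)
    or <- enumerate_all_structures(sq, m)
    r <- engine_global_mfe(sq, m)
    expect_equal(r$free_energy, min(or$energies), tolerance = 1e-6,
                 label = as.character(sq))
  }
  # a signature including a helix forces all its pairs
  sq <- generate_fixture("two_helix", 32)
  ann <- attr(sq, "annotation")
  hs <- enumerate_saturated_helices(sq)
  rk <- rank_helices(hs, sq, m)
  grown <- grow_pool_until(4, rk, sq$n)
  for (sig in grown$signatures) {
    r <- predict_partition_mfe(sq, sig, m, helices = hs)
    if (is.null(r)) next
    for (t in which(sig$flags))
      expect_true(contains_helix(r$structure, sig$pool[[t]], sq$n))
    for (t in which(!sig$flags))
      expect_false(any(apply(helix_pairs(sig$pool[[t]], sq$n), 1, function(p)
        any(r$structure$pairs[, 1] == p[1] & r$structure$pairs[, 2] == p[2]))))
    # reported energy reproduces the independent loop-sum evaluation
    expect_equal(r$free_energy,
                 evaluate_structure_energy(r$structure, sq, m),
                 tolerance = 1e-9)
  }
})

test_that("backtracking is deterministic run to run", {
  m <- m_global
  sq <- random_circle(20, 77, gc = TRUE)
  r1 <- engine_global_mfe(sq, m)
  r2 <- engine_global_mfe(sq, m)
  expect_identical(r1$structure$pairs, r2$structure$pairs)
  expect_identical(r1$free_energy, r2$free_energy)
})
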