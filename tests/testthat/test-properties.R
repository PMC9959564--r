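# Property-style invariants over generated cases (fixed seeds).

test_that("planted stems are recovered as the top-ranked structure", {
  m <- load_parameters()
  for (n in seq(22, 40, by = 2)) {
    sq <- generate_fixture("hairpin_circle", n)
    ann <- attr(sq, "annotation")[[1]]
    # by construction the stem is stable enough to beat the open circle
    expect_lt(helix_free_energy(m, ann, sq) +
                2 * loop_free_energy(m, loop_descriptor("hairpin", 4)), 0)
    fit <- circfold(sq, max_structures = 3)
    expect_true(contains_helix(fit$results[[1]]$structure, ann, n),
                label = sprintf("planted stem at N=%d", n))
    expect_lt(fit$results[[1]]$free_energy, 0)
  }
})

test_that("forced helices appear in every result and forced loops never pair", {
  for (seed in 1:12) {
    n <- 24 + 2 * (seed %% 6)
    sq <- random_circle(n, 400 + seed, gc = TRUE)
    hs <- enumerate_saturated_helices(sq)
    if (length(hs) == 0) next
    h <- hs[[1 + (seed %% length(hs))]]
    cs <- sprintf("HELIX %d %d %d", h$i, h$j, h$k)
    fit <- circfold(sq, constraints = cs, max_structures = 4)
    for (res in fit$results)
      expect_true(contains_helix(res$structure, h, n), label = cs)
    # forced loop away from the helix
    used <- as.vector(helix_pairs(h, n))
    free <- setdiff(seq_len(n), used)
    run <- free[1]
    fit2 <- circfold(sq, constraints = sprintf("LOOP %d 2", run),
                     max_structures = 4)
    banned <- circfold:::.cpos(run + 0:1, n)
    for (res in fit2$results)
      expect_false(any(res$structure$pairs %in% banned))
  }
})

test_that("any two reported structures differ in at least one pool helix", {
  for (case in list(generate_fixture("two_helix", 34),
                    generate_fixture("hairpin_circle", 30),
                    random_circle(36, 5, gc = TRUE))) {
    fit <- circfold(case, max_structures = 6)
    if (length(fit$results) < 2) next
    incl <- vapply(fit$results, function(res)
      vapply(fit$pool, function(h)
        contains_helix(res$structure, h, case$n), logical(1)),
      logical(length(fit$pool)))
    incl <- matrix(incl, ncol = length(fit$results))
    for (a in 1:(ncol(incl) - 1)) for (b in (a + 1):ncol(incl))
      expect_true(any(incl[, a] != incl[, b]),
                  label = sprintf("%s results %d vs %d", case$name, a, b))
  }
})

test_that("every emitted structure round-trips through dot-bracket", {
  fit <- circfold(generate_fixture("two_helix", 30), max_structures = 5)
  for (res in fit$results) {
    back <- parse_dot_bracket(dot_bracket(res$structure))
    expect_identical(back$pairs, res$structure$pairs)
  }
})

test_that("constrained minima are never deeper than the unconstrained minimum", {
  m <- load_parameters()
  for (seed in 1:10) {
    n <- 18 + seed
    sq <- random_circle(n, 500 + seed, gc = TRUE)
    base <- engine_global_mfe(sq, m)
    hs <- enumerate_saturated_helices(sq)
    if (length(hs) == 0) next
    h <- hs[[1 + (seed %% length(hs))]]
    cons <- validate_constraints(sprintf("HELIX %d %d %d", h$i, h$j, h$k), sq)
    con <- engine_global_mfe(sq, m, constraints = cons)
    if (is.null(con)) next
    expect_gte(con$free_energy, base$free_energy - 1e-9)
  }
})
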