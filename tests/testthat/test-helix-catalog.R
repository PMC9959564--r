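test_that("saturated helix enumeration matches the brute-force pair-matrix oracle", {
  # spec'd toy cases
  expect_length(enumerate_saturated_helices(circ_sequence("AAAAAAAA")), 0)
  hs <- enumerate_saturated_helices(circ_sequence("GGGGAAAACCCCAAAA"), 2)
  tb <- helix_table(hs)
  expect_true(any(tb$i == 1 & tb$j == 12 & tb$k == 4))
  # random circles against the independent oracle
  for (seed in 1:25) {
    n <- 8 + (seed * 7) %% 23     # N in 8..30
    sq <- random_circle(n, seed, gc = seed %% 2 == 0)
    got <- as.matrix(helix_table(enumerate_saturated_helices(sq, 2)))
    want <- brute_saturated_helices(sq, 2)
    expect_equal(unname(got[, , drop = FALSE]) + 0, unname(want) + 0,
                 ignore_attr = TRUE,
                 label = sprintf("helices for %s", as.character(sq)))
  }
})

test_that("lone-pair mode agrees with the oracle too (inextensibility at min length 1)", {
  for (seed in 1:10) {
    sq <- random_circle(12 + seed, seed, gc = TRUE)
    got <- as.matrix(helix_table(enumerate_saturated_helices(sq, 1)))
    want <- brute_saturated_helices(sq, 1)
    expect_equal(unname(got[, , drop = FALSE]) + 0, unname(want) + 0,
                 ignore_attr = TRUE,
                 label = sprintf("helices (min 1) for %s",
                                 as.character(sq)))
  }
})

test_that("enumeration is invariant under cyclic rotation", {
  sq <- random_circle(17, 99, gc = TRUE)
  n <- sq$n
  base <- helix_table(enumerate_saturated_helices(sq, 2))
  canon_set <- function(tb, shift) {
    # shift positions back and re-canonicalize each (i, j, k)
    rows <- lapply(seq_len(nrow(tb)), function(r) {
      i <- circfold:::.cpos(tb$i[r] + shift, n)
      j <- circfold:::.cpos(tb$j[r] + shift, n)
      k <- tb$k[r]
      i2 <- circfold:::.cpos(j - k + 1L, n); j2 <- circfold:::.cpos(i + k - 1L, n)
      if (i2 < i || (i2 == i && j2 < j)) c(i2, j2, k) else c(i, j, k)
    })
    m <- do.call(rbind, rows)
    m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  for (s in c(1, 5, 11)) {
    rot <- helix_table(enumerate_saturated_helices(rotate_sequence(sq, s), 2))
    expect_identical(canon_set(rot, s), canon_set(base, 0))
  }
})

test_that("ranking orders by stability with deterministic ties and drops non-stable helices", {
  m <- load_parameters()
  expect_identical(rank_helices(list(), circ_sequence("AAAA"), m), list())
  sq <- circ_sequence("GGGGAAAACCCCAAAA")
  hs <- enumerate_saturated_helices(sq, 2)
  rk <- rank_helices(hs, sq, m)
  g <- vapply(rk, attr, numeric(1), "dG")
  expect_true(all(diff(g) >= 0))
  expect_true(all(g < 0))
  # the 4-pair helix outranks the shorter ones of identical stack make-up
  expect_identical(unclass(rk[[1]])[c("i", "j", "k")],
                   list(i = 1L, j = 12L, k = 4L))
  # order independence: shuffled input gives the same ranking
  shuffled <- circfold:::.with_seed(1, sample(hs))
  expect_identical(helix_table(rank_helices(shuffled, sq, m)),
                   helix_table(rk))
})

test_that("helix compatibility captures overlap and crossing on the circle", {
  expect_false(helices_compatible(helix(1, 12, 4), helix(3, 20, 2), 24))
  expect_false(helices_compatible(helix(1, 5, 1), helix(3, 8, 1), 10))
  # nested, disjoint helices are compatible
  expect_true(helices_compatible(helix(1, 20, 3), helix(6, 15, 3), 24))
  # symmetry over random helix pairs
  for (seed in 1:20) {
    hs <- circfold:::.with_seed(seed, list(
      helix(sample(24, 1), sample(24, 1), sample(3, 1)),
      helix(sample(24, 1), sample(24, 1), sample(3, 1))))
    a <- tryCatch(helices_compatible(hs[[1]], hs[[2]], 24),
                  error = function(e) NULL)
    b <- tryCatch(helices_compatible(hs[[2]], hs[[1]], 24),
                  error = function(e) NULL)
    if (!is.null(a) && !is.null(b)) expect_identical(a, b)
  }
  # origin-spanning crossing is detected on the circle, not the line
  expect_false(helices_compatible(helix(15, 4, 2), helix(2, 10, 1), 16))
  expect_true(helices_compatible(helix(15, 4, 2), helix(6, 13, 2), 16))
})
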