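test_that("parameter loading resolves temperature and the packaged table", {
  m <- load_parameters("turner2004", 37)
  expect_s3_class(m, "circfold_energy")
  expect_equal(m$temperature, 310.15)
  # packaged Turner value for the 5'GC/3'CG stack
  expect_equal(stack_free_energy(m, "GC", "CG"), -3.40, tolerance = 1e-9)
  expect_error(load_parameters("turner2004", 200), "temperature")
  expect_error(load_parameters("/no/such/file.par", 37), "not found")
})

test_that("a truncated parameter file fails loudly, naming the missing key", {
  src <- readLines(system.file("extdata", "turner2004.par",
                               package = "circfold"))
  drop <- grep("^GC/CG", src)
  tmp <- tempfile(fileext = ".par")
  writeLines(src[-drop], tmp)
  expect_error(load_parameters(tmp, 37), "GC/CG")
})

test_that("stack free energies are linear in T, symmetric, and vanish at dH/dS", {
  m37 <- load_parameters("turner2004", 37)
  m57 <- load_parameters("turner2004", 57)
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (p1 in pairs) for (p2 in pairs) {
    g37 <- stack_free_energy(m37, p1, p2)
    g57 <- stack_free_energy(m57, p1, p2)
    ds <- m37$stack_dS[substr(p1, 1, 1), substr(p1, 2, 2),
                       substr(p2, 1, 1), substr(p2, 2, 2)]
    # G(T2) - G(T1) = -dS * (T2 - T1) exactly
    expect_equal(g57 - g37, -20 * ds, tolerance = 1e-10)
    # strand-flip symmetry: outer (X,Y) inner (W,Z) == outer (Z,W) inner (Y,X)
    flip1 <- paste0(substr(p2, 2, 2), substr(p2, 1, 1))
    flip2 <- paste0(substr(p1, 2, 2), substr(p1, 1, 1))
    expect_equal(g37, stack_free_energy(m37, flip1, flip2), tolerance = 1e-10)
  }
  # root of the linear form: T = dH/dS makes the stack free energy zero
  dh <- m37$stack_dH["G", "C", "C", "G"]
  ds <- m37$stack_dS["G", "C", "C", "G"]
  t0 <- dh / ds - 273.15
  m0 <- load_parameters("turner2004", t0)
  expect_equal(stack_free_energy(m0, "GC", "CG"), 0, tolerance = 1e-9)
  expect_error(stack_free_energy(m37, "AA", "GC"), "not canonical")
})

test_that("loop energies follow the tables, the affine multiloop and the log extrapolation", {
  m <- load_parameters("turner2004", 37)
  expect_gte(loop_free_energy(m, loop_descriptor("hairpin", 2)), 1e5)
  expect_equal(loop_free_energy(m, loop_descriptor("hairpin", 3)), 5.4)
  a <- m$multiloop[1]; b <- m$multiloop[2]
  expect_equal(loop_free_energy(m, loop_descriptor("multiloop", 0, 3L)),
               a + 3 * b)
  # hand-computed Jacobson-Stockmayer evaluation for a size-40 hairpin
  expect_equal(loop_free_energy(m, loop_descriptor("hairpin", 40)),
               m$hairpin_g37[30] + 1.75 * m$kB * 310.15 * log(40 / 30),
               tolerance = 1e-9)
  # entropic rescaling at another temperature
  m2 <- load_parameters("turner2004", 57)
  expect_equal(loop_free_energy(m2, loop_descriptor("hairpin", 5)),
               (330.15 / 310.15) * m$hairpin_g37[5], tolerance = 1e-9)
  # non-decreasing in unpaired count from size 9 up, through the
  # tabulated/extrapolated boundary (the published tables themselves dip
  # at a few small sizes, e.g. the size-6 hairpin)
  for (kind in c("hairpin", "bulge", "internal")) {
    g <- vapply(9:60, function(s)
      loop_free_energy(m, loop_descriptor(kind, s)), numeric(1))
    expect_true(all(diff(g) >= -1e-9))
  }
  # exterior face re-classification
  expect_equal(loop_free_energy(m, loop_descriptor("circular_exterior", 0,
                                                   0L)), 0)
  expect_equal(loop_free_energy(m, loop_descriptor("circular_exterior", 4,
                                                   1L)),
               loop_free_energy(m, loop_descriptor("hairpin", 4)))
})

test_that("helix free energy is the sum of its stacks", {
  m <- load_parameters()
  sq <- circ_sequence("GGGGAAAACCCCAAAA")
  expect_equal(helix_free_energy(m, helix(1, 12, 1), sq), 0)
  g2 <- stack_free_energy(m, "GC", "GC")
  expect_equal(helix_free_energy(m, helix(1, 12, 3), sq), 2 * g2)
  # incremental property for k = 2..4
  for (k in 2:4)
    expect_equal(helix_free_energy(m, helix(1, 12, k), sq),
                 helix_free_energy(m, helix(1, 12, k - 1), sq) + g2,
                 tolerance = 1e-12)
  # same physical helix from either strand orientation
  expect_equal(helix_free_energy(m, helix(1, 12, 4), sq),
               helix_free_energy(m, helix(9, 4, 4), sq), tolerance = 1e-12)
  sq2 <- circ_sequence("GAGGAAAACCCCAAAA")
  expect_error(helix_free_energy(m, helix(1, 12, 3), sq2), "not canonical")
})
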