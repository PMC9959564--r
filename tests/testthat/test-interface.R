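test_that("sequence parsing normalizes, validates and caps input", {
  sq <- parse_sequence("acgu\nACGT")
  expect_equal(as.character(sq), "ACGUACGU")
  expect_equal(sq$n, 8)
  long <- paste(rep("A", 501), collapse = "")
  expect_error(parse_sequence(long), "500")
  expect_error(parse_sequence(">a\nACGU\n>b\nGGGG"), "one circular sequence")
  expect_error(parse_sequence("ACGX"), "position 4")
  fa <- parse_sequence(">myCirc test\nGGGG\nAAAA\nCCCC")
  expect_equal(fa$name, "myCirc test")
  expect_equal(fa$n, 12)
  # digits and whitespace from copy-pasted numbered text are stripped
  expect_equal(as.character(parse_sequence("1 GGGG\n2 aaaa")), "GGGGAAAA")
})

test_that("constraint validation accepts sound sets and rejects each violation distinctly", {
  sq <- circ_sequence("GGGGAAAACCCCAAAA")
  ok <- validate_constraints("HELIX 1 12 4", sq)
  expect_s3_class(ok, "circfold_constraints")
  expect_error(validate_constraints(c("HELIX 1 12 4", "LOOP 2 3"), sq),
               "claim position 2")
  sqx <- circ_sequence("GAAACAAUAAAAAAAA")
  expect_error(validate_constraints(c("HELIX 1 5 1", "HELIX 3 8 1"), sqx),
               "cross")
  expect_error(validate_constraints("HELIX 5 8 1", sq), "not canonical")
  expect_error(validate_constraints("HELIX 1 40 2", sq), "out of range")
  expect_error(validate_constraints("LOOP 1 40", sq), "longer than")
  expect_error(parse_constraints("HELIX 1 2"), "cannot parse")
})

test_that("prediction defaults, degenerate requests and determinism", {
  sq <- generate_fixture("hairpin_circle", 26)
  fit <- circfold(sq)
  expect_lte(length(fit$results), 5)
  expect_gte(length(fit$results), 1)
  # results sorted ascending by free energy
  g <- vapply(fit$results, `[[`, numeric(1), "free_energy")
  expect_true(all(diff(g) >= 0))
  fit1 <- circfold(sq, max_structures = 1)
  expect_length(fit1$results, 1)
  # byte-identical repeated runs
  t1 <- write_report(circfold(sq), "text")
  t2 <- write_report(circfold(sq), "text")
  expect_identical(t1, t2)
  j1 <- write_report(circfold(sq), "json")
  j2 <- write_report(circfold(sq), "json")
  expect_identical(as.character(j1), as.character(j2))
})

test_that("reports render and reparse across text, CT and JSON", {
  # open-circle-only report: N dots, energy zero
  fit0 <- circfold("AAAAAAAAAAAA")
  txt0 <- write_report(fit0, "text")
  row <- grep("^1 ", txt0, value = TRUE)
  expect_match(row, paste0("^1 ", strrep("\\.", 12), " 0\\.00"))
  fit <- circfold(generate_fixture("two_helix", 30), max_structures = 4)
  txt <- parse_report_text(write_report(fit, "text"))
  expect_equal(length(txt$structures), length(fit$results))
  for (r in seq_along(fit$results)) {
    expect_identical(txt$structures[[r]]$pairs, fit$results[[r]]$structure$pairs)
    expect_equal(txt$energies[r], fit$results[[r]]$free_energy,
                 tolerance = 5.1e-3)   # text carries 2 decimals
  }
  js <- jsonlite::fromJSON(write_report(fit, "json"), simplifyVector = FALSE)
  expect_equal(length(js$structures), length(fit$results))
  expect_equal(js$structures[[1]]$free_energy,
               fit$results[[1]]$free_energy, tolerance = 1e-9)
  ct <- write_report(fit, "ct")
  for (r in seq_along(ct)) {
    back <- read_ct(ct[[r]])
    expect_identical(back$structure$pairs, fit$results[[r]]$structure$pairs)
    expect_equal(back$energy, round(fit$results[[r]]$free_energy, 2))
    expect_equal(back$sequence, as.character(fit$sequence))
  }
})

test_that("origin-spanning pairing is preserved by the CT writer and flagged in text", {
  # force a helix whose pair run wraps the origin: (19,7), (20,6), (1,5)
  sq <- circ_sequence("GAAACCCAAAAAAAAAAAGG")
  fit <- circfold(sq, constraints = "HELIX 19 7 3", max_structures = 1,
                  control = fold_control(closing = "all"))
  expect_gte(length(fit$results), 1)
  st <- fit$results[[1]]$structure
  expect_true(contains_helix(st, helix(19, 7, 3), 20))
  expect_true(origin_spanning(st))
  txt <- write_report(fit, "text")
  expect_true(any(grepl("origin", txt)))
  ct <- write_report(fit, "ct")[[1]]
  back <- read_ct(ct)
  expect_identical(back$structure$pairs, st$pairs)
  # circular backbone: position N connects forward to position 1
  lastrow <- strsplit(trimws(ct[length(ct)]), "[[:space:]]+")[[1]]
  expect_equal(as.integer(lastrow[4]), 1)
})

test_that("fixture generators plant what they claim", {
  sq16 <- generate_fixture("hairpin_circle", 16)
  expect_equal(as.character(sq16), "GGGGAAAACCCCAAAA")
  ann <- attr(sq16, "annotation")[[1]]
  expect_identical(unclass(ann)[c("i", "j", "k")],
                   list(i = 1L, j = 12L, k = 4L))
  # the planted stem is a saturated helix of the generated circle
  tb <- helix_table(enumerate_saturated_helices(sq16))
  expect_true(any(tb$i == ann$i & tb$j == ann$j & tb$k == ann$k))
  # seeded determinism
  expect_identical(as.character(generate_fixture("random", 12, seed = 1)),
                   as.character(generate_fixture("random", 12, seed = 1)))
  expect_false(identical(as.character(generate_fixture("random", 12, 1)),
                         as.character(generate_fixture("random", 12, 2))))
  # two_helix plants two mutually compatible helices
  sq <- generate_fixture("two_helix", 28)
  ann2 <- attr(sq, "annotation")
  expect_length(ann2, 2)
  expect_true(helices_compatible(ann2[[1]], ann2[[2]], sq$n))
  tb2 <- helix_table(enumerate_saturated_helices(sq))
  for (h in ann2)
    expect_true(any(tb2$i == h$i & tb2$j == h$j & tb2$k == h$k))
})
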