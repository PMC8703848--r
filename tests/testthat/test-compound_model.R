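test_that("standard CSV parses into records with normalized labels", {
  ds <- suppressWarnings(read_compound_table(fixture_standard()))
  expect_s3_class(ds, "compound_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$bbb_label, c("BBB_plus", "BBB_minus", "BBB_plus"))
  expect_equal(ds$charge_class, c("neutral", "positive", "negative"))
})

test_that("unparseable numeric cells become absent descriptors with a warning", {
  expect_warning(ds <- read_compound_table(fixture_standard()),
                 "unparseable 'ccs'")
  expect_true(is.na(ds$ccs[3]))
  expect_equal(nrow(ds), 3L)         # the row itself is kept
  expect_equal(ds$mw[3], 95)         # other descriptors intact
})

test_that("ccsbase_batch dialect demands a smiles column; empty files error", {
  no_smiles <- write_fixture_csv(c("id,ccs", "a,100"))
  expect_error(read_compound_table(no_smiles, dialect = "ccsbase_batch"),
               "smiles")
  empty <- write_fixture_csv("id,smiles,ccs")
  expect_error(read_compound_table(empty), "empty dataset")
  only_smiles <- write_fixture_csv(c("smiles", "CCO", "c1ccccc1"))
  ds <- read_compound_table(only_smiles, dialect = "ccsbase_batch")
  expect_equal(nrow(ds), 2L)
})

test_that("optional SMILES validation drops and counts erroneous rows", {
  p <- write_fixture_csv(c("id,smiles,ccs",
                           "a,CCO,150", "b,CC(=O,160", "c,C1CC,170"))
  expect_warning(ds <- read_compound_table(p, validate_smiles = TRUE),
                 "erroneous SMILES")
  expect_equal(ds$id, "a")   # unbalanced paren and unpaired ring digit dropped
})

test_that("dataset_summary reproduces printed library ratios", {
  mk <- function(np, nm) {
    compound_dataset(data.frame(
      id = seq_len(np + nm),
      bbb_label = c(rep("BBB+", np), rep("BBB-", nm))))
  }
  expect_equal(dataset_summary(mk(1282, 310))$ratio, 4.1)
  expect_equal(dataset_summary(mk(327, 35))$ratio, 9.3)
  expect_equal(dataset_summary(mk(100, 100))$ratio, 1.0)
  s <- dataset_summary(tiny_dataset())
  expect_equal(s$n_plus + s$n_minus + s$n_unknown, s$n_total)
  # no negatives -> ratio undefined
  expect_true(is.na(dataset_summary(mk(5, 0) )$ratio))
})

test_that("ratio inversion property holds within rounding", {
  set.seed(11)
  for (i in 1:20) {
    np <- sample(10:2000, 1); nm <- sample(10:2000, 1)
    r <- np / nm
    expect_equal(round(r, 1), round(1 / round(1 / r, 6), 1))
  }
})

test_that("write_predictions round-trips through read_compound_table", {
  ds <- suppressWarnings(read_compound_table(fixture_standard()))
  preds <- classify_dataset(ds, ccs200_rule())
  out <- tempfile(fileext = ".csv")
  write_predictions(ds, preds, out)
  back <- read_compound_table(out)
  expect_equal(back$id, ds$id)
  expect_equal(back$mw, ds$mw, tolerance = 1e-12)
  expect_equal(back$ccs, ds$ccs, tolerance = 1e-12)
  expect_true("predicted" %in% names(back))
})

test_that("misaligned predictions raise an alignment error", {
  ds <- suppressWarnings(read_compound_table(fixture_standard()))
  preds <- classify_dataset(ds, ccs200_rule())[-1, ]
  expect_error(write_predictions(ds, preds, tempfile()), "alignment error")
})

test_that("duplicate ids and negative physical descriptors are rejected", {
  expect_error(compound_dataset(data.frame(id = c("a", "a"))), "unique")
  expect_error(compound_dataset(data.frame(id = "a", ccs = -5)),
               "non-negative")
})
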