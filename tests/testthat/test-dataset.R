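make_toy_table <- function(path, rows = NULL) {
  rows <- rows %||% data.frame(
    structure_ref = c("S1", "S1", "S2"),
    chain = "A",
    mutation = c("R273C", "notamut", "D10K"),
    na_type = c("dsDNA", "dsDNA", "RNA"),
    ddg_exp = c(-1.2, 0.5, 0.8),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("read_dataset validates rows and reports rejections", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_toy_table(path)
  msgs <- capture_messages(rec <- read_dataset(path))
  expect_equal(nrow(rec), 2)
  expect_true(any(grepl("row 2 rejected", msgs)))
  expect_equal(rec$direction, c("forward", "forward"))
  smry <- attr(rec, "summary")
  expect_equal(smry$n, 2)
  expect_equal(smry$n_reducing, 1)
})

test_that("missing mandatory columns are an error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(structure_ref = "S1", chain = "A", mutation = "R1C")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_dataset(path)), "na_type")
})

test_that("column mapping adapts foreign headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(PDB = "S1", chain = "A", mutation = "R1C",
                    na_type = "RNA", DDG = -0.4)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_dataset(path, col_map = c(
    PDB = "structure_ref", DDG = "ddg_exp")))
  expect_equal(rec$structure_ref, "S1")
  expect_equal(rec$ddg_exp, -0.4)
})

test_that("reverse augmentation negates ddG and swaps residues", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_toy_table(path)
  rec <- suppressMessages(read_dataset(path))
  aug <- augment_reverse(rec)
  expect_equal(nrow(aug), 4)
  fwd <- aug[aug$direction == "forward", ]
  rev <- aug[aug$direction == "reverse", ]
  expect_equal(rev$mutation[fwd$mutation == "R273C"], "C273R")
  expect_equal(rev$ddg_exp, -fwd$ddg_exp)
  expect_equal(rev$partner_id, fwd$partner_id)
  # augmenting twice is rejected
  expect_error(augment_reverse(aug), "forward records only")
})

test_that("augmentation with modelled mutant structures flags them", {
  rec <- data.frame(structure_ref = "S1", chain = "A", mutation = "R2C",
                    na_type = "RNA", ddg_exp = -1, direction = "forward",
                    partner_id = 1, stringsAsFactors = FALSE)
  aug <- augment_reverse(rec, mutant_structures = c("S1:R2C" = "S1_R2C"))
  rev <- aug[aug$direction == "reverse", ]
  expect_equal(rev$structure_ref, "S1_R2C")
  expect_true(rev$modeled)
})

test_that("the augmented ddG distribution is exactly symmetric", {
  tab <- generate_training_table(seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_dataset(path))
  aug <- augment_reverse(rec)
  expect_equal(mean(aug$ddg_exp), 0, tolerance = 1e-12)
  expect_equal(sum(aug$ddg_exp < 0), sum(aug$ddg_exp > 0))
})

test_that("fold assignment balances pairs, keeps partners, reproduces", {
  tab <- generate_training_table(seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_dataset(path))
  aug <- augment_reverse(rec)
  folds <- make_folds(aug, k = 10, seed = 31)
  # pair-level fold sizes within one of each other: 331 pairs -> 33/34
  pair_folds <- tapply(folds, aug$partner_id, unique)
  expect_true(all(lengths(pair_folds) == 1))  # partners never split
  sizes <- table(unlist(pair_folds))
  expect_true(all(sizes %in% c(33, 34)))
  expect_identical(folds, make_folds(aug, k = 10, seed = 31))
  expect_false(identical(folds, make_folds(aug, k = 10, seed = 32)))
  expect_error(make_folds(aug, k = 1000, seed = 1), "exceeds")
})

test_that("structure-grouped folds keep complexes together", {
  tab <- generate_training_table(seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- suppressMessages(read_dataset(path))
  folds <- make_folds(rec, k = 5, seed = 1, by_structure = TRUE)
  per_struct <- tapply(folds, rec$structure_ref, unique)
  expect_true(all(lengths(per_struct) == 1))
})

test_that("datasets round-trip through write and read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_toy_table(path)
  rec <- suppressMessages(read_dataset(path))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(rec, path2)
  rec2 <- suppressMessages(read_dataset(path2))
  for (col in c("structure_ref", "chain", "mutation", "na_type", "ddg_exp"))
    expect_equal(rec2[[col]], rec[[col]], info = col)
})
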