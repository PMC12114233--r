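test_that("docking CSV reading builds the score matrix with explicit missing entries", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,structure_id,docking_score",
               "a,S1,-9.1", "a,S2,-8.7", "a,S3,-10.0"), f)
  tab <- read_docking_csv(f)
  expect_equal(dim(tab$scores), c(1L, 3L))
  expect_equal(n_missing(tab), 0L)
  expect_equal(unname(tab$scores["a", "S2"]), -8.7)

  # 5 compounds x 5 structures with 2 absent pairs
  grid <- expand.grid(compound_id = paste0("c", 1:5),
                      structure_id = paste0("S", 1:5))
  grid$docking_score <- -8 - seq_len(nrow(grid)) / 10
  grid <- grid[-c(3, 17), ]
  utils::write.csv(grid, f, row.names = FALSE, quote = FALSE)
  tab <- read_docking_csv(f)
  expect_equal(n_missing(tab), 2L)
})

test_that("duplicate (compound, structure) rows are rejected by name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,structure_id,docking_score",
               "a,S1,-9.1", "a,S1,-9.2"), f)
  expect_error(read_docking_csv(f), "duplicate.*a, S1")
})

test_that("score table CSV round trip preserves entries and missing positions", {
  m <- matrix(c(-9.25, NA, -8.5, -10, -7.75, NA), 3, 2,
              dimnames = list(c("x", "y", "z"), c("S1", "S2")))
  tab <- score_table(m)
  f <- withr::local_tempfile(fileext = ".csv")
  write_docking_csv(tab, f)
  back <- read_docking_csv(f)
  expect_identical(back$scores[tab$compounds, tab$structures], tab$scores)
})

test_that("schema mapping adapts foreign column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mol,target,glide_gscore", "a,S1,-9.1"), f)
  tab <- read_docking_csv(f, schema = c(compound_id = "mol",
                                        structure_id = "target",
                                        docking_score = "glide_gscore"))
  expect_equal(unname(tab$scores["a", "S1"]), -9.1)
})

test_that("SMILES list reading preserves ids and skips unparseable molecules", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", "CC(=O)O acetic"), f)
  rec <- read_molecules(f, "smiles_list")
  expect_equal(rec$compound_id, c("benzene", "ethanol", "acetic"))

  writeLines(c("c1ccccc1 ok1", "not@a@smiles))) bad", "CCO ok2"), f)
  expect_message(rec <- read_molecules(f, "smiles_list"), "1 unparseable")
  expect_equal(nrow(rec), 2L)

  writeLines(character(), f)
  expect_equal(nrow(read_molecules(f, "smiles_list")), 0L)
})

test_that("SDF files read into compound records with ids preserved", {
  sdf <- ChemmineR::smiles2sdf(c(mol_a = "CCO", mol_b = "c1ccccc1"))
  f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  rec <- read_molecules(f, "sdf")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$compound_id, c("mol_a", "mol_b"))
  expect_equal(canonical_smiles(rec$smiles[rec$compound_id == "mol_a"]),
               canonical_smiles("CCO"), ignore_attr = TRUE)
})

test_that("activity labeling follows the strict pChEMBL > 8 rule and drops straddlers", {
  rec <- compound_records(c("a", "b", "c", "d"),
                          pchembl_values = list(9.1, c(7.0, 7.5),
                                                c(7.5, 8.5), 8.0))
  lab <- label_activity(rec, threshold = 8.0)
  expect_equal(lab$compound_id, c("a", "b", "d"))
  expect_equal(lab$activity_label, c(1L, 0L, 0L))  # exactly 8.0 -> inactive
  expect_equal(attr(lab, "dropped"), "c")

  # idempotent and order-independent
  again <- label_activity(lab)
  expect_equal(again$activity_label, lab$activity_label)
  shuf <- label_activity(rec[c(3, 1, 4, 2), ])
  expect_equal(shuf$activity_label[order(shuf$compound_id)],
               lab$activity_label[order(lab$compound_id)])
})

test_that("labeling errors on compounds without activity values", {
  rec <- compound_records(c("a", "b"), pchembl_values = list(9, numeric()))
  expect_error(label_activity(rec), "without pChEMBL")
})

test_that("multi-activity filtering keeps only single-valued compounds", {
  rec <- compound_records(c("a", "b", "c"),
                          pchembl_values = list(9, c(9, 9.5), 7))
  expect_equal(drop_multi_activity(rec)$compound_id, c("a", "c"))
  expect_equal(nrow(drop_multi_activity(rec[c(2, 2), ][1, ])), 0L)
  single <- compound_records("x", pchembl_values = list(5))
  expect_equal(drop_multi_activity(single), single)
})

test_that("merge_by_id collapses repeated measurements into one record", {
  df <- data.frame(compound_id = c("a", "b", "a"), pchembl = c(9, 7, 9.5))
  rec <- merge_by_id(df)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pchembl_values[[1]], c(9, 9.5))
})

test_that("stratified folds are balanced, disjoint, exhaustive and deterministic", {
  labels <- setNames(rep(c(1, 0), c(10, 40)), paste0("c", 1:50))
  sp <- stratified_folds(labels, k = 5, seed = 42)
  per_fold_active <- tapply(labels[names(sp$fold_assignments)],
                            sp$fold_assignments, sum)
  expect_true(all(per_fold_active == 2))
  per_fold_n <- table(sp$fold_assignments)
  expect_true(all(per_fold_n == 10))
  expect_setequal(names(sp$fold_assignments), names(labels))

  sp2 <- stratified_folds(labels, k = 5, seed = 42)
  expect_identical(sp$fold_assignments, sp2$fold_assignments)
  sp3 <- stratified_folds(labels, k = 5, seed = 43)
  expect_false(identical(sp$fold_assignments, sp3$fold_assignments))

  # pigeonhole: 7 actives over 5 folds -> active counts in {1, 2}
  labels7 <- setNames(rep(c(1, 0), c(7, 43)), paste0("c", 1:50))
  sp7 <- stratified_folds(labels7, k = 5, seed = 1)
  act <- tapply(labels7[names(sp7$fold_assignments)],
                sp7$fold_assignments, sum)
  expect_true(all(act %in% 1:2))
  expect_lte(max(act) - min(act), 1)
})

test_that("stratified folds reject an underfilled class", {
  labels <- setNames(rep(c(1, 0), c(3, 40)), paste0("c", 1:43))
  expect_error(stratified_folds(labels, k = 5, seed = 1), "cannot fill")
})
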