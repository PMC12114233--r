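test_that("stereocenter inversion flips parity and is an involution", {
  out <- invert_stereocenter("C[C@H](N)O", 2)
  expect_identical(out, "C[C@@H](N)O")
  # the two parities are genuinely different molecules
  expect_false(canonical_smiles("C[C@H](N)O") == canonical_smiles(out))
  # double inversion returns the canonical input
  back <- invert_stereocenter(out, 2)
  expect_identical(canonical_smiles(back), canonical_smiles("C[C@H](N)O"))

  # inversion inside a sugar ring (C5-like center of the library template)
  smi <- sprintf("OC[C@H]1O[C@@H](c2cc(Cl)ccc2Cc2ccc(OCC)cc2)[C@H](O)[C@@H](O)[C@@H]1O")
  inv <- invert_stereocenter(smi, 3)           # the [C@H]1 ring carbon
  expect_false(canonical_smiles(inv) == canonical_smiles(smi))
  expect_identical(canonical_smiles(invert_stereocenter(inv, 3)),
                   canonical_smiles(smi))
})

test_that("inverting a non-stereocenter or out-of-range atom errors", {
  expect_error(invert_stereocenter("C[C@H](N)O", 1), "not a defined")
  expect_error(invert_stereocenter("CCO", 2), "not a defined")
  expect_error(invert_stereocenter("CCO", 9), "out of range")
})

test_that("the paired t-test reproduces a hand-computed example", {
  r <- c(-9.0, -9.5, -9.8)
  s <- r + c(-0.1, -0.3, -0.2)
  res <- paired_score_test(r, s)
  expect_equal(res$mean_diff, -0.2)
  expect_equal(res$t_statistic, -3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0741799, tolerance = 1e-5)
  expect_equal(res$ci95, c(-0.4484138, 0.0484138), tolerance = 1e-6)
  expect_equal(res$median_R, -9.5)
})

test_that("the paired test is antisymmetric in its libraries", {
  set.seed(33)
  r <- rnorm(40, -9.5, 0.8)
  s <- r + rnorm(40, 0.26, 0.6)
  ab <- paired_score_test(r, s)
  ba <- paired_score_test(s, r)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$ci95, -rev(ba$ci95))
})

test_that("degenerate paired inputs are rejected informatively", {
  r <- c(-9, -10, -8)
  expect_error(paired_score_test(r, r + 0.26), "degenerate.*0.26")
  expect_error(paired_score_test(r, r[1:2]), "equal length")
  expect_error(paired_score_test(-9, -9.2), "at least 2")
})

test_that("interaction loss tally reports columns above the cutoff, descending", {
  cols <- c("GLU99:hbond_acceptor", "LYS321:hbond_donor", "SER287:polar")
  mR <- matrix(0L, 12, 3, dimnames = list(paste0("l", 1:12), cols))
  mS <- mR
  mR[1:10, 1] <- 1L; mS[1:3, 1] <- 1L     # loss 7
  mR[1:6, 2] <- 1L;  mS[1:5, 2] <- 1L     # loss 1
  mR[1:2, 3] <- 1L;  mS[1:2, 3] <- 1L     # loss 0
  tally <- interaction_loss_tally(mR, mS, min_loss = 5)
  expect_equal(tally$losses$column, "GLU99:hbond_acceptor")
  expect_equal(tally$losses$loss_count, 7L)
  expect_equal(tally$losses$loss_fraction, 7 / 12)
  expect_equal(unname(tally$column_diff), c(7, 1, 0))

  # identical matrices -> nothing to report
  empty <- interaction_loss_tally(mR, mR)
  expect_equal(nrow(empty$losses), 0L)
  expect_equal(nrow(empty$gains), 0L)

  # a column gained in S goes to the gains log, never the loss report
  mS2 <- mS; mS2[1:8, 3] <- 1L            # gain 6 in SER287
  tally2 <- interaction_loss_tally(mR, mS2, min_loss = 5)
  expect_false("SER287:polar" %in% tally2$losses$column)
  expect_equal(tally2$gains$column, "SER287:polar")
  expect_equal(tally2$gains$gain_count, 6L)
})

test_that("loss/gain totals are conserved against the matrix totals", {
  for (s in 1:10) {
    cols <- sprintf("RES%d:type%d", 1:6, rep(1:2, 3))
    lp <- setNames(runif(3), sample(cols, 3))
    sim <- simulate_interaction_matrices(80, cols, lp, seed = s)
    tally <- interaction_loss_tally(sim$matrix_R, sim$matrix_S, min_loss = 0)
    diff_total <- sum(sim$matrix_R) - sum(sim$matrix_S)
    expect_equal(sum(tally$column_diff), diff_total)
    losses_all <- sum(tally$column_diff[tally$column_diff > 0])
    gains_all <- sum(-tally$column_diff[tally$column_diff < 0])
    expect_equal(losses_all - gains_all, diff_total)
  }
})

test_that("interaction matrices round-trip through CSV", {
  cols <- c("GLU99:hbond_acceptor", "LEU283:hydrophobic")
  sim <- simulate_interaction_matrices(15, cols,
                                       c("GLU99:hbond_acceptor" = 0.4),
                                       seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_interaction_csv(sim$matrix_R, f)
  expect_identical(read_interaction_csv(f), sim$matrix_R)
})

test_that("column-set mismatches are rejected", {
  m1 <- matrix(0L, 2, 1, dimnames = list(NULL, "A:x"))
  m2 <- matrix(0L, 2, 1, dimnames = list(NULL, "B:y"))
  expect_error(interaction_loss_tally(m1, m2), "different column sets")
})
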