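test_that("calibration closed-form cases hold", {
  # single reference with S = 1: DSj = DSj0 * (dG / DS)
  S <- matrix(1, 1, 1)
  expect_equal(calibrate_scores(-9, -8, 8, S, p = 7),
               structure(-9 * (8 / -8), uncalibrated = integer(0)))

  # constant activity/score ratio c: DSj = c * DSj0 for every query,
  # independent of p and of the similarity values
  set.seed(2)
  q <- runif(6, -11, -7)
  r_scores <- runif(10, -11, -7)
  r_act <- -0.9 * r_scores                 # ratio fixed at -0.9... / DS
  ratio <- r_act[1] / r_scores[1]
  S2 <- matrix(runif(60, 0.05, 1), 6, 10)
  for (p in c(1, 4, 20)) {
    out <- calibrate_scores(q, r_scores, r_act, S2, p)
    expect_equal(as.numeric(out), ratio * q, tolerance = 1e-12)
  }

  # high-p dominance: weight collapses onto the most similar reference
  S3 <- matrix(c(0.9, 0.3), 1, 2)
  out <- calibrate_scores(-9, c(-8, -10), c(8, 5), S3, p = 60)
  expect_equal(as.numeric(out), -9 * (8 / -8), tolerance = 1e-6)
})

test_that("calibration matches the naive double-loop oracle", {
  set.seed(44)
  for (r in 1:20) {
    nq <- sample(3:8, 1)
    nr <- sample(5:20, 1)
    q <- runif(nq, -12, -6)
    rs <- runif(nr, -12, -6)
    ra <- runif(nr, 4, 10)
    S <- matrix(runif(nq * nr), nq, nr)
    p <- sample(c(1, 4, 12, 28, 60), 1)
    expect_equal(as.numeric(calibrate_scores(q, rs, ra, S, p)),
                 brute_calibrate(q, rs, ra, S, p), tolerance = 1e-10)
  }
})

test_that("duplicating a reference doubles its weight term", {
  set.seed(8)
  q <- runif(4, -11, -7)
  rs <- runif(6, -11, -7)
  ra <- runif(6, 4, 10)
  S <- matrix(runif(24, 0.1, 0.9), 4, 6)
  dup <- c(seq_len(6), 3)                      # reference 3 twice
  out_dup <- calibrate_scores(q, rs[dup], ra[dup], S[, dup], p = 5)
  expect_equal(as.numeric(out_dup),
               brute_calibrate(q, rs[dup], ra[dup], S[, dup], 5),
               tolerance = 1e-12)
  # and reference order never matters
  perm <- sample(6)
  out_perm <- calibrate_scores(q, rs[perm], ra[perm], S[, perm], p = 5)
  expect_equal(as.numeric(out_perm),
               as.numeric(calibrate_scores(q, rs, ra, S, p = 5)),
               tolerance = 1e-12)
})

test_that("negative docking scores with positive activities calibrate positive", {
  set.seed(10)
  q <- runif(20, -12, -6)
  rs <- runif(30, -12, -6)
  ra <- runif(30, 4, 10)                       # pChEMBL scale
  S <- matrix(runif(600, 0.01, 1), 20, 30)
  out <- calibrate_scores(q, rs, ra, S, p = 12)
  expect_true(all(out > 0))
})

test_that("zero-weight queries pass through uncalibrated with a flag", {
  S <- matrix(c(0, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_warning(out <- calibrate_scores(c(-9, -10), c(-8, -8), c(8, 9),
                                         S, p = 4),
                 "uncalibrated")
  expect_equal(out[[1]], -9)
  expect_equal(attr(out, "uncalibrated"), 1L)
})

test_that("zero reference scores and shape mismatches are rejected", {
  expect_error(calibrate_scores(-9, c(-8, 0), c(8, 9), matrix(1, 1, 2), 4),
               "excluded")
  expect_error(calibrate_scores(c(-9, -8), -8, 8, matrix(1, 1, 1), 4),
               "dimension")
})

test_that("the most-similar reference's weight share grows with p", {
  s <- c(0.8, 0.6, 0.3)
  share <- vapply(c(1, 2, 4, 8, 16, 32), function(p)
    s[1]^p / sum(s^p), 0)
  expect_true(all(diff(share) > 0))
  # mirrored through the API: calibrated value approaches the best
  # reference's single-term value
  q <- -9; rs <- c(-8, -9, -10); ra <- c(9, 7, 5)
  vals <- vapply(c(4, 12, 28, 60), function(p)
    as.numeric(calibrate_scores(q, rs, ra, matrix(s, 1, 3), p)), 0)
  target <- q * ra[1] / rs[1]
  expect_true(all(diff(abs(vals - target)) <= 1e-12))
})

test_that("cross-validated grid search is deterministic and spans 8 exponents", {
  lib <- simulate_library_smiles(90, seed = 5)
  lib <- label_activity(lib)
  set.seed(60)
  score <- -5 - 0.5 * lib$pchembl + rnorm(nrow(lib), 0, 1.1)
  rec <- data.frame(compound_id = lib$compound_id, smiles = lib$smiles,
                    score = score, pchembl = lib$pchembl,
                    activity_label = lib$activity_label)
  r1 <- cross_validate_calibration(rec, cfg = list(seed = 9))
  expect_equal(nrow(r1$per_p), 8L)
  expect_equal(r1$per_p$p, seq(4L, 60L, by = 8L))
  expect_equal(r1$final_threshold,
               mean(r1$fold_detail[[as.character(r1$best_p)]]$thresholds))
  r2 <- cross_validate_calibration(rec, cfg = list(seed = 9))
  expect_identical(r1$per_p, r2$per_p)
  expect_identical(r1$best_p, r2$best_p)
  expect_identical(r1$folds$fold_assignments, r2$folds$fold_assignments)
})

test_that("external application respects disjointness and the dominance limit", {
  lib <- simulate_library_smiles(80, seed = 6)
  lib <- label_activity(lib)
  set.seed(61)
  lib$score <- -5 - 0.5 * lib$pchembl + rnorm(nrow(lib), 0, 1.1)
  ref <- lib[1:60, ]
  ext <- lib[61:nrow(lib), ]
  res <- apply_final_model(
    data.frame(compound_id = ext$compound_id, smiles = ext$smiles,
               score = ext$score, activity_label = ext$activity_label),
    final_threshold = 8,
    reference_records = data.frame(compound_id = ref$compound_id,
                                   smiles = ref$smiles, score = ref$score,
                                   pchembl = ref$pchembl))
  expect_s3_class(res$counts, "confusion_counts")
  expect_true(is.finite(res$mcc) && is.finite(res$ba))
  expect_equal(res$counts$tp + res$counts$tn + res$counts$fp + res$counts$fn,
               nrow(ext))

  expect_error(apply_final_model(
    data.frame(compound_id = ref$compound_id[1], smiles = ref$smiles[1],
               score = -9, activity_label = 1),
    8, data.frame(compound_id = ref$compound_id, smiles = ref$smiles,
                  score = ref$score, pchembl = ref$pchembl)),
    "overlap")
  expect_error(apply_final_model(ref[0, ], 8, ref), "empty")

  # an external compound structurally identical to a reference compound is
  # dominated by it at high p
  ext1 <- data.frame(compound_id = "query_dup", smiles = ref$smiles[1],
                     score = -9.3, activity_label = 1)
  res1 <- apply_final_model(ext1, 8, data.frame(
    compound_id = ref$compound_id, smiles = ref$smiles,
    score = ref$score, pchembl = ref$pchembl), best_p = 60L)
  # compare against single-term value unless other exact duplicates share S=1
  fp_all <- compute_fingerprints(c(ref$smiles[1], ref$smiles),
                                 ids = c("q", ref$compound_id))
  S <- tanimoto_matrix(fp_all["q", , drop = FALSE], fp_all[-1, , drop = FALSE])
  top <- S[1, ] > 1 - 1e-12
  expected <- -9.3 * mean(ref$pchembl[top] / ref$score[top])
  expect_equal(unname(res1$calibrated), expected, tolerance = 1e-6)
})
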