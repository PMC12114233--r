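# Fragment pools for the combinatorial gliflozin-like library generator.
# Template: glucose nucleus C-linked at C1 to a substituted central aromatic
# ring, methylene bridge, distal aromatic ring with a second substituent.
gliflozin_template <- "OC[C@H]1O[C@@H](c2cc(%s)ccc2Cc2ccc(%s)cc2)[C@H](O)[C@@H](O)[C@@H]1O"
gliflozin_substituents <- c(
  "F", "Cl", "Br", "I", "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC",
  "OC(C)C", "C#N", "C(F)(F)F", "N", "N(C)C", "CO", "S(C)(=O)=O")

#' Configuration for the two-class multi-structure score simulator
#'
#' Class-conditional score distributions are Gaussian per structure; scores
#' of the same compound across structures share a latent "true affinity"
#' component, so their pairwise correlation equals `rho`.
#'
#' @param n_active,n_inactive compounds per class.
#' @param mu_active,mu_inactive class mean scores (docking-score units;
#'   lower = stronger predicted binding).
#' @param sigma within-class standard deviation (> 0).
#' @param n_structures number of pseudo-structures.
#' @param rho inter-structure score correlation in \[0, 1).
#' @param dropout_rate probability a (compound, structure) score is missing.
#' @param seed integer seed.
#' @return validated config list of class `score_sim_config`.
#' @export
score_sim_config <- function(n_active = 200L, n_inactive = 600L,
                             mu_active = -10, mu_inactive = -8, sigma = 1,
                             n_structures = 5L, rho = 0.3,
                             dropout_rate = 0, seed = 1L) {
  stopifnot(sigma > 0, rho >= 0, rho < 1,
            dropout_rate >= 0, dropout_rate < 1,
            n_active >= 1, n_inactive >= 1, n_structures >= 1)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 mu_active = mu_active, mu_inactive = mu_inactive,
                 sigma = sigma, n_structures = as.integer(n_structures),
                 rho = rho, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "score_sim_config")
}

#' Simulate a two-class multi-structure docking score table
#'
#' Each compound draws a latent affinity deviation shared by all structures
#' plus independent per-structure noise; `rho` sets the variance split, so
#' the correlation between any two structure columns is `rho` while every
#' column is Gaussian with the configured class mean and SD `sigma`.
#' Missing entries (failed docks) are placed i.i.d. at `dropout_rate`.
#'
#' @param cfg a [score_sim_config].
#' @return list with `table` (a [score_table]) and `labels` (named 0/1
#'   vector, 1 = active).
#' @export
simulate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "score_sim_config"))
  n <- cfg$n_active + cfg$n_inactive
  ids <- sprintf("cmpd_%05d", seq_len(n))
  labels <- stats::setNames(rep(c(1L, 0L), c(cfg$n_active, cfg$n_inactive)),
                            ids)
  mu <- ifelse(labels == 1L, cfg$mu_active, cfg$mu_inactive)
  m <- with_seed(cfg$seed, {
    z <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * cfg$n_structures), n, cfg$n_structures)
    sc <- mu + cfg$sigma * (sqrt(cfg$rho) * z +
                              sqrt(1 - cfg$rho) * e)
    if (cfg$dropout_rate > 0)
      sc[stats::runif(length(sc)) < cfg$dropout_rate] <- NA_real_
    sc
  })
  dimnames(m) <- list(ids, sprintf("struct_%d", seq_len(cfg$n_structures)))
  list(table = score_table(m), labels = labels)
}

#' Simulate a gliflozin-like SMILES library with an activity signal
#'
#' Molecules are built combinatorially from a glucose-nucleus template and
#' two aromatic-ring substituent pools, so fingerprint similarity has
#' interpretable structure. Each substituent carries a latent activity
#' effect; a compound's pChEMBL value is the base activity plus its two
#' fragment effects plus measurement noise. Compounds sharing fragments
#' therefore have correlated activities -- the neighborhood signal the
#' similarity calibration exploits.
#'
#' @param n number of compounds.
#' @param seed integer seed.
#' @param base_pchembl library-mean activity (default 7.8, just below the
#'   activity threshold so both classes are well populated).
#' @param fragment_sd SD of per-fragment activity effects (default 0.8).
#' @param noise_sd per-measurement noise SD (default 0.25).
#' @return compound-record data frame with `compound_id`, `smiles`,
#'   `pchembl_values` (single values) and a `pchembl` convenience column;
#'   the sampled fragment indices are attached as attribute `"fragments"`.
#' @export
simulate_library_smiles <- function(n, seed, base_pchembl = 7.8,
                                    fragment_sd = 0.8, noise_sd = 0.25) {
  if (n == 0L) return(empty_records())
  subs <- gliflozin_substituents
  k <- length(subs)
  dat <- with_seed(seed, {
    eff1 <- stats::rnorm(k, 0, fragment_sd)
    eff2 <- stats::rnorm(k, 0, fragment_sd)
    i1 <- sample.int(k, n, replace = TRUE)
    i2 <- sample.int(k, n, replace = TRUE)
    pch <- base_pchembl + eff1[i1] + eff2[i2] + stats::rnorm(n, 0, noise_sd)
    list(i1 = i1, i2 = i2, pch = pch)
  })
  smi <- sprintf(gliflozin_template, subs[dat$i1], subs[dat$i2])
  rec <- compound_records(sprintf("lig_%05d", seq_len(n)), smiles = smi,
                          pchembl_values = as.list(dat$pch))
  rec$pchembl <- dat$pch
  attr(rec, "fragments") <- data.frame(s1 = dat$i1, s2 = dat$i2)
  rec
}

#' Configuration for the paired stereoisomer score simulator
#'
#' Defaults emulate a 291-pair comparison of R- versus S-configured sugar
#' moieties where the disadvantaged S configuration scores on average 0.26
#' score units weaker, with a per-pair shift SD of 0.65 (implied by a 95%
#' CI of width 0.15 around the mean difference at that sample size).
#'
#' @param n_pairs number of index-aligned molecule pairs.
#' @param delta mean score shift of the disadvantaged configuration
#'   (positive = weaker binding).
#' @param sigma_pair SD of the per-pair shift (>= 0).
#' @param mu_R,sigma_R mean and SD of the reference (R) library scores.
#' @param seed integer seed.
#' @return validated config list of class `stereo_sim_config`.
#' @export
stereo_sim_config <- function(n_pairs = 291L, delta = 0.26,
                              sigma_pair = 0.65, mu_R = -9.50,
                              sigma_R = 0.8, seed = 1L) {
  stopifnot(n_pairs >= 1, sigma_pair >= 0, sigma_R > 0)
  structure(list(n_pairs = as.integer(n_pairs), delta = delta,
                 sigma_pair = sigma_pair, mu_R = mu_R, sigma_R = sigma_R,
                 seed = as.integer(seed)),
            class = "stereo_sim_config")
}

#' Simulate paired R/S-configuration score libraries
#'
#' `scores_S[i] = scores_R[i] + d_i` with `d_i ~ Normal(delta,
#' sigma_pair^2)`; the vectors are index-aligned pairs.
#'
#' @param cfg a [stereo_sim_config].
#' @return list with numeric vectors `scores_R` and `scores_S`.
#' @export
simulate_paired_libraries <- function(cfg) {
  stopifnot(inherits(cfg, "stereo_sim_config"))
  with_seed(cfg$seed, {
    r <- stats::rnorm(cfg$n_pairs, cfg$mu_R, cfg$sigma_R)
    d <- stats::rnorm(cfg$n_pairs, cfg$delta, cfg$sigma_pair)
    list(scores_R = r, scores_S = r + d)
  })
}

#' Simulate a pair of binary interaction matrices with column-wise losses
#'
#' The first matrix has i.i.d. Bernoulli occupancy per column; the second is
#' derived from it by independently zeroing each set bit of a column with
#' that column's loss probability -- emulating interactions lost when a
#' ligand library is docked in a disadvantaged configuration.
#'
#' @param n_ligands number of ligands (rows).
#' @param columns character vector of `RESIDUE:interaction_type` labels.
#' @param loss_profile named numeric vector of per-column loss
#'   probabilities in \[0, 1\] (columns absent from the profile lose
#'   nothing).
#' @param seed integer seed.
#' @param occupancy per-column probability a bit is set in the first matrix
#'   (scalar or one value per column, default 0.6).
#' @return list with binary matrices `matrix_R` and `matrix_S`.
#' @export
simulate_interaction_matrices <- function(n_ligands, columns, loss_profile,
                                          seed, occupancy = 0.6) {
  stopifnot(all(loss_profile >= 0), all(loss_profile <= 1),
            all(names(loss_profile) %in% columns))
  occ <- rep_len(occupancy, length(columns))
  with_seed(seed, {
    mR <- sapply(seq_along(columns), function(j)
      as.integer(stats::runif(n_ligands) < occ[j]))
    mR <- matrix(mR, nrow = n_ligands,
                 dimnames = list(sprintf("lig_%04d", seq_len(n_ligands)),
                                 columns))
    mS <- mR
    for (cn in names(loss_profile)) {
      set <- which(mR[, cn] == 1L)
      drop <- set[stats::runif(length(set)) < loss_profile[[cn]]]
      mS[drop, cn] <- 0L
    }
    list(matrix_R = mR, matrix_S = mS)
  })
}

#' Simulate a full docking study: library, activities and score table
#'
#' End-to-end generator behind [run_full_comparison]: draws a gliflozin-like
#' library with fragment-structured activities, labels it at the activity
#' threshold, and generates per-structure docking scores linearly coupled to
#' activity (`score = intercept + slope * pChEMBL + noise`) with a shared
#' latent noise component across structures (`rho`) plus independent
#' per-structure noise.
#'
#' @param n number of compounds.
#' @param seed integer seed.
#' @param n_structures number of pseudo-structures (default 5).
#' @param slope score units per pChEMBL unit (default -0.5: more active
#'   compounds score more negative).
#' @param intercept score at pChEMBL 0 (default -5, placing a
#'   threshold-level compound near -9).
#' @param sigma total docking-noise SD (default 1.2).
#' @param rho shared (inter-structure) fraction of the noise variance
#'   (default 0.5).
#' @param dropout_rate probability a score is missing (default 0.02).
#' @param activity_threshold labeling cutoff (default 8).
#' @param ... passed to [simulate_library_smiles].
#' @return list with `records` (labeled compound records incl. `pchembl`),
#'   `table` (a [score_table]), `labels` (named 0/1 vector).
#' @export
simulate_study <- function(n = 260L, seed = 1L, n_structures = 5L,
                           slope = -0.5, intercept = -5, sigma = 1.2,
                           rho = 0.5, dropout_rate = 0.02,
                           activity_threshold = 8, ...) {
  lib <- simulate_library_smiles(n, derive_seed(seed, "library"), ...)
  lib <- label_activity(lib, threshold = activity_threshold)
  n_kept <- nrow(lib)
  m <- with_seed(derive_seed(seed, "scores"), {
    z <- stats::rnorm(n_kept)
    e <- matrix(stats::rnorm(n_kept * n_structures), n_kept, n_structures)
    sc <- intercept + slope * lib$pchembl +
      sigma * (sqrt(rho) * z + sqrt(1 - rho) * e)
    if (dropout_rate > 0)
      sc[stats::runif(length(sc)) < dropout_rate] <- NA_real_
    sc
  })
  dimnames(m) <- list(lib$compound_id,
                      sprintf("struct_%d", seq_len(n_structures)))
  list(records = lib, table = score_table(m),
       labels = stats::setNames(lib$activity_label, lib$compound_id))
}
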