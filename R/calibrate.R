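#' Similarity-weighted docking-score calibration
#'
#' Corrects each query docking score by the similarity-weighted mean ratio
#' of known activity to docking score over a reference set:
#' \deqn{DS_j = DS_j^0 \cdot \frac{1}{\omega}\sum_i S_{ij}^p
#'       \frac{\Delta G_i}{DS_i}, \qquad \omega = \sum_i S_{ij}^p}
#' where `S` holds Tanimoto similarities and the exponent `p` sets how
#' sharply the correction concentrates on the most similar references.
#' Activities are on the pChEMBL scale, so calibrated scores of negative
#' raw scores come out positive and approximate pChEMBL values.
#'
#' A query with total weight `omega = 0` (no similarity to any reference)
#' is returned uncalibrated; its index is recorded in the
#' `"uncalibrated"` attribute.
#'
#' @param query_scores numeric vector of raw query docking scores.
#' @param reference_scores numeric vector of reference docking scores
#'   (none may be zero).
#' @param reference_activities numeric vector of reference activities
#'   (pChEMBL units), aligned with `reference_scores`.
#' @param S similarity matrix, queries in rows, references in columns.
#' @param p positive integer similarity exponent.
#' @return numeric vector of calibrated scores.
#' @export
calibrate_scores <- function(query_scores, reference_scores,
                             reference_activities, S, p) {
  S <- as.matrix(S)
  if (nrow(S) != length(query_scores) ||
      ncol(S) != length(reference_scores) ||
      length(reference_scores) != length(reference_activities))
    stop("dimension mismatch between scores, activities and S", call. = FALSE)
  if (any(reference_scores == 0))
    stop("reference docking scores of 0 must be excluded before calibration",
         call. = FALSE)
  stopifnot(p >= 1)
  w <- S^p
  omega <- rowSums(w)
  ratio <- reference_activities / reference_scores
  out <- query_scores * as.vector(w %*% ratio) / omega
  flat <- which(omega == 0)
  if (length(flat)) {
    out[flat] <- query_scores[flat]
    warning(length(flat), " query score(s) left uncalibrated (zero total ",
            "similarity weight)")
  }
  attr(out, "uncalibrated") <- flat
  out
}

#' Cross-validated similarity-exponent grid search
#'
#' Splits labeled, scored, SMILES-annotated compounds into stratified folds;
#' treats each fold once as the query set calibrated against the union of
#' the remaining folds; fits a KDE-intersection threshold on each calibrated
#' fold and evaluates its MCC; and averages over folds for every exponent in
#' the grid. The best exponent maximizes the mean MCC (ties go to the
#' smaller exponent, i.e. the least similarity dependence), and the final
#' classification threshold is the mean of its fold thresholds.
#'
#' @param records data frame with columns `compound_id`, `smiles`,
#'   `score` (docking score from one structure), `pchembl` (single
#'   activity value), `activity_label` (0/1).
#' @param cfg list with elements `fingerprint_kind` (default
#'   `"morgan_circular"`), `n_folds` (default 5), `seed` (default 1),
#'   `activity_threshold` (default 8; informational).
#' @param p_grid integer exponents to scan (default `seq(4, 60, by = 8)`).
#' @return object of class `calibration_result`: `per_p` data frame
#'   (`p`, `mean_mcc`, `mean_threshold`, `n_folds_ok`), `fold_detail` list,
#'   `best_p`, `best_mean_mcc`, `final_threshold`, `folds`
#'   (the [stratified_folds] split), `calibrated` (named calibrated scores
#'   at `best_p`, assembled across folds), and the echoed `cfg`.
#' @export
cross_validate_calibration <- function(records, cfg = list(),
                                       p_grid = seq(4L, 60L, by = 8L)) {
  need <- c("compound_id", "smiles", "score", "pchembl", "activity_label")
  if (!all(need %in% names(records)))
    stop("`records` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  kind <- cfg$fingerprint_kind %||% "morgan_circular"
  k <- cfg$n_folds %||% 5L
  seed <- cfg$seed %||% 1L
  labels <- stats::setNames(records$activity_label, records$compound_id)
  split <- stratified_folds(labels, k, seed)
  fold <- split$fold_assignments[records$compound_id]

  fps <- compute_fingerprints(records$smiles, kind, ids = records$compound_id)
  S_full <- tanimoto_matrix(fps, fps)

  fold_detail <- list()
  per_p <- lapply(p_grid, function(p) {
    thr <- mccs <- bas <- rep(NA_real_, k)
    cal_all <- stats::setNames(rep(NA_real_, nrow(records)),
                               records$compound_id)
    for (q in seq_len(k)) {
      qi <- which(fold == q)
      ri <- which(fold != q)
      res <- tryCatch({
        cal <- calibrate_scores(records$score[qi], records$score[ri],
                                records$pchembl[ri],
                                S_full[qi, ri, drop = FALSE], p)
        lab <- records$activity_label[qi]
        model <- find_threshold(cal[lab == 1], cal[lab == 0])
        pred <- classify(as.numeric(cal), model)
        cc <- confusion_counts(lab, pred)
        list(thr = model$threshold, mcc = mcc(cc),
             ba = balanced_accuracy(cc), cal = cal)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("p = %d, fold %d failed: %s", p, q,
                        conditionMessage(res)))
      } else {
        thr[q] <- res$thr
        mccs[q] <- res$mcc
        bas[q] <- res$ba
        cal_all[qi] <- res$cal
      }
    }
    fold_detail[[as.character(p)]] <<- list(thresholds = thr, mccs = mccs,
                                            bas = bas, calibrated = cal_all)
    data.frame(p = p, mean_mcc = mean(mccs, na.rm = TRUE),
               mean_ba = mean(bas, na.rm = TRUE),
               mean_threshold = mean(thr, na.rm = TRUE),
               n_folds_ok = sum(!is.na(mccs)))
  })
  per_p <- do.call(rbind, per_p)
  ok <- per_p$n_folds_ok == k
  if (!any(ok))
    stop("threshold fitting failed in every grid configuration",
         call. = FALSE)
  cand <- per_p[ok, , drop = FALSE]
  best <- cand[order(-cand$mean_mcc, cand$p)[1L], ]
  structure(list(per_p = per_p,
                 fold_detail = fold_detail,
                 best_p = best$p,
                 best_mean_mcc = best$mean_mcc,
                 best_mean_ba = best$mean_ba,
                 final_threshold = best$mean_threshold,
                 folds = split,
                 calibrated = fold_detail[[as.character(best$p)]]$calibrated,
                 cfg = list(fingerprint_kind = kind, n_folds = k, seed = seed,
                            p_grid = p_grid,
                            activity_threshold = cfg$activity_threshold %||% 8)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result (%s): best p = %d, mean CV MCC = %.3f\n",
              x$cfg$fingerprint_kind, x$best_p, x$best_mean_mcc))
  cat(sprintf("  final threshold (mean over %d folds) = %.3f\n",
              x$cfg$n_folds, x$final_threshold))
  invisible(x)
}

#' Apply a calibrated classification model to an external set
#'
#' Calibrates external compound scores against the full reference dataset
#' at the selected exponent and classifies them at the fixed final
#' threshold (calibrated scores approximate pChEMBL values, so higher is
#' active).
#'
#' @param external_records data frame with `compound_id`, `smiles`, `score`,
#'   `activity_label`; ids must be disjoint from the reference set.
#' @param final_threshold classification threshold on the calibrated scale.
#' @param reference_records data frame with `compound_id`, `smiles`,
#'   `score`, `pchembl`.
#' @param kind fingerprint kind used during cross-validation.
#' @param best_p selected similarity exponent.
#' @return list with `counts` ([confusion_counts]), `mcc`, `ba` (`NA` when
#'   the external set holds a single class), `calibrated` (named scores),
#'   `predictions`.
#' @export
apply_final_model <- function(external_records, final_threshold,
                              reference_records,
                              kind = "morgan_circular", best_p = 12L) {
  if (!nrow(external_records)) stop("external set is empty", call. = FALSE)
  overlap <- intersect(external_records$compound_id,
                       reference_records$compound_id)
  if (length(overlap))
    stop("external and reference sets overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  fp_e <- compute_fingerprints(external_records$smiles, kind,
                               ids = external_records$compound_id)
  fp_r <- compute_fingerprints(reference_records$smiles, kind,
                               ids = reference_records$compound_id)
  S <- tanimoto_matrix(fp_e, fp_r)
  cal <- calibrate_scores(external_records$score, reference_records$score,
                          reference_records$pchembl, S, best_p)
  model <- list(threshold = final_threshold, orientation = "higher_is_active")
  pred <- classify(as.numeric(cal), model)
  cc <- confusion_counts(external_records$activity_label, pred)
  ba <- if (cc$tp + cc$fn >= 1 && cc$tn + cc$fp >= 1)
    balanced_accuracy(cc) else NA_real_
  list(counts = cc, mcc = suppressWarnings(mcc(cc)), ba = ba,
       calibrated = stats::setNames(as.numeric(cal),
                                    external_records$compound_id),
       predictions = pred)
}
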