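#' Stratified k-fold assignment
#'
#' Shuffles each class independently under a single seed and deals compounds
#' round-robin into folds, so per-fold class counts are maximally balanced:
#' active (and inactive) counts of any two folds differ by at most one.
#' Fold indices run 1..k.
#'
#' @param labels named binary vector (names = compound ids, values 0/1).
#' @param k number of folds (>= 2).
#' @param seed integer seed; identical seeds give identical assignments.
#' @return object of class `dataset_split`: list with `fold_assignments`
#'   (named integer vector), `k`, `seed`.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (is.null(names(labels)))
    stop("`labels` must be named by compound id", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must be binary 0/1", call. = FALSE)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0L))
    stop("both classes must be present", call. = FALSE)
  if (any(counts < k))
    stop(sprintf("class with %d member(s) cannot fill %d folds",
                 min(counts), k), call. = FALSE)
  assign_fold <- integer(length(labels))
  names(assign_fold) <- names(labels)
  with_seed(seed, {
    for (cls in c(1, 0)) {
      ids <- names(labels)[labels == cls]
      ids <- sample(ids)
      assign_fold[ids] <- ((seq_along(ids) - 1L) %% k) + 1L
    }
  })
  structure(list(fold_assignments = assign_fold, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d compounds in %d folds (seed %d)\n",
              length(x$fold_assignments), x$k, x$seed))
  invisible(x)
}
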