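#' Enumerate candidate structure ensembles
#'
#' All subsets of the structure ids with sizes `min_size..max_size`, ordered
#' by size and then lexicographically. With five structures and sizes 2-5
#' this yields the 26 candidate ensembles.
#'
#' @param structure_ids character vector of distinct structure ids.
#' @param min_size smallest subset size (>= 2).
#' @param max_size largest subset size (defaults to all structures).
#' @return list of character vectors (each an ensemble spec).
#' @export
enumerate_ensembles <- function(structure_ids, min_size = 2L,
                                max_size = length(structure_ids)) {
  stopifnot(!anyDuplicated(structure_ids))
  if (min_size < 2L) stop("`min_size` must be at least 2", call. = FALSE)
  if (min_size > max_size)
    stop("`min_size` exceeds `max_size`", call. = FALSE)
  if (max_size > length(structure_ids))
    stop("`max_size` exceeds the number of structures", call. = FALSE)
  ids <- sort(structure_ids)
  out <- list()
  for (s in min_size:max_size)
    out <- c(out, utils::combn(ids, s, simplify = FALSE))
  out
}

#' Rank-by-number ensemble scores
#'
#' A compound's ensemble score is the arithmetic mean of its docking scores
#' across the member structures. Compounds missing a score in any member
#' structure are excluded (mean of a partial set would bias the ranking).
#'
#' @param table a [score_table].
#' @param spec character vector of member structure ids.
#' @return list with `scores` (named mean-score vector) and `compound_ids`
#'   (the retained compounds).
#' @export
ensemble_scores <- function(table, spec) {
  stopifnot(inherits(table, "score_table"))
  spec <- as.character(spec)
  if (anyDuplicated(spec)) stop("ensemble members must be distinct",
                                call. = FALSE)
  missing_s <- setdiff(spec, table$structures)
  if (length(missing_s))
    stop("unknown structure id(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  sub <- table$scores[, spec, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0L
  if (!any(keep))
    stop("no compound has scores in every member structure", call. = FALSE)
  list(scores = rowMeans(sub[keep, , drop = FALSE]),
       compound_ids = table$compounds[keep])
}

#' Scan all structure ensembles and rank them by MCC
#'
#' For every subset of structures of the requested sizes, computes
#' rank-by-number mean scores, fits a KDE-intersection threshold on the
#' compounds retained for that subset, and evaluates MCC and balanced
#' accuracy on the same compounds. Subsets whose threshold fit fails are
#' reported with `NA` metrics rather than aborting the scan.
#'
#' @param table a [score_table].
#' @param labels named binary vector covering the table's compounds.
#' @param min_size,max_size subset size bounds (see [enumerate_ensembles]).
#' @return data frame sorted by MCC (descending; ties to the smaller, then
#'   lexicographically earlier ensemble) with columns `members`, `size`,
#'   `threshold`, `orientation`, `mcc`, `ba`, `n_retained`.
#' @export
scan_ensembles <- function(table, labels, min_size = 2L,
                           max_size = length(table$structures)) {
  stopifnot(inherits(table, "score_table"), !is.null(names(labels)))
  specs <- enumerate_ensembles(table$structures, min_size, max_size)
  rows <- lapply(specs, function(spec) {
    res <- tryCatch({
      es <- ensemble_scores(table, spec)
      lab <- labels[es$compound_ids]
      if (anyNA(lab))
        stop("labels missing for retained compounds")
      model <- find_threshold(es$scores[lab == 1], es$scores[lab == 0])
      pred <- classify(es$scores, model)
      cc <- confusion_counts(lab, pred)
      data.frame(members = paste(spec, collapse = "+"),
                 size = length(spec), threshold = model$threshold,
                 orientation = model$orientation, mcc = mcc(cc),
                 ba = balanced_accuracy(cc), n_retained = length(lab),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("ensemble %s failed: %s",
                      paste(spec, collapse = "+"), conditionMessage(e)))
      data.frame(members = paste(spec, collapse = "+"),
                 size = length(spec), threshold = NA_real_,
                 orientation = NA_character_, mcc = NA_real_, ba = NA_real_,
                 n_retained = NA_integer_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$mcc, out$size, out$members, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
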