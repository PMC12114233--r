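#' Construct a compound-by-structure docking score table
#'
#' A `score_table` holds one docking score per (compound, structure) pair as a
#' numeric matrix with compounds in rows and target structures in columns.
#' Failed docks are first-class missing entries (`NA`); infinite values are
#' rejected.
#'
#' @param scores numeric matrix, rows = compounds, columns = structures.
#'   Must have row and column names.
#' @return an object of class `score_table`.
#' @examples
#' m <- matrix(c(-9, -10, NA, -8), 2, 2,
#'             dimnames = list(c("a", "b"), c("S1", "S2")))
#' tab <- score_table(m)
#' n_missing(tab)
#' @export
score_table <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` must have compound row names and structure column names",
         call. = FALSE)
  if (anyDuplicated(rownames(scores)))
    stop("duplicate compound ids in score table", call. = FALSE)
  if (anyDuplicated(colnames(scores)))
    stop("duplicate structure ids in score table", call. = FALSE)
  if (any(is.infinite(scores)))
    stop("docking scores must be finite (use NA for failed docks)",
         call. = FALSE)
  structure(list(scores = scores,
                 compounds = rownames(scores),
                 structures = colnames(scores)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d compounds x %d structures (%d missing)\n",
              length(x$compounds), length(x$structures), n_missing(x)))
  invisible(x)
}

#' @rdname score_table
#' @param x a `score_table`.
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "score_table"))
  sum(is.na(x$scores))
}

#' Read a long-format docking score CSV
#'
#' Expects one row per (compound, structure) pair. Pairs absent from the file
#' become missing entries; duplicate pairs are an error.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical column roles
#'   `compound_id`, `structure_id`, `docking_score` to the column names used
#'   in the file.
#' @return a [score_table].
#' @export
read_docking_csv <- function(path,
                             schema = c(compound_id = "compound_id",
                                        structure_id = "structure_id",
                                        docking_score = "docking_score")) {
  need <- c("compound_id", "structure_id", "docking_score")
  if (!all(need %in% names(schema)))
    stop("`schema` must map compound_id, structure_id and docking_score",
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(schema[need]), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  cid <- as.character(df[[schema[["compound_id"]]]])
  sid <- as.character(df[[schema[["structure_id"]]]])
  val <- df[[schema[["docking_score"]]]]
  if (!is.numeric(val))
    stop("docking_score column is not numeric", call. = FALSE)
  key <- paste(cid, sid, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (compound, structure) pair at data row %d: (%s, %s)",
                 bad, cid[bad], sid[bad]), call. = FALSE)
  }
  comp <- unique(cid)
  struct <- unique(sid)
  m <- matrix(NA_real_, length(comp), length(struct),
              dimnames = list(comp, struct))
  m[cbind(match(cid, comp), match(sid, struct))] <- val
  score_table(m)
}

#' Write a score table as a long-format CSV
#'
#' Missing entries are omitted, so a write/read round trip reproduces the
#' table, including missing-entry positions.
#'
#' @param x a [score_table].
#' @param path output CSV path.
#' @export
write_docking_csv <- function(x, path) {
  stopifnot(inherits(x, "score_table"))
  idx <- which(!is.na(x$scores), arr.ind = TRUE)
  df <- data.frame(compound_id = x$compounds[idx[, 1L]],
                   structure_id = x$structures[idx[, 2L]],
                   docking_score = x$scores[idx],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
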