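#' Read molecules from a SMILES list or SDF file
#'
#' Compound records are returned as a data frame with one row per molecule:
#' `compound_id`, `smiles`, and a `pchembl_values` list column (empty until
#' activities are attached). Molecules the toolkit cannot parse are skipped
#' with a message giving the count; ids from the file are preserved.
#'
#' @param path input file.
#' @param fmt `"smiles_list"` (one SMILES per line, optional whitespace-
#'   separated id) or `"sdf"`.
#' @return a compound-record data frame.
#' @export
read_molecules <- function(path, fmt = c("smiles_list", "sdf")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  if (fmt == "smiles_list") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty_records())
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
    auto <- !nzchar(ids)
    ids[auto] <- sprintf("mol_%04d", which(auto))
    can <- canonical_smiles(smi, ids = ids)
    keep <- !is.na(can)
    if (any(!keep))
      message(sum(!keep), " unparseable molecule(s) skipped")
    compound_records(compound_id = ids[keep], smiles = smi[keep])
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    ok <- ChemmineR::validSDF(sdf)
    if (any(!ok)) message(sum(!ok), " unparseable molecule(s) skipped")
    sdf <- sdf[ok]
    if (!length(sdf)) return(empty_records())
    ids <- ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    compound_records(compound_id = ids, smiles = smi)
  }
}

empty_records <- function() {
  df <- data.frame(compound_id = character(), smiles = character(),
                   stringsAsFactors = FALSE)
  df$pchembl_values <- list()
  df
}

#' Build a compound-record data frame
#'
#' @param compound_id unique character ids.
#' @param smiles optional SMILES strings.
#' @param pchembl_values optional list of numeric activity vectors
#'   (one vector per compound, -log10 molar units).
#' @return data frame with a `pchembl_values` list column.
#' @export
compound_records <- function(compound_id, smiles = NA_character_,
                             pchembl_values = NULL) {
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id))
    stop("compound ids must be unique; merge duplicates first with ",
         "`merge_by_id()`", call. = FALSE)
  df <- data.frame(compound_id = compound_id,
                   smiles = rep_len(as.character(smiles), length(compound_id)),
                   stringsAsFactors = FALSE)
  if (is.null(pchembl_values))
    pchembl_values <- rep(list(numeric()), nrow(df))
  stopifnot(length(pchembl_values) == nrow(df))
  df$pchembl_values <- pchembl_values
  df
}

#' Read a compound activity CSV (`compound_id,pchembl`)
#'
#' Multiple rows per compound are allowed; they are merged into one record
#' holding all activity values.
#'
#' @param path CSV path with columns `compound_id` and `pchembl`.
#' @return compound-record data frame (no SMILES).
#' @export
read_activities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "pchembl") %in% names(df)))
    stop("activity CSV needs columns compound_id and pchembl", call. = FALSE)
  merge_by_id(data.frame(compound_id = as.character(df$compound_id),
                         pchembl = as.numeric(df$pchembl),
                         stringsAsFactors = FALSE))
}

#' Merge duplicate compound entries by id
#'
#' Collapses a long table (`compound_id`, `pchembl`, optional `smiles`) so
#' each compound appears once, with all its activity values kept in the
#' `pchembl_values` list column. Mirrors the merging applied to registry data
#' where one molecule carries several measured activities.
#'
#' @param df data frame with `compound_id`, `pchembl`, optionally `smiles`.
#' @return compound-record data frame.
#' @export
merge_by_id <- function(df) {
  stopifnot(all(c("compound_id", "pchembl") %in% names(df)))
  ids <- unique(df$compound_id)
  vals <- split(df$pchembl, factor(df$compound_id, levels = ids))
  smi <- if ("smiles" %in% names(df))
    vapply(split(df$smiles, factor(df$compound_id, levels = ids)),
           function(s) s[[1L]], "")
  else NA_character_
  compound_records(ids, smiles = smi, pchembl_values = unname(vals))
}

#' Label compounds active/inactive at a pChEMBL threshold
#'
#' A compound is active (label 1) when every activity value lies strictly
#' above `threshold`, inactive (label 0) when every value lies at or below
#' it. Compounds whose values straddle the threshold receive conflicting
#' labels and are dropped; the dropped ids are attached as attribute
#' `"dropped"`.
#'
#' @param records compound-record data frame with non-empty
#'   `pchembl_values`.
#' @param threshold activity cutoff on the pChEMBL scale (default 8).
#' @return the labeled records with an `activity_label` column.
#' @export
label_activity <- function(records, threshold = 8.0) {
  stopifnot(is.data.frame(records), "pchembl_values" %in% names(records))
  nv <- lengths(records$pchembl_values)
  if (any(nv == 0L))
    stop("compound(s) without pChEMBL values: ",
         paste(utils::head(records$compound_id[nv == 0L], 5L), collapse = ", "),
         call. = FALSE)
  above <- vapply(records$pchembl_values, function(v) all(v > threshold), TRUE)
  below <- vapply(records$pchembl_values, function(v) all(v <= threshold), TRUE)
  keep <- above | below
  out <- records[keep, , drop = FALSE]
  out$activity_label <- as.integer(above[keep])
  rownames(out) <- NULL
  attr(out, "dropped") <- records$compound_id[!keep]
  out
}

#' Drop compounds with multiple activity values
#'
#' Retains only compounds with exactly one pChEMBL value, the consistency
#' filter applied before model building.
#'
#' @param records compound-record data frame.
#' @return filtered records.
#' @export
drop_multi_activity <- function(records) {
  stopifnot(is.data.frame(records), "pchembl_values" %in% names(records))
  out <- records[lengths(records$pchembl_values) == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
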