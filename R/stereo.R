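# Tokenize the atoms of a SMILES string: returns a data frame with the
# start/end character positions of each atom token, in atom order.
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I",
                "b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES", call. = FALSE)
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% organic2) {
      starts <- c(starts, i); ends <- c(ends, i + 1L)
      i <- i + 2L
    } else if (ch %in% organic1) {
      starts <- c(starts, i); ends <- c(ends, i)
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L                      # two-digit ring closure
    } else {
      i <- i + 1L                      # bonds, branches, digits, charges
    }
  }
  data.frame(start = starts, end = ends)
}

#' Invert one tetrahedral stereocenter in a SMILES string
#'
#' Flips the parity marker (`@` to `@@` or back) of the atom at
#' `atom_index` (1-based, in SMILES atom order). The atom must carry a
#' tetrahedral parity; anything else is an error. Applying the inversion
#' twice returns a molecule identical (canonically) to the input.
#'
#' @param smiles a SMILES string.
#' @param atom_index 1-based index of the atom in SMILES order.
#' @return the modified SMILES string (same layout as the input).
#' @examples
#' invert_stereocenter("C[C@H](N)O", 2)
#' @export
invert_stereocenter <- function(smiles, atom_index) {
  toks <- smiles_atom_tokens(smiles)
  if (atom_index < 1L || atom_index > nrow(toks))
    stop(sprintf("atom_index %d out of range (molecule has %d atoms)",
                 atom_index, nrow(toks)), call. = FALSE)
  s <- toks$start[atom_index]
  e <- toks$end[atom_index]
  token <- substr(smiles, s, e)
  if (!grepl("@", token, fixed = TRUE))
    stop(sprintf("atom %d (%s) is not a defined tetrahedral stereocenter",
                 atom_index, token), call. = FALSE)
  flipped <- if (grepl("@@", token, fixed = TRUE))
    sub("@@", "@", token, fixed = TRUE)
  else
    sub("@", "@@", token, fixed = TRUE)
  paste0(substr(smiles, 1L, s - 1L), flipped,
         substr(smiles, e + 1L, nchar(smiles)))
}

#' Paired comparison of two index-aligned docking score libraries
#'
#' Classical paired t-test on the differences `d = scores_S - scores_R`
#' between two libraries of identical molecules docked in two
#' configurations, with two-sided p-value and 95% confidence interval for
#' the mean difference.
#'
#' @param scores_R,scores_S equal-length (>= 2) aligned score vectors.
#' @return object of class `paired_comparison` with `n_pairs`, means and
#'   medians of both libraries, `mean_diff` (S - R), `t_statistic`,
#'   `df`, `p_value`, `ci95`, `alpha`.
#' @export
paired_score_test <- function(scores_R, scores_S) {
  if (length(scores_R) != length(scores_S))
    stop("score vectors must be index-aligned and equal length",
         call. = FALSE)
  n <- length(scores_R)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- scores_S - scores_R
  if (stats::sd(d) == 0)
    stop(sprintf("degenerate case: all pairwise differences equal %.6g",
                 d[1L]), call. = FALSE)
  tt <- stats::t.test(scores_S, scores_R, paired = TRUE,
                      conf.level = 0.95)
  structure(list(n_pairs = n,
                 mean_R = mean(scores_R), mean_S = mean(scores_S),
                 median_R = stats::median(scores_R),
                 median_S = stats::median(scores_S),
                 mean_diff = mean(d),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 ci95 = as.numeric(tt$conf.int),
                 alpha = 0.05),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired_comparison over %d pairs\n", x$n_pairs))
  cat(sprintf("  mean R = %.3f, mean S = %.3f (medians %.3f / %.3f)\n",
              x$mean_R, x$mean_S, x$median_R, x$median_S))
  cat(sprintf("  mean diff (S - R) = %.3f, t = %.3f (df %d), p = %.3g\n",
              x$mean_diff, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Per-column interaction losses between two binary interaction matrices
#'
#' Columns are (residue, interaction-type) indicators; the loss of a column
#' is `colSums(R) - colSums(S)`. Columns losing more than `min_loss`
#' interactions are reported (sorted by loss, descending); columns gained in
#' the second matrix are listed separately. The sum over all column
#' differences is conserved: total losses minus total gains equals the
#' difference of the matrix totals.
#'
#' @param matrix_R,matrix_S binary matrices with identical column names
#'   (ligands in rows).
#' @param min_loss report threshold; only columns with `loss > min_loss`
#'   enter the loss table (default 5).
#' @param denominator divisor for `loss_fraction` (default: number of
#'   ligands in `matrix_R`).
#' @return list with `losses` and `gains` data frames
#'   (`column`, `loss_count`/`gain_count`, fraction) and `column_diff`,
#'   the full named vector of per-column differences.
#' @export
interaction_loss_tally <- function(matrix_R, matrix_S, min_loss = 5L,
                                   denominator = nrow(matrix_R)) {
  matrix_R <- as.matrix(matrix_R)
  matrix_S <- as.matrix(matrix_S)
  if (is.null(colnames(matrix_R)) || is.null(colnames(matrix_S)))
    stop("interaction matrices need column names", call. = FALSE)
  if (!setequal(colnames(matrix_R), colnames(matrix_S)))
    stop("interaction matrices have different column sets", call. = FALSE)
  matrix_S <- matrix_S[, colnames(matrix_R), drop = FALSE]
  stopifnot(all(matrix_R %in% c(0, 1)), all(matrix_S %in% c(0, 1)))
  diff <- colSums(matrix_R) - colSums(matrix_S)
  lost <- diff[diff > min_loss]
  lost <- lost[order(-lost, names(lost))]
  gained <- -diff[diff < 0]
  gained <- gained[order(-gained, names(gained))]
  list(losses = data.frame(column = names(lost),
                           loss_count = as.integer(lost),
                           loss_fraction = as.numeric(lost) / denominator,
                           stringsAsFactors = FALSE, row.names = NULL),
       gains = data.frame(column = names(gained),
                          gain_count = as.integer(gained),
                          gain_fraction = as.numeric(gained) / denominator,
                          stringsAsFactors = FALSE, row.names = NULL),
       column_diff = diff)
}

#' Read/write a binary interaction matrix CSV
#'
#' Format: first column `ligand_id`, remaining columns named
#' `RESIDUE:interaction_type` with 0/1 entries.
#'
#' @param path CSV path.
#' @return binary matrix with ligand ids as row names.
#' @export
read_interaction_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "ligand_id")
    stop("first column must be ligand_id", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$ligand_id
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L)))
    stop("interaction matrix entries must be 0/1", call. = FALSE)
  m
}

#' @rdname read_interaction_csv
#' @param m binary interaction matrix (ligands in rows).
#' @export
write_interaction_csv <- function(m, path) {
  df <- data.frame(ligand_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
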