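# Fingerprint backends (OpenBabel):
#   maccs_keys      -> MACCS, 166 structural keys
#   morgan_circular -> ECFP4 (radius-2 circular), 4096 bits folded to 2048
#   path_based      -> FP2 (linear paths up to 7 atoms), 1024 bits
fp_backend <- function(kind) {
  switch(kind,
         maccs_keys = list(ob = "MACCS", nbits = 166L, fold = FALSE),
         morgan_circular = list(ob = "ECFP4", nbits = 2048L, fold = TRUE),
         path_based = list(ob = "FP2", nbits = 1024L, fold = FALSE),
         stop("unknown fingerprint kind: ", kind, call. = FALSE))
}

have_obabel <- function() nzchar(Sys.which("obabel"))

# Decode FPS hex lines (chemfp convention: bytes in order, bits LSB-first
# within each byte) into a 0/1 integer matrix.
decode_fps <- function(lines, nbits_declared) {
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  hex <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  nb <- nchar(hex[1L]) * 4L
  m <- matrix(0L, length(hex), nb)
  lut <- sapply(0:255, function(b) bitwAnd(bitwShiftR(b, 0:7), 1L))  # 8 x 256
  for (r in seq_along(hex)) {
    bytes <- strtoi(substring(hex[r], seq(1L, nchar(hex[r]), 2L),
                              seq(2L, nchar(hex[r]), 2L)), 16L)
    m[r, ] <- as.integer(lut[, bytes + 1L])
  }
  rownames(m) <- ids
  m[, seq_len(min(nbits_declared, nb)), drop = FALSE]
}

run_obabel <- function(input_lines, args) {
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile()
  on.exit(unlink(c(inf, outf)))
  writeLines(input_lines, inf)
  status <- suppressWarnings(
    system2("obabel", c(inf, "-e", args, "-O", outf),
            stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(outf))
    stop("obabel failed (is OpenBabel installed?)", call. = FALSE)
  readLines(outf, warn = FALSE)
}

#' Canonical SMILES
#'
#' Converts SMILES to OpenBabel canonical form so alternative spellings of
#' the same molecule compare equal. Unparseable entries are returned as
#' `NA`.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional ids (must not contain whitespace); defaults to
#'   positional ids.
#' @return character vector of canonical SMILES, `NA` where parsing failed,
#'   named by `ids`.
#' @export
canonical_smiles <- function(smiles, ids = NULL) {
  if (!length(smiles)) return(character())
  ids <- ids %||% sprintf("m%06d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids),
            !any(grepl("[ \t]", ids)))
  out <- run_obabel(paste(smiles, ids), "-ocan")
  parts <- strsplit(out, "[ \t]+")
  can <- vapply(parts, `[[`, "", 1L)
  got <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  res <- stats::setNames(rep(NA_character_, length(smiles)), ids)
  res[got] <- can
  res
}

#' Compute binary molecular fingerprints
#'
#' Computes one fingerprint per molecule as a row of a 0/1 matrix. SMILES
#' are canonicalized before hashing, so different spellings of the same
#' molecule yield identical fingerprints. Kinds: `maccs_keys` (166
#' structural keys), `morgan_circular` (radius-2 circular, 2048 bits),
#' `path_based` (linear paths up to 7 bonds, 1024 bits).
#'
#' @param smiles character vector of SMILES strings.
#' @param kind fingerprint family.
#' @param ids optional molecule ids (row names of the result).
#' @return integer 0/1 matrix, one row per molecule, with attribute
#'   `"kind"`.
#' @export
compute_fingerprints <- function(smiles,
                                 kind = c("morgan_circular", "maccs_keys",
                                          "path_based"),
                                 ids = NULL) {
  kind <- match.arg(kind)
  be <- fp_backend(kind)
  ids <- ids %||% sprintf("m%06d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  can <- canonical_smiles(smiles, ids = ids)
  if (anyNA(can))
    stop("unparseable SMILES for: ",
         paste(utils::head(ids[is.na(can)], 5L), collapse = ", "),
         call. = FALSE)
  raw_bits <- if (be$fold) 2L * be$nbits else be$nbits
  out <- run_obabel(paste(unname(can), ids),
                    c("-ofps", paste0("-xf", be$ob)))
  m <- decode_fps(out, raw_bits)
  if (!setequal(rownames(m), ids) || nrow(m) != length(ids))
    stop("fingerprinting failed for: ",
         paste(utils::head(setdiff(ids, rownames(m)), 5L), collapse = ", "),
         call. = FALSE)
  m <- m[ids, , drop = FALSE]
  if (be$fold) {
    half <- be$nbits
    m <- (m[, seq_len(half), drop = FALSE] |
            m[, half + seq_len(half), drop = FALSE]) * 1L
    rownames(m) <- ids
  }
  attr(m, "kind") <- kind
  m
}

#' @rdname compute_fingerprints
#' @description `compute_fingerprint()` is the single-molecule convenience
#'   wrapper returning a plain 0/1 vector.
#' @export
compute_fingerprint <- function(smiles, kind = c("morgan_circular",
                                                 "maccs_keys", "path_based")) {
  kind <- match.arg(kind)
  m <- compute_fingerprints(smiles[1L], kind, ids = "query")
  structure(as.integer(m[1L, ]), kind = kind)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints are defined as
#' similarity 0 (with a warning).
#'
#' @param a,b 0/1 vectors of the same kind and length.
#' @return number in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    stop("fingerprint kinds differ: ", ka, " vs ", kb, call. = FALSE)
  if (length(a) != length(b))
    stop("fingerprint lengths differ", call. = FALSE)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  inter / uni
}

#' Query-by-reference Tanimoto similarity matrix
#'
#' @param query,reference 0/1 fingerprint matrices of the same kind
#'   (rows = molecules).
#' @return numeric matrix of Tanimoto similarities, queries in rows,
#'   references in columns.
#' @export
tanimoto_matrix <- function(query, reference) {
  kq <- attr(query, "kind"); kr <- attr(reference, "kind")
  if (!is.null(kq) && !is.null(kr) && !identical(kq, kr))
    stop("fingerprint kinds differ: ", kq, " vs ", kr, call. = FALSE)
  if (ncol(query) != ncol(reference))
    stop("fingerprint lengths differ", call. = FALSE)
  q <- query * 1.0
  r <- reference * 1.0
  inter <- q %*% t(r)
  uni <- outer(rowSums(q), rowSums(r), "+") - inter
  s <- ifelse(uni == 0, 0, inter / uni)
  dimnames(s) <- list(rownames(query), rownames(reference))
  s
}
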