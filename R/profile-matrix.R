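#' Coerce a data frame or matrix to a validated compound-by-gene matrix
#'
#' The package's universal input is a compounds x genes matrix of
#' differential expression values (treated vs. control, log-ratio scale).
#' Tabular inputs carry the compound identifiers in a `compound_id` column
#' (or, failing that, the first column); all remaining columns are genes.
#' Matrices must have compound row names and gene column names.
#'
#' Values are assumed to be already control-normalized: no normalization is
#' applied here, so preprocessing stays explicit in [decompose_profiles()].
#'
#' @param data A data frame with a `compound_id` column and one numeric
#'   column per gene, or a numeric matrix with compound row names and gene
#'   column names.
#' @return A numeric matrix (compounds x genes) with unique, non-empty
#'   dimnames and no non-finite entries.
#' @examples
#' df <- tibble::tibble(compound_id = c("a", "b"), g1 = c(1, 0), g2 = c(0, 1))
#' as_profile_matrix(df)
#' @export
as_profile_matrix <- function(data) {
  if (is.matrix(data)) {
    x <- data
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("profile matrix must have compound row names and gene column names")
    }
    storage.mode(x) <- "double"
  } else if (is.data.frame(data)) {
    df <- as.data.frame(data, stringsAsFactors = FALSE)
    id_col <- if ("compound_id" %in% names(df)) "compound_id" else names(df)[1]
    ids <- as.character(df[[id_col]])
    value_cols <- setdiff(names(df), id_col)
    for (nm in value_cols) {
      v <- df[[nm]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                       !is.na(v))[1]
        abort(sprintf(
          "non-numeric value in gene column '%s' (compound '%s')",
          nm, ids[if (is.na(bad)) 1L else bad]))
      }
    }
    x <- as.matrix(df[value_cols])
    rownames(x) <- ids
  } else {
    abort("`data` must be a data frame or a numeric matrix")
  }
  validate_profile_matrix(x)
  x
}

validate_profile_matrix <- function(x) {
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort(sprintf("profile matrix must be at least 2 x 2 (got %d x %d)",
                  nrow(x), ncol(x)))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicate compound ids: %s",
                  fmt_ids(unique(rownames(x)[duplicated(rownames(x))]))))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("duplicate gene ids: %s",
                  fmt_ids(unique(colnames(x)[duplicated(colnames(x))]))))
  }
  if (any(!nzchar(rownames(x))) || any(!nzchar(colnames(x)))) {
    abort("compound and gene ids must be non-empty strings")
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "missing or non-finite value at compound '%s', gene '%s'",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

#' Convert a compound-by-gene matrix to a tibble
#'
#' Inverse of [as_profile_matrix()]: one row per compound, a `compound_id`
#' column, and one column per gene.
#'
#' @param x Numeric matrix with compound row names and gene column names.
#' @return A tibble.
#' @export
profile_tbl <- function(x) {
  stopifnot(is.matrix(x))
  dplyr::bind_cols(tibble(compound_id = rownames(x)), as_tibble(x))
}
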