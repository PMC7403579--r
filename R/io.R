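#' Read a compound-by-gene profile matrix from delimited text
#'
#' Reads a TSV or CSV file (dialect auto-detected from the extension:
#' `.csv` means comma, anything else tab) with one header row and one
#' leading identifier column, and returns the profile in compounds x genes
#' orientation as a tibble regardless of the file's orientation.
#'
#' Identifier matching everywhere in the package is exact and
#' case-sensitive.
#'
#' @param path Path to the delimited file.
#' @param orientation `"compounds_as_rows"` (default) if file rows are
#'   compounds, `"genes_as_rows"` if file rows are genes.
#' @return A tibble with a `compound_id` column and one numeric column per
#'   gene. Feed it to [decompose_profiles()] or [as_profile_matrix()].
#' @seealso [write_profile_matrix()]
#' @export
read_profile_matrix <- function(path,
                                orientation = c("compounds_as_rows",
                                                "genes_as_rows")) {
  orientation <- rlang::arg_match(orientation)
  df <- read_delim_auto(path)
  if (ncol(df) < 2 || nrow(df) < 1) {
    abort(sprintf("'%s': expected an id column plus at least one value column",
                  path))
  }
  ids <- as.character(df[[1]])
  vars <- names(df)[-1]
  n <- length(ids)
  x <- matrix(NA_real_, nrow = n, ncol = length(vars),
              dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    v <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(num))[1]
    if (!is.na(bad)) {
      abort(sprintf("'%s': missing or non-numeric cell at row '%s', column '%s'",
                    path, ids[bad], vars[j]))
    }
    x[, j] <- num
  }
  if (orientation == "genes_as_rows") x <- t(x)
  validate_profile_matrix(x)
  profile_tbl(x)
}

#' Write a profile matrix (or any compound-keyed table) to delimited text
#'
#' Values are written at full double precision (shortest round-trip
#' representation), so read -> write -> read reproduces values exactly.
#'
#' @param data Tibble as returned by [read_profile_matrix()], or a matrix.
#' @param path Output path; `.csv` writes comma-separated, otherwise TSV.
#' @return `data`, invisibly.
#' @export
write_profile_matrix <- function(data, path) {
  if (is.matrix(data)) data <- profile_tbl(data)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(data, path)
  } else {
    readr::write_tsv(data, path)
  }
  invisible(data)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character(), name_repair = "minimal")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within
#' a line are dropped (first occurrence kept); duplicate term ids are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `description`, and `genes`
#'   (a list-column of character vectors).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s': no gene sets found", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)[1]
  if (!is.na(short)) {
    abort(sprintf("'%s' line %d: expected >= 3 tab-separated fields",
                  path, short))
  }
  term_id <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(term_id)) {
    abort(sprintf("'%s': duplicate term ids: %s", path,
                  fmt_ids(unique(term_id[duplicated(term_id)]))))
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(genes) == 0)) abort(sprintf("'%s': empty gene set", path))
  tibble(term_id = term_id,
         description = vapply(fields, `[[`, character(1), 2),
         genes = genes)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Tibble with `term_id`, `description`, `genes` columns, as
#'   returned by [read_gene_sets()].
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Read per-compound boolean flags (e.g. prior-publication status)
#'
#' The flag column accepts `0`/`1` and `true`/`false` in any case. Compounds
#' unknown to a profile matrix are not rejected here; mismatches surface at
#' join time in [categorize()] / [compare_indicators()].
#'
#' @param path Delimited file (TSV, or CSV by extension) with a header; the
#'   compound identifier is taken from a `compound_id` column or else the
#'   first column.
#' @param flag_col Name of the boolean column; default the first non-id
#'   column.
#' @return A tibble with `compound_id`, a logical `flag` column, and any
#'   further columns passed through as labels.
#' @export
read_flags <- function(path, flag_col = NULL) {
  df <- read_delim_auto(path)
  id_col <- if ("compound_id" %in% names(df)) "compound_id" else names(df)[1]
  flag_col <- flag_col %||% setdiff(names(df), id_col)[1]
  if (is.na(flag_col) || !flag_col %in% names(df)) {
    abort(sprintf("'%s': no boolean flag column found", path))
  }
  raw <- as.character(df[[flag_col]])
  flag <- parse_flag(raw)
  bad <- which(is.na(flag))[1]
  if (!is.na(bad)) {
    abort(sprintf("'%s': unparseable boolean '%s' in column '%s' (row %d)",
                  path, raw[bad], flag_col, bad))
  }
  extra <- setdiff(names(df), c(id_col, flag_col))
  dplyr::bind_cols(
    tibble(compound_id = as.character(df[[id_col]]), flag = flag),
    df[extra])
}

parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "t")] <- TRUE
  out[lx %in% c("0", "false", "f")] <- FALSE
  out
}
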