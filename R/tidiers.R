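#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' Tidy a fitted decomposition
#'
#' @param x An `olsa_fit` from [decompose_profiles()].
#' @param matrix Which component to tidy: `"scores"` (long tibble
#'   compound/vector/score), `"loadings"` (gene/vector/loading),
#'   `"variance"` (vector/explained-variance share), or `"strength"`
#'   (compound/total strength).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.olsa_fit <- function(x, matrix = c("scores", "loadings", "variance",
                                        "strength"), ...) {
  matrix <- rlang::arg_match(matrix)
  vnames <- colnames(x$scores)
  switch(matrix,
    scores = tidyr::pivot_longer(
      profile_tbl(x$scores), -"compound_id",
      names_to = "vector", values_to = "score"),
    loadings = tidyr::pivot_longer(
      dplyr::bind_cols(tibble(gene_id = rownames(x$loadings)),
                       as_tibble(x$loadings)),
      -"gene_id", names_to = "vector", values_to = "loading"),
    variance = tibble(vector = vnames,
                      explained_variance = unname(x$explained_variance)),
    strength = tibble(compound_id = names(x$total_strength),
                      strength = unname(x$total_strength)))
}

#' One-row summary of a fitted decomposition
#'
#' @param x An `olsa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, number of retained vectors,
#'   threshold, retained variance, and varimax convergence info.
#' @export
glance.olsa_fit <- function(x, ...) {
  tibble(n_compounds = x$n_compounds, n_genes = x$n_genes,
         n_components = x$n_components, threshold = x$threshold,
         retained_variance = sum(x$explained_variance),
         unit_normalized = x$preprocessing$unit_normalize,
         varimax_iterations = x$varimax$iterations,
         varimax_converged = x$varimax$converged)
}

#' Tidy a Ward dendrogram's merge table
#'
#' @param x A `ward_dendrogram` from [ward_linkage()].
#' @param ... Unused.
#' @return The merge tibble (`step`, `a`, `b`, `height`, `size`).
#' @export
tidy.ward_dendrogram <- function(x, ...) x$merges

#' One-row summary of a selection report
#'
#' @param x A `selection_report` from [categorize()].
#' @param ... Unused.
#' @return A one-row tibble with the distribution stats, cutoffs, and
#'   category counts.
#' @export
glance.selection_report <- function(x, ...) {
  cuts <- attr(x, "cutoffs")
  tibble(median = attr(x, "median"), iqr = attr(x, "iqr"),
         moderate_cutoff = cuts[["moderate"]],
         high_cutoff = cuts[["high"]],
         n_high = sum(x$category == "high"),
         n_moderate = sum(x$category == "moderate"),
         n_negative = sum(x$category == "negative"),
         n_other = sum(x$category == "other"))
}
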