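#' Top-loading gene signature of a latent vector
#'
#' Ranks a vector's genes by absolute loading (descending) and takes the
#' top fraction — by default the top 1% of genes, mirroring the usual
#' signature size for enrichment — as the vector's gene signature. The
#' signature size is `max(1, round(fraction * n_genes))` with halves
#' rounded away from zero; ties at the boundary are broken by gene id
#' (lexicographic) so the selection is deterministic.
#'
#' @param fit An `olsa_fit` from [decompose_profiles()].
#' @param vector_name Vector name, e.g. `"P14V"`.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return An object of class `vector_signature`: list with `vector_name`,
#'   `fraction`, `ranked` (tibble `gene_id`, `loading`, `rank`), and
#'   `top_genes` (ordered character vector).
#' @export
top_fraction_genes <- function(fit, vector_name, fraction = 0.01) {
  stopifnot(inherits(fit, "olsa_fit"))
  check_vector_name(fit, vector_name)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single value in (0, 1]")
  }
  loading <- fit$loadings[, vector_name]
  gene_id <- rownames(fit$loadings)
  ord <- order(-abs(loading), gene_id)
  ranked <- tibble(gene_id = gene_id[ord], loading = loading[ord],
                   rank = seq_along(ord))
  k <- max(1, round_half_up(fraction * length(gene_id)))
  structure(list(vector_name = vector_name, fraction = fraction,
                 ranked = ranked, top_genes = ranked$gene_id[seq_len(k)]),
            class = "vector_signature")
}

#' @export
print.vector_signature <- function(x, ...) {
  cat(sprintf("Signature of %s: top %d genes (fraction %.3g)\n",
              x$vector_name, length(x$top_genes), x$fraction))
  cat(" ", fmt_ids(x$top_genes, 10), "\n")
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' One-sided over-representation probability `P(X >= overlap)` for
#' `X ~ Hypergeometric(universe_size, term_size, query_size)` — the upper
#' tail of Fisher's exact test.
#'
#' @param overlap Number of query genes in the term.
#' @param query_size,term_size,universe_size Set sizes; must be mutually
#'   consistent.
#' @return p-value in (0, 1].
#' @examples
#' hypergeometric_p(2, 2, 2, 4) # 1/6
#' @export
hypergeometric_p <- function(overlap, query_size, term_size, universe_size) {
  args <- c(overlap, query_size, term_size, universe_size)
  if (any(args != round_half_up(args)) || any(args < 0)) {
    abort("all counts must be nonnegative integers")
  }
  if (overlap > min(query_size, term_size) ||
      query_size > universe_size || term_size > universe_size ||
      overlap < query_size + term_size - universe_size) {
    abort("inconsistent counts for hypergeometric test")
  }
  phyper(overlap - 1, term_size, universe_size - term_size, query_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with cumulative-minimum enforcement, capped at 1;
#' input order is preserved.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the same order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation of a vector signature
#'
#' Tests each term of a gene-set collection for over-representation in a
#' vector's top-loading gene signature with the hypergeometric test and
#' adjusts across terms with Benjamini-Hochberg.
#'
#' The default universe is the profile's genes intersected with the union
#' of the collection's genes, the offline analogue of testing against a
#' full annotation database; `"matrix"` and `"collection"` use one side
#' only. The signature is intersected with the universe, terms are sized
#' within the universe, and terms absent from the universe are skipped.
#'
#' @param signature A `vector_signature` from [top_fraction_genes()].
#' @param sets Gene-set tibble from [read_gene_sets()].
#' @param matrix_genes Character vector of the profile's gene ids.
#' @param universe One of `"intersection"` (default), `"matrix"`,
#'   `"collection"`.
#' @return A tibble with `term_id`, `description`, `overlap`,
#'   `query_size`, `term_size`, `universe_size`, `p_value`, `fdr`, sorted
#'   by `fdr` then `p_value` ascending (most significant first).
#' @export
enrich <- function(signature, sets, matrix_genes,
                   universe = c("intersection", "matrix", "collection")) {
  stopifnot(inherits(signature, "vector_signature"))
  universe <- rlang::arg_match(universe)
  collection_genes <- unique(unlist(sets$genes))
  univ <- switch(universe,
    intersection = intersect(matrix_genes, collection_genes),
    matrix = unique(matrix_genes),
    collection = collection_genes)
  if (length(univ) == 0) abort("empty gene universe")
  query <- intersect(signature$top_genes, univ)
  res <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    term_genes <- intersect(sets$genes[[i]], univ)
    if (length(term_genes) == 0) return(NULL)
    ov <- length(intersect(query, term_genes))
    tibble(term_id = sets$term_id[i],
           description = sets$description[i],
           overlap = ov,
           query_size = length(query),
           term_size = length(term_genes),
           universe_size = length(univ),
           p_value = hypergeometric_p(ov, length(query), length(term_genes),
                                      length(univ)))
  })
  if (nrow(res) == 0) abort("no collection terms overlap the universe")
  res$fdr <- benjamini_hochberg(res$p_value)
  dplyr::arrange(res, .data$fdr, .data$p_value)
}
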