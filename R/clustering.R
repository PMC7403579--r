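#' Ward hierarchical clustering of compound profiles
#'
#' Agglomerative clustering of compound profiles with Euclidean distance
#' and Ward's minimum-increase-in-within-cluster-variance criterion
#' (`stats::hclust` method `"ward.D2"`: Lance-Williams on squared
#' distances, merge heights reported on the distance scale, the default of
#' the common scientific stacks). Whole-profile clustering is dominated by
#' each compound's largest effect, which is exactly why latent moderate
#' effects end up in different clusters from the strong inducers — the
#' contrast the decomposition is built to expose.
#'
#' By default clustering runs on the raw profiles; set
#' `unit_normalize = TRUE` to cluster the same direction-only profiles fed
#' to [decompose_profiles()].
#'
#' @param data Profile table or matrix with at least 2 compounds.
#' @param unit_normalize Scale each profile to unit L2 norm first.
#' @return An object of class `ward_dendrogram`: list with `hclust` (the
#'   fitted `stats::hclust` object), `merges` (tibble `step`, `a`, `b`,
#'   `height`, `size`; negative entries are leaves, positive entries refer
#'   to earlier merge steps, hclust convention), and `compound_ids`.
#' @export
ward_linkage <- function(data, unit_normalize = FALSE) {
  x <- as_profile_matrix(data)
  if (unit_normalize) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) {
      abort(sprintf("zero-norm profile for compound(s): %s",
                    fmt_ids(rownames(x)[nrm == 0])))
    }
    x <- x / nrm
  }
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- sum(vapply(hc$merge[i, ], function(v) {
      if (v < 0) 1L else sizes[v]
    }, integer(1)))
  }
  structure(list(hclust = hc,
                 merges = tibble(step = seq_len(nrow(hc$merge)),
                                 a = hc$merge[, 1], b = hc$merge[, 2],
                                 height = hc$height, size = sizes),
                 compound_ids = rownames(x)),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("Ward (Euclidean) dendrogram of %d compounds; merge heights %.3g .. %.3g\n",
              length(x$compound_ids), min(x$merges$height),
              max(x$merges$height)))
  invisible(x)
}

#' Cluster membership at a k-cluster cut
#'
#' @param dendrogram A `ward_dendrogram` from [ward_linkage()].
#' @param k Number of clusters, between 1 and the number of compounds.
#' @return A tibble with `compound_id` and integer `cluster`.
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  n <- length(dendrogram$compound_ids)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    abort(sprintf("`k` must be between 1 and %d", n))
  }
  cl <- cutree(dendrogram$hclust, k = k)
  tibble(compound_id = names(cl), cluster = unname(cl))
}

#' Do two compounds share a cluster at a k-cluster cut?
#'
#' @inheritParams cut_clusters
#' @param compound_a,compound_b Compound ids.
#' @return `TRUE` iff both compounds fall in the same cluster when the
#'   tree is cut into `k` clusters.
#' @export
co_clustered <- function(dendrogram, compound_a, compound_b, k) {
  members <- cut_clusters(dendrogram, k)
  for (cpd in c(compound_a, compound_b)) {
    if (!cpd %in% members$compound_id) {
      abort(sprintf("unknown compound '%s'", cpd))
    }
  }
  members$cluster[members$compound_id == compound_a] ==
    members$cluster[members$compound_id == compound_b]
}

#' Export a dendrogram as a merge table or Newick tree
#'
#' @param dendrogram A `ward_dendrogram`.
#' @param path Output path.
#' @param format `"tsv"` writes the flat merge table; `"newick"` writes a
#'   Newick tree (requires the ape package).
#' @return `dendrogram`, invisibly.
#' @export
write_dendrogram <- function(dendrogram, path, format = c("tsv", "newick")) {
  stopifnot(inherits(dendrogram, "ward_dendrogram"))
  format <- rlang::arg_match(format)
  if (format == "tsv") {
    readr::write_tsv(dendrogram$merges, path)
  } else {
    rlang::check_installed("ape")
    ape::write.tree(ape::as.phylo(dendrogram$hclust), file = path)
  }
  invisible(dendrogram)
}
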