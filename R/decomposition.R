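#' Total response strength of each compound
#'
#' The L2 norm of each compound's gene-expression-change profile: the
#' magnitude of the whole response, which the decomposition factors out of
#' the directional analysis so that response *direction* and response
#' *strength* are reported separately.
#'
#' @param data Profile table or matrix (see [as_profile_matrix()]).
#' @return A tibble with `compound_id` and nonnegative `strength`.
#' @examples
#' df <- tibble::tibble(compound_id = c("a", "b"), g1 = c(3, 0), g2 = c(4, 0))
#' total_strength(df) # a: 5, b: 0
#' @export
total_strength <- function(data) {
  x <- as_profile_matrix(data)
  tibble(compound_id = rownames(x), strength = unname(sqrt(rowSums(x^2))))
}

#' Number of components covering a cumulative variance threshold
#'
#' Smallest K such that the first K variance shares sum to at least
#' `threshold` (the canonical cutoff is 80% of the cumulative
#' contribution). Comparison uses a 1e-12 slack so that a threshold of 1
#' returns the numerical rank rather than overshooting it.
#'
#' @param variance_shares Nonnegative, non-increasing fractions summing to
#'   ~1 (e.g. squared singular values over their sum).
#' @param threshold Fraction in (0, 1].
#' @return Integer K.
#' @examples
#' select_component_count(c(0.5, 0.3, 0.15, 0.05), 0.8) # 2
#' @export
select_component_count <- function(variance_shares, threshold = 0.8) {
  s <- as.numeric(variance_shares)
  if (length(s) == 0) abort("variance shares must be non-empty")
  if (any(s < -1e-12)) abort("variance shares must be nonnegative")
  if (any(diff(s) > 1e-12)) abort("variance shares must be non-increasing")
  if (abs(sum(s) - 1) > 1e-6) abort("variance shares must sum to 1")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single value in (0, 1]")
  }
  K <- which(cumsum(s) >= threshold - 1e-12)[1]
  if (is.na(K)) K <- length(s)
  as.integer(K)
}

#' Orthogonal linear separation of compound response profiles
#'
#' Decomposes a compounds x genes differential-expression matrix into
#' orthogonal latent effect vectors with per-compound response scores:
#'
#' 1. record each compound's total strength (L2 norm);
#' 2. if `unit_normalize`, scale each compound row to unit norm so only the
#'    response *direction* is decomposed (zero-norm rows are an error);
#' 3. center each gene column to mean zero;
#' 4. singular value decomposition of the preprocessed matrix;
#' 5. retain the smallest K components whose squared-singular-value shares
#'    reach `threshold` (default 80% of the cumulative contribution);
#' 6. varimax-rotate the K retained loading columns ([varimax_rotate()]);
#' 7. recompute each rotated vector's explained variance (mean squared
#'    score) and reorder vectors by it, descending, naming them
#'    `P1V ... PKV` so `PXV` is the vector with the X-th highest variance;
#' 8. orient each vector so its largest-|loading| gene loads positively.
#'
#' Scores are projections of the preprocessed profiles onto the rotated
#' loadings; a compound's score on a vector is read as the strength of
#' that latent effect in its response.
#'
#' @param data Profile table or matrix (see [as_profile_matrix()]); at
#'   least 3 compounds.
#' @param threshold Cumulative-variance cutoff in (0, 1] for the retained
#'   subspace.
#' @param unit_normalize Scale each compound profile to unit L2 norm before
#'   decomposition (default `TRUE`).
#' @param varimax_tol,varimax_max_iter Convergence controls passed to
#'   [varimax_rotate()].
#' @return An object of class `olsa_fit`: a list with `loadings` (genes x
#'   K, columns `P1V...PKV`), `scores` (compounds x K), a named
#'   `explained_variance` vector of per-vector shares of total variance,
#'   `total_strength`, `singular_values`, `rotation` (K x K orthogonal,
#'   including reordering and sign flips), `threshold`, `preprocessing`,
#'   and `varimax` convergence metadata. Use [tidy()][tidy.olsa_fit],
#'   [glance()][glance.olsa_fit], [score_table()], [top_fraction_genes()].
#' @examples
#' sim <- simulate_profiles(n_compounds = 20, n_genes = 50, n_factors = 2,
#'                          noise_sd = 0.01, seed = 1)
#' fit <- decompose_profiles(sim$profile)
#' glance(fit)
#' @export
decompose_profiles <- function(data, threshold = 0.8, unit_normalize = TRUE,
                               varimax_tol = 1e-6, varimax_max_iter = 1000) {
  x <- as_profile_matrix(data)
  if (nrow(x) < 3) {
    abort(sprintf("decomposition needs at least 3 compounds (got %d)", nrow(x)))
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single value in (0, 1]")
  }
  strength <- sqrt(rowSums(x^2))
  if (unit_normalize) {
    zero <- which(strength == 0)
    if (length(zero) > 0) {
      abort(sprintf("zero-norm profile for compound(s): %s",
                    fmt_ids(rownames(x)[zero])))
    }
    x <- x / strength
  }
  gene_center <- colMeans(x)
  x <- sweep(x, 2, gene_center)

  sv <- svd(x)
  d2 <- sv$d^2
  total_var <- sum(d2)
  if (total_var == 0) abort("preprocessed matrix is identically zero")
  shares <- d2 / total_var
  K <- select_component_count(shares, threshold)

  vr <- varimax_rotate(sv$v[, seq_len(K), drop = FALSE],
                       tol = varimax_tol, max_iter = varimax_max_iter)
  L <- vr$loadings
  R <- vr$rotation
  scores <- x %*% L

  ev <- colSums(scores^2) / total_var
  ord <- order(-ev, seq_len(K))
  L <- L[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  ev <- ev[ord]
  R <- R[, ord, drop = FALSE]

  ## deterministic orientation: largest-|loading| gene loads positively
  for (j in seq_len(K)) {
    i_star <- which.max(abs(L[, j]))
    if (L[i_star, j] < 0) {
      L[, j] <- -L[, j]
      scores[, j] <- -scores[, j]
      R[, j] <- -R[, j]
    }
  }

  vnames <- paste0("P", seq_len(K), "V")
  dimnames(L) <- list(colnames(x), vnames)
  dimnames(scores) <- list(rownames(x), vnames)
  names(ev) <- vnames
  colnames(R) <- vnames

  structure(list(
    loadings = L,
    scores = scores,
    explained_variance = ev,
    total_strength = setNames(strength, rownames(x)),
    singular_values = sv$d,
    rotation = R,
    n_components = K,
    threshold = threshold,
    preprocessing = list(unit_normalize = unit_normalize,
                         gene_centered = TRUE,
                         gene_center = gene_center),
    varimax = list(iterations = vr$iterations, converged = vr$converged,
                   tol = varimax_tol, max_iter = varimax_max_iter,
                   criterion = vr$criterion),
    n_compounds = nrow(x),
    n_genes = ncol(x)
  ), class = "olsa_fit")
}

#' @export
print.olsa_fit <- function(x, ...) {
  cat(sprintf(
    "Orthogonal linear separation: %d compounds x %d genes -> %d vectors\n",
    x$n_compounds, x$n_genes, x$n_components))
  cat(sprintf("  cumulative variance threshold %.2f (retained %.3f)\n",
              x$threshold, sum(x$explained_variance)))
  cat(sprintf("  unit-normalized: %s; varimax sweeps: %d (converged: %s)\n",
              x$preprocessing$unit_normalize, x$varimax$iterations,
              x$varimax$converged))
  cat("  top vectors by explained variance share:\n")
  ev <- head(x$explained_variance, 5)
  for (v in names(ev)) cat(sprintf("    %-6s %.4f\n", v, ev[[v]]))
  invisible(x)
}

#' Per-compound response scores for one latent vector
#'
#' @param fit An `olsa_fit` from [decompose_profiles()].
#' @param vector_name Vector name, e.g. `"P14V"`.
#' @param sort Sort compounds by score, descending (default `FALSE`).
#' @return A tibble with `compound_id` and `score`.
#' @export
score_table <- function(fit, vector_name, sort = FALSE) {
  stopifnot(inherits(fit, "olsa_fit"))
  check_vector_name(fit, vector_name)
  out <- tibble(compound_id = rownames(fit$scores),
                score = unname(fit$scores[, vector_name]))
  if (sort) out <- dplyr::arrange(out, dplyr::desc(.data$score))
  out
}

check_vector_name <- function(fit, vector_name) {
  valid <- colnames(fit$scores)
  if (!is.character(vector_name) || length(vector_name) != 1 ||
      !vector_name %in% valid) {
    abort(sprintf("unknown vector '%s'; valid vectors: %s",
                  as.character(vector_name)[1],
                  paste(valid, collapse = ", ")))
  }
  invisible(vector_name)
}
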