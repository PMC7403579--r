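# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / brute force) and share no code with the
# package implementation paths they check.

# Hypergeometric upper tail by full enumeration over all query draws.
oracle_hyper_p <- function(overlap, query, term, universe) {
  draws <- combn(universe, query)
  in_term <- seq_len(term) # wlog the first `term` elements form the term
  hits <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(hits >= overlap)
}

# Varimax criterion (the definition, written independently).
oracle_varimax_crit <- function(L) {
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}

# Best rotation angle for a 2-column problem by exhaustive grid search.
oracle_varimax_angle <- function(L, step = 1e-4) {
  angles <- seq(0, pi / 2, by = step)
  crits <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    oracle_varimax_crit(L %*% R)
  }, numeric(1))
  list(angle = angles[which.max(crits)], criterion = max(crits))
}

# Ward agglomeration by direct minimization of the increase in total
# within-cluster sum of squares (no Lance-Williams recurrence).
oracle_ward_merges <- function(x) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    cen <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2, cen)^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      delta_ess = best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Members of each merged cluster from an hclust object, in merge order.
hclust_merge_members <- function(hc) {
  members <- list()
  out <- list()
  for (i in seq_len(nrow(hc$merge))) {
    m <- unlist(lapply(hc$merge[i, ], function(v) {
      if (v < 0) -v else members[[v]]
    }))
    members[[i]] <- m
    out[[i]] <- sort(m)
  }
  out
}

# Random profile tibble with reproducible entries.
random_profile <- function(n_compounds, n_genes, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_compounds * n_genes), n_compounds, n_genes,
                dimnames = list(sprintf("c%03d", seq_len(n_compounds)),
                                sprintf("g%03d", seq_len(n_genes))))
    latentfx::profile_tbl(x)
  })
}

# Random orthonormal columns.
random_orthonormal <- function(n, k, seed) {
  withr::with_seed(seed, qr.Q(qr(matrix(rnorm(n * k), n, k))))
}
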