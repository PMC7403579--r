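#' Median and interquartile range of a score distribution
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the default of the common scientific
#' stacks); median + m*IQR cutoffs shift under other conventions, so the
#' convention is fixed and documented here.
#'
#' @param scores Numeric vector (length >= 2), or a tibble with a `score`
#'   column.
#' @return A tibble with `median` and `iqr`.
#' @examples
#' distribution_stats(c(1, 2, 3, 4)) # median 2.5, iqr 1.5
#' @export
distribution_stats <- function(scores) {
  s <- pull_scores(scores)
  if (length(s) < 2) abort("need at least 2 scores")
  q <- quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(median = q[2], iqr = q[3] - q[1])
}

pull_scores <- function(scores) {
  if (is.data.frame(scores)) {
    if (!"score" %in% names(scores)) abort("score table needs a `score` column")
    s <- scores$score
  } else {
    s <- as.numeric(scores)
  }
  if (any(!is.finite(s))) abort("scores must be finite")
  s
}

score_tbl <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("compound_id", "score") %in% names(scores))) {
      abort("score table needs `compound_id` and `score` columns")
    }
    tibble(compound_id = as.character(scores$compound_id),
           score = pull_scores(scores))
  } else {
    if (is.null(names(scores))) abort("scores must be named or a tibble")
    tibble(compound_id = names(scores), score = pull_scores(scores))
  }
}

#' Compounds at or above a median + m*IQR score cutoff
#'
#' The comparison is inclusive (`>=`), so with a degenerate (zero-IQR)
#' distribution every compound at the median is a hit.
#'
#' @param scores Tibble with `compound_id` and `score`, or a named numeric
#'   vector.
#' @param m Nonnegative IQR multiplier.
#' @return A tibble of hits with `compound_id`, `score`, and the `cutoff`
#'   applied, sorted by score descending.
#' @examples
#' threshold_hits(c(a = 1, b = 2, c = 3, d = 4), m = 0.75) # cutoff 3.625
#' @export
threshold_hits <- function(scores, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 0) {
    abort("`m` must be a single nonnegative number")
  }
  tb <- score_tbl(scores)
  st <- distribution_stats(tb$score)
  cutoff <- st$median + m * st$iqr
  dplyr::arrange(
    dplyr::mutate(dplyr::filter(tb, .data$score >= cutoff), cutoff = cutoff),
    dplyr::desc(.data$score))
}

#' Categorize compounds on one latent vector's score distribution
#'
#' Splits a score distribution into candidate categories:
#' * `high` — score at or above `median + high_m * IQR`; the
#'   strong, typically already-recognized responders.
#' * `moderate` — score in `[median + moderate_m * IQR, median + high_m *
#'   IQR)` *and* flag `FALSE` (no prior report); the latent-effect
#'   candidates.
#' * `negative` — the `n_negative` compounds with the smallest absolute
#'   score (ties broken by compound id); predicted non-responders. A
#'   negative candidate that also meets the moderate cutoff is a
#'   contradiction and raises an error.
#' * `other` — everything else.
#'
#' @param scores Tibble with `compound_id` and `score` (e.g. from
#'   [score_table()]), or a named numeric vector.
#' @param flags Optional tibble with `compound_id` and logical `flag`
#'   (e.g. prior-publication status from [read_flags()]); compounds
#'   missing from `flags` are treated as unflagged.
#' @param moderate_m,high_m IQR multipliers, `high_m > moderate_m`.
#'   Defaults: 0.75 for moderate (the canonical moderate-candidate
#'   cutoff) and 2 for high.
#' @param n_negative Number of predicted negatives (must be smaller than
#'   the number of compounds).
#' @return An object of class `selection_report`: a tibble with
#'   `compound_id`, `score`, `flag`, `category`, carrying the distribution
#'   stats and cutoffs as attributes (`median`, `iqr`, `cutoffs`).
#' @export
categorize <- function(scores, flags = NULL, moderate_m = 0.75, high_m = 2,
                       n_negative = 3) {
  tb <- score_tbl(scores)
  if (!is.numeric(high_m) || !is.numeric(moderate_m) || high_m <= moderate_m) {
    abort("`high_m` must be greater than `moderate_m`")
  }
  if (n_negative >= nrow(tb)) {
    abort(sprintf("`n_negative` (%d) must be smaller than the number of compounds (%d)",
                  n_negative, nrow(tb)))
  }
  tb <- join_flags(tb, flags)
  st <- distribution_stats(tb$score)
  cut_mod <- st$median + moderate_m * st$iqr
  cut_high <- st$median + high_m * st$iqr

  tb$category <- "other"
  tb$category[tb$score >= cut_high] <- "high"
  tb$category[tb$score >= cut_mod & tb$score < cut_high & !tb$flag] <- "moderate"

  neg_idx <- order(abs(tb$score), tb$compound_id)[seq_len(n_negative)]
  if (any(tb$score[neg_idx] >= cut_mod)) {
    abort("smallest-|score| compounds overlap the moderate cutoff; negative set is ill-defined for this distribution")
  }
  tb$category[neg_idx] <- "negative"

  structure(tb,
            median = st$median, iqr = st$iqr,
            cutoffs = c(moderate = cut_mod, high = cut_high),
            moderate_m = moderate_m, high_m = high_m,
            class = c("selection_report", class(tb)))
}

join_flags <- function(tb, flags) {
  if (is.null(flags)) {
    tb$flag <- FALSE
    return(tb)
  }
  if (!all(c("compound_id", "flag") %in% names(flags))) {
    abort("`flags` needs `compound_id` and `flag` columns")
  }
  out <- dplyr::left_join(tb,
                          dplyr::select(flags, "compound_id", "flag"),
                          by = "compound_id")
  out$flag[is.na(out$flag)] <- FALSE
  out
}

#' Marker-gene indicator
#'
#' A conventional single-gene indicator: the marker gene's
#' differential-expression column, read as a per-compound score (e.g. a
#' canonical stress-marker transcript).
#'
#' @param data Profile table or matrix.
#' @param marker_gene Gene id present in the profile.
#' @return A tibble with `compound_id` and `score`.
#' @export
marker_indicator <- function(data, marker_gene) {
  x <- as_profile_matrix(data)
  if (!marker_gene %in% colnames(x)) {
    abort(sprintf("unknown marker gene '%s'", marker_gene))
  }
  tibble(compound_id = rownames(x), score = unname(x[, marker_gene]))
}

#' Reference-compound correlation indicator
#'
#' A conventional similarity indicator: the Pearson correlation of each
#' compound's profile with a chosen reference compound's profile (e.g. a
#' well-known inducer of the effect of interest).
#'
#' @param data Profile table or matrix; every profile must be
#'   non-constant.
#' @param reference_compound Compound id present in the profile.
#' @return A tibble with `compound_id` and `score` (Pearson r; the
#'   reference correlates 1 with itself).
#' @export
reference_correlation <- function(data, reference_compound) {
  x <- as_profile_matrix(data)
  if (!reference_compound %in% rownames(x)) {
    abort(sprintf("unknown reference compound '%s'", reference_compound))
  }
  sds <- apply(x, 1, sd)
  flat <- which(sds == 0)
  if (length(flat) > 0) {
    abort(sprintf("constant profile (zero variance) for compound(s): %s",
                  fmt_ids(rownames(x)[flat])))
  }
  r <- as.numeric(cor(t(x), x[reference_compound, ]))
  tibble(compound_id = rownames(x), score = r)
}

#' Compare detection indicators across IQR thresholds
#'
#' For each indicator (latent-vector score, marker-gene expression,
#' reference-compound correlation, ...) and each IQR multiplier, computes
#' the hit set at `median + m * IQR` of that indicator's own distribution
#' and splits the hits into flagged (e.g. previously reported) and
#' unflagged counts — the tabular analogue of comparing hit bars across
#' indicators.
#'
#' @param indicators Named list of score tables (each with `compound_id`
#'   and `score`), or a single score table.
#' @param m_values Numeric vector of nonnegative IQR multipliers.
#' @param flags Optional flags tibble (see [categorize()]).
#' @return A tibble with `indicator`, `m`, `cutoff`, `n_hits`,
#'   `n_flagged`, `n_unflagged`, and a `hits` list-column of compound ids
#'   (hit sets at larger `m` are always subsets of those at smaller `m`).
#' @export
compare_indicators <- function(indicators, m_values, flags = NULL) {
  if (is.data.frame(indicators)) indicators <- list(indicator = indicators)
  if (length(indicators) == 0 || is.null(names(indicators)) ||
      any(!nzchar(names(indicators)))) {
    abort("`indicators` must be a non-empty named list of score tables")
  }
  if (length(m_values) == 0 || any(m_values < 0)) {
    abort("`m_values` must be nonnegative")
  }
  purrr::map_dfr(names(indicators), function(nm) {
    tb <- join_flags(score_tbl(indicators[[nm]]), flags)
    purrr::map_dfr(m_values, function(m) {
      hits <- threshold_hits(tb, m)
      flagged <- tb$flag[match(hits$compound_id, tb$compound_id)]
      tibble(indicator = nm, m = m,
             cutoff = if (nrow(hits) > 0) hits$cutoff[1] else
               distribution_stats(tb$score)$median + m * distribution_stats(tb$score)$iqr,
             n_hits = nrow(hits),
             n_flagged = sum(flagged),
             n_unflagged = sum(!flagged),
             hits = list(hits$compound_id))
    })
  })
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. For families of comparisons, adjust
#' the resulting p-values with [benjamini_hochberg()].
#'
#' @param group_a,group_b Numeric vectors (each length >= 2); at least one
#'   group must have nonzero variance.
#' @return A tibble with `estimate` (mean difference a - b), `t`, `df`,
#'   `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  if (var(a) == 0 && var(b) == 0) {
    abort("both groups have zero variance; Welch's t is undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(estimate = mean(a) - mean(b),
         t = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Permutation test for a difference in group means
#'
#' Two-sided test on `|mean(a) - mean(b)|` under relabelling. When the
#' number of distinct splits `choose(n, n_a)` is at most 10,000 the null
#' distribution is enumerated exhaustively and the p-value is the exact
#' tail fraction; otherwise `n_perm` random relabellings are drawn and
#' `p = (1 + #{|d*| >= |d|}) / (n_perm + 1)`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param n_perm Number of random permutations for the Monte Carlo path.
#' @param seed Integer seed; required on the Monte Carlo path so results
#'   are reproducible.
#' @return A tibble with `p_value`, `method` (`"exhaustive"` or
#'   `"monte_carlo"`), and `n_perm` (splits examined).
#' @examples
#' permutation_test(c(1, 2), c(100, 101)) # exhaustive, p = 2/6
#' @export
permutation_test <- function(group_a, group_b, n_perm = 9999, seed = NULL) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) abort("groups must be non-empty")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-12 * max(1, obs)
  if (choose(n, na) <= 10000) {
    splits <- combn(n, na)
    d <- apply(splits, 2, function(idx) {
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    tibble(p_value = sum(d >= obs - tol) / ncol(splits),
           method = "exhaustive", n_perm = ncol(splits))
  } else {
    if (is.null(seed)) abort("`seed` is required for the Monte Carlo path")
    d <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1)))
    tibble(p_value = (1 + sum(d >= obs - tol)) / (n_perm + 1),
           method = "monte_carlo", n_perm = as.integer(n_perm))
  }
}
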