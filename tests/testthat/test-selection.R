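test_that("distribution stats use linear-interpolation quantiles", {
  st <- distribution_stats(c(1, 2, 3, 4))
  expect_equal(st$median, 2.5)
  expect_equal(st$iqr, 1.5) # Q3 = 3.25, Q1 = 1.75
  expect_equal(distribution_stats(c(5, 5, 5))$iqr, 0)
  st2 <- distribution_stats(c(0, 10))
  expect_equal(st2$median, 5)
  expect_equal(st2$iqr, 5)
  expect_error(distribution_stats(3), "at least 2")
})

test_that("threshold hits apply median + m*IQR inclusively", {
  s <- c(a = 1, b = 2, c = 3, d = 4)
  hits <- threshold_hits(s, 0.75)
  expect_equal(hits$cutoff[1], 3.625) # 2.5 + 0.75 * 1.5
  expect_equal(hits$compound_id, "d")
  # m = 0: everything at or above the median
  expect_setequal(threshold_hits(s, 0)$compound_id, c("c", "d"))
  # degenerate zero-IQR distribution: all compounds equal the cutoff
  expect_equal(nrow(threshold_hits(c(a = 2, b = 2, c = 2), 5)), 3)
  expect_error(threshold_hits(s, -1), "nonnegative")
})

test_that("categorize partitions compounds into exclusive categories", {
  scores <- c(hi = 10, m1 = 4.2, m2 = 4.1, z1 = 0, z2 = 0, z3 = 0,
              a = -1, b = 1, c = -2, d = 2)
  flags <- tibble::tibble(compound_id = c("m1", "m2", "hi"),
                          flag = c(FALSE, FALSE, TRUE))
  rep <- categorize(scores, flags, moderate_m = 0.75, high_m = 2,
                    n_negative = 3)
  expect_setequal(rep$compound_id[rep$category == "negative"],
                  c("z1", "z2", "z3")) # the three exact zeros
  expect_true(all(table(rep$compound_id) == 1))
  expect_setequal(unique(rep$category),
                  c("high", "moderate", "negative", "other"))

  # all-flagged cohort has an empty moderate set
  all_flagged <- tibble::tibble(compound_id = names(scores), flag = TRUE)
  rep2 <- categorize(scores, all_flagged)
  expect_identical(sum(rep2$category == "moderate"), 0L)

  expect_error(categorize(scores, n_negative = 10), "smaller than")
  expect_error(categorize(scores, moderate_m = 2, high_m = 1), "greater than")
})

test_that("categorize is always a partition on random score tables", {
  for (seed in 1:20) {
    withr::local_seed(seed)
    n <- sample(8:40, 1)
    s <- setNames(rnorm(n), sprintf("c%02d", seq_len(n)))
    rep <- tryCatch(categorize(s, n_negative = 3), error = function(e) e)
    # the negative/moderate overlap guard may fire; any other outcome
    # must be a full partition
    if (inherits(rep, "error")) {
      expect_match(conditionMessage(rep), "negative set")
    } else {
      expect_equal(nrow(rep), n)
      expect_true(all(rep$category %in%
                        c("high", "moderate", "negative", "other")))
      expect_identical(sum(rep$category == "negative"), 3L)
    }
  }
})

test_that("marker indicator extracts the gene column", {
  df <- tibble::tibble(compound_id = c("a", "b"), g1 = c(0.1, 2), g2 = c(5, 6))
  ind <- marker_indicator(df, "g1")
  expect_equal(ind$score, c(0.1, 2))
  expect_error(marker_indicator(df, "gX"), "unknown marker")
  # hits on a marker indicator share the threshold code path
  expect_equal(threshold_hits(ind, 0)$cutoff[1],
               distribution_stats(c(0.1, 2))$median)
})

test_that("reference correlation matches hand-computed Pearson r", {
  x <- matrix(c(1, 2, 3,
                2, 4, 6,
                1, 2, 4,
                3, 2, 1), 4, 3, byrow = TRUE,
              dimnames = list(c("ref", "double", "near", "anti"),
                              c("g1", "g2", "g3")))
  r <- reference_correlation(profile_tbl(x), "ref")
  expect_equal(r$score[r$compound_id == "ref"], 1)
  expect_equal(r$score[r$compound_id == "double"], 1)
  expect_equal(r$score[r$compound_id == "anti"], -1)
  # hand computation: cor((1,2,3), (1,2,4)) = 0.981981
  expect_equal(r$score[r$compound_id == "near"], 0.98198, tolerance = 1e-5)

  xc <- rbind(x, flat = c(2, 2, 2))
  expect_error(reference_correlation(profile_tbl(xc), "ref"), "flat")
  expect_error(reference_correlation(profile_tbl(x), "nope"), "unknown reference")
})

test_that("indicator hit sets are monotone in m and split by flags", {
  withr::local_seed(8)
  for (i in 1:10) {
    s <- setNames(rnorm(30), sprintf("c%02d", 1:30))
    cmp <- compare_indicators(list(ind = tibble::tibble(
      compound_id = names(s), score = unname(s))),
      m_values = c(0, 0.5, 1, 2))
    for (j in 2:4) {
      expect_true(all(cmp$hits[[j]] %in% cmp$hits[[j - 1]]))
    }
    expect_equal(cmp$n_hits, cmp$n_flagged + cmp$n_unflagged)
    expect_equal(cmp$n_flagged, rep(0L, 4)) # no flags: all unflagged
  }
})

test_that("the decomposition score sees masked inducers that markers miss", {
  bm <- get_benchmark()
  cmp <- compare_indicators(
    list(vector_score = score_table(bm$fit, bm$target_vector),
         marker = marker_indicator(bm$profile, bm$marker_gene)),
    m_values = 1, flags = bm$flags)
  vec_hits <- cmp$hits[[which(cmp$indicator == "vector_score")]]
  mk_hits <- cmp$hits[[which(cmp$indicator == "marker")]]
  expect_true(all(bm$truth$masked_set %in% vec_hits))
  expect_length(intersect(bm$truth$masked_set, mk_hits), 0)
})

test_that("Welch's t matches the hand formula and rejects degenerate input", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  res <- welch_t_test(a, b)
  # independent hand computation of the Welch statistic
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)   # -2.1909
  expect_equal(res$df, df_hand, tolerance = 1e-12) # 6
  expect_equal(res$p_value, 2 * pt(t_hand, df_hand), tolerance = 1e-12)

  eq <- welch_t_test(c(1, 2, 3), c(2, 2, 2))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  expect_error(welch_t_test(c(0, 0, 0), c(1, 1, 1)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("permutation test enumerates exhaustively and is seed-stable", {
  # identical groups: every relabelling ties the observed difference
  expect_equal(permutation_test(c(1, 2), c(1, 2))$p_value, 1)
  # C(4,2) = 6 splits; only the original split and its mirror reach |99|
  res <- permutation_test(c(1, 2), c(100, 101))
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(res$method, "exhaustive")

  # Monte Carlo path: choose(16, 8) > 10000 forces sampling
  withr::local_seed(1)
  a <- rnorm(8); b <- rnorm(8) + 1
  r1 <- permutation_test(a, b, n_perm = 500, seed = 42)
  r2 <- permutation_test(a, b, n_perm = 500, seed = 42)
  expect_identical(r1$method, "monte_carlo")
  expect_identical(r1$p_value, r2$p_value)
  expect_error(permutation_test(a, b, n_perm = 500), "seed")
  expect_error(permutation_test(numeric(0), b), "non-empty")
})
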