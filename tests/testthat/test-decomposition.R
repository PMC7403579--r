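test_that("total strength is the per-compound L2 norm", {
  df <- tibble::tibble(compound_id = c("a", "b", "c"),
                       g1 = c(3, 0, 0.6), g2 = c(4, 0, 0.8))
  st <- total_strength(df)
  expect_equal(st$strength, c(5, 0, 1)) # 3-4-5 triangle, zero, unit row
})

test_that("component count is the smallest K reaching the cumulative threshold", {
  shares <- c(0.5, 0.3, 0.15, 0.05)
  expect_identical(select_component_count(shares, 0.8), 2L)
  expect_identical(select_component_count(shares, 1.0), 4L)
  expect_identical(select_component_count(1.0, 0.8), 1L)
  expect_identical(select_component_count(shares, 0.81), 3L)
  expect_error(select_component_count(numeric(0), 0.8), "non-empty")
  expect_error(select_component_count(c(0.3, 0.5, 0.2), 0.8), "non-increasing")
  expect_error(select_component_count(c(0.6, 0.3), 0.8), "sum to 1")
  expect_error(select_component_count(shares, 0), "0, 1")
})

test_that("varimax fixes simple structure, is identity for K = 1, rejects bad input", {
  # perfectly simple structure: already a varimax fixed point
  L <- cbind(c(rep(1 / sqrt(3), 3), rep(0, 3)),
             c(rep(0, 3), rep(1 / sqrt(3), 3)))
  r <- varimax_rotate(L)
  expect_equal(abs(r$rotation), diag(2), tolerance = 1e-8)
  expect_equal(r$loadings, L %*% r$rotation, tolerance = 1e-12)

  one <- matrix(rnorm(8), 8, 1)
  one <- one / sqrt(sum(one^2))
  r1 <- varimax_rotate(one)
  expect_identical(r1$rotation, matrix(1, 1, 1))
  expect_identical(r1$loadings, one)

  expect_error(varimax_rotate(matrix(rnorm(12), 6, 2)), "orthonormal")
})

test_that("varimax recovers a known planar rotation to grid-search accuracy", {
  L <- cbind(c(rep(1 / sqrt(3), 3), rep(0, 3)),
             c(rep(0, 3), rep(1 / sqrt(3), 3)))
  theta <- 30 * pi / 180
  Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  L30 <- L %*% Rot

  fit <- varimax_rotate(L30, tol = 1e-10)
  oracle <- oracle_varimax_angle(L30)
  expect_equal(fit$criterion, oracle$criterion, tolerance = 1e-6)
  # recovered angle agrees with the exhaustive grid modulo the symmetry
  # group of the two-column criterion (quarter-turns and reflections)
  ang <- atan2(fit$rotation[2, 1], fit$rotation[1, 1])
  d <- min(vapply(c(ang, -ang), function(a) {
    m <- (a - oracle$angle) %% (pi / 2)
    min(m, pi / 2 - m)
  }, numeric(1)))
  expect_lt(d, 1e-3)
})

test_that("varimax agrees with an independent implementation on random problems", {
  for (seed in 1:5) {
    L <- random_orthonormal(40, 3, seed)
    mine <- varimax_rotate(L, tol = 1e-10)
    ref <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
    expect_equal(mine$criterion, oracle_varimax_crit(unclass(ref$loadings)),
                 tolerance = 1e-8)
  }
})

test_that("decompose recovers planted loadings exactly in the noiseless case", {
  # 2 orthonormal simple-structure loading columns over 20 genes
  L <- matrix(0, 20, 2)
  L[1:10, 1] <- (1:10) / sqrt(sum((1:10)^2))
  L[11:20, 2] <- (10:1) / sqrt(sum((10:1)^2))
  # full-rank scores with zero column means so centering is a no-op,
  # balanced so neither component alone reaches the 80% cutoff
  s1 <- c(3, -3, 2, -2, 1, -1, 1.5, -1.5)
  s2 <- c(2, 2, -2, -2, 1.5, -1.5, -1, 1)
  S <- cbind(s1, s2)
  x <- S %*% t(L)
  dimnames(x) <- list(paste0("c", 1:8), paste0("g", 1:20))

  fit <- decompose_profiles(profile_tbl(x), unit_normalize = FALSE)
  expect_identical(fit$n_components, 2L)
  cos <- abs(crossprod(L, fit$loadings))
  # best one-to-one assignment over both permutations
  best <- max(cos[1, 1] + cos[2, 2], cos[1, 2] + cos[2, 1]) / 2
  expect_gte(best, 0.999)
})

test_that("scores times loadings reproduce the retained-subspace projection", {
  prof <- random_profile(12, 30, seed = 42)
  fit <- decompose_profiles(prof, threshold = 0.6)
  x <- as_profile_matrix(prof)
  x <- scale(x / sqrt(rowSums(x^2)), scale = FALSE)
  sv <- svd(x)
  K <- fit$n_components
  proj <- x %*% sv$v[, 1:K] %*% t(sv$v[, 1:K])
  expect_equal(max(abs(fit$scores %*% t(fit$loadings) - proj)), 0,
               tolerance = 1e-8)
})

test_that("threshold 1 retains exactly the numerical rank", {
  set.seed(7)
  x <- matrix(rnorm(10 * 4), 10, 4) %*% matrix(rnorm(4 * 12), 4, 12)
  dimnames(x) <- list(paste0("c", 1:10), paste0("g", 1:12))
  fit <- decompose_profiles(profile_tbl(x), threshold = 1,
                            unit_normalize = FALSE)
  rank_oracle <- qr(scale(x, scale = FALSE))$rank
  expect_identical(fit$n_components, as.integer(rank_oracle))
})

test_that("degenerate inputs are rejected with informative errors", {
  df <- tibble::tibble(compound_id = c("a", "b", "zero"),
                       g1 = c(1, 2, 0), g2 = c(2, 1, 0))
  expect_error(decompose_profiles(df), "zero-norm.*zero")
  df2 <- tibble::tibble(compound_id = c("a", "b"), g1 = c(1, 2), g2 = c(2, 1))
  expect_error(decompose_profiles(df2), "at least 3 compounds")
  expect_error(decompose_profiles(random_profile(5, 6, 1), threshold = 1.5),
               "0, 1")
})

test_that("score tables extract named vectors and reject unknown names", {
  prof <- random_profile(10, 20, seed = 3)
  fit <- decompose_profiles(prof, threshold = 0.5)
  tb <- score_table(fit, "P2V")
  expect_equal(tb$score, unname(fit$scores[, "P2V"]))
  expect_equal(tb$compound_id, rownames(fit$scores))
  srt <- score_table(fit, "P1V", sort = TRUE)
  expect_true(!is.unsorted(rev(srt$score)))
  expect_error(score_table(fit, "P99V"), "P1V")
})

test_that("decomposition is bit-reproducible on a fixed input", {
  prof <- random_profile(15, 40, seed = 11)
  f1 <- decompose_profiles(prof)
  f2 <- decompose_profiles(prof)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$scores, f2$scores)
})

test_that("decomposition invariants hold on random matrices", {
  for (seed in 1:25) {
    withr::local_seed(seed)
    n <- sample(4:20, 1)
    p <- sample(10:60, 1)
    fit <- decompose_profiles(random_profile(n, p, seed = seed + 1000),
                              threshold = runif(1, 0.4, 1))
    K <- fit$n_components
    # orthonormal loadings
    expect_lt(max(abs(crossprod(fit$loadings) - diag(K))), 1e-8)
    # variance ordering
    expect_true(all(diff(fit$explained_variance) <= 1e-12))
    # rotation orthogonal and consistent with loadings
    expect_lt(max(abs(crossprod(fit$rotation) - diag(K))), 1e-10)
    # rotation preserves total retained variance
    x <- as_profile_matrix(random_profile(n, p, seed = seed + 1000))
    x <- scale(x / sqrt(rowSums(x^2)), scale = FALSE)
    sv <- svd(x)
    pre <- sum(sv$d[1:K]^2) / sum(sv$d^2)
    expect_equal(sum(fit$explained_variance), pre, tolerance = 1e-10)
    # sign convention: largest-|loading| gene loads positively
    for (j in seq_len(K)) {
      expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
    }
  }
})

test_that("planted factors and scores are recovered on the masked benchmark", {
  bm <- get_benchmark()
  expect_true(all(bm$matching$cosine >= 0.9))
  expect_true(all(bm$matching$score_cor >= 0.9))
  # planted strong inducers occupy the top ranks of the target vector
  top <- score_table(bm$fit, bm$target_vector, sort = TRUE)
  expect_setequal(top$compound_id[1:5], bm$truth$strong_set)
})

test_that("tidiers return well-formed tibbles", {
  prof <- random_profile(8, 15, seed = 5)
  fit <- decompose_profiles(prof, threshold = 0.6)
  expect_equal(nrow(tidy(fit, "scores")), 8 * fit$n_components)
  expect_equal(nrow(tidy(fit, "loadings")), 15 * fit$n_components)
  expect_named(tidy(fit, "variance"), c("vector", "explained_variance"))
  expect_equal(nrow(glance(fit)), 1)
})
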