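test_that("parameter correlation matrix has 1485 unique pairs", {
  X <- sample_parameters(n = 60, seed = 31)
  cm <- parameter_correlations(X)
  expect_equal(dim(cm$r), c(55, 55))
  expect_equal(cm$n_pairs, 55 * 54 / 2)  # 1485
  expect_equal(unname(diag(cm$r)), rep(1, 55))
  expect_equal(cm$r, t(cm$r))
  # an injected linear dependence is recovered as r ~ 1
  X2 <- X
  X2[, "gbar_KDR"] <- 2 * X2[, "gbar_NaF"] + 0.5
  cm2 <- parameter_correlations(X2)
  expect_equal(cm2$r["gbar_NaF", "gbar_KDR"], 1, tolerance = 1e-9)
  # a constant column is reported as missing, not zero
  X3 <- X
  X3[, "Cm"] <- 1
  cm3 <- parameter_correlations(X3)
  expect_true(all(is.na(cm3$r["Cm", setdiff(colnames(X3), "Cm")])))
})

test_that("measurement correlation matrix has 91 unique pairs", {
  set.seed(4)
  M <- matrix(rnorm(40 * 14), 40, 14,
              dimnames = list(NULL, paste0("m", 1:14)))
  cm <- measurement_correlations(as.data.frame(M))
  expect_equal(cm$n_pairs, 14 * 13 / 2)  # 91
  M2 <- cbind(M, m15 = M[, 5])
  cm2 <- parameter_correlations(M2)
  expect_equal(cm2$r["m5", "m15"], 1)
})

test_that("normalized Euclidean distances match their brute-force oracle", {
  space <- parameter_space()
  X <- sample_parameters(space, n = 8, seed = 17)
  d <- normalized_euclidean(X, space)
  expect_equal(diag(d$D), rep(0, 8), ignore_attr = TRUE)
  expect_equal(d$D, t(d$D))
  expect_equal(d$max_distance, sqrt(55))
  # brute-force sum of squares for one pair
  xn <- (X[3, ] - space$min) / (space$max - space$min)
  yn <- (X[7, ] - space$min) / (space$max - space$min)
  expect_equal(d$D[3, 7], sqrt(sum((xn - yn)^2)), tolerance = 1e-9)
  # the two extreme synthetic vectors are sqrt(55) apart
  ext <- rbind(space$min, space$max)
  colnames(ext) <- space$name
  expect_equal(normalized_euclidean(ext, space)$D[1, 2], sqrt(55),
               tolerance = 1e-12)
  expect_equal(normalized_euclidean(X[c(1, 1), ], space)$D[1, 2], 0)
})

test_that("Mahalanobis distances match the quadratic-form oracle", {
  space <- parameter_space()
  X <- sample_parameters(space, n = 120, seed = 23)
  d <- mahalanobis_distances(X, space)
  expect_false(d$regularized)
  S <- cov(X)
  delta <- X[5, ] - X[9, ]
  oracle <- sqrt(drop(delta %*% solve(S, delta)))
  expect_equal(d$D[5, 9], oracle, tolerance = 1e-9)
  # with identity covariance the metric reduces to plain Euclidean
  d_id <- mahalanobis_distances(X, space, sigma = diag(55),
                                regularize = FALSE)
  expect_equal(d_id$D, as.matrix(dist(X)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # n <= p triggers recorded diagonal-loading regularization
  d_small <- mahalanobis_distances(X[1:20, ], space)
  expect_true(d_small$regularized)
  # normalization constant is the x_max/x_min distance under the same Sigma
  Si <- solve(S)
  dmax <- sqrt(drop((space$max - space$min) %*% Si %*%
                    (space$max - space$min)))
  expect_equal(d$max_distance, dmax, tolerance = 1e-9)
})

test_that("distance matrices satisfy the triangle inequality", {
  space <- parameter_space()
  X <- sample_parameters(space, n = 60, seed = 41)
  for (D in list(normalized_euclidean(X, space)$D,
                 mahalanobis_distances(X, space)$D)) {
    set.seed(1)
    for (k in 1:50) {
      ijk <- sample(nrow(D), 3)
      expect_lte(D[ijk[1], ijk[2]],
                 D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
    }
  }
})

test_that("cross-set comparisons behave under null and shifted samples", {
  set.seed(8)
  a <- rnorm(40, -62, 1)
  r_self <- compare_sets(list(a, a))
  expect_equal(r_self$kruskal_p, 1, tolerance = 0.1)
  expect_equal(r_self$pairwise_p[1, 2], 1)
  # a 10-mV shift is detected with high power at n >= 30 per set
  r_shift <- compare_sets(list(a, a + 10))
  expect_lt(r_shift$kruskal_p, 0.01)
  expect_lt(r_shift$pairwise_p[1, 2], 0.01)
  expect_error(compare_sets(list(a)), "at least 2")
  expect_error(compare_sets(list(a, numeric(0))), "at least 2 valid")
})
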