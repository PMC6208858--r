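test_that("every family is amenable and inverts exactly on its range", {
  fams <- list(
    zeta_transform("affine", alpha = 2.5, beta = 0),
    zeta_transform("affine", alpha = 0.7, beta = 0.2),
    zeta_transform("stretched_exp", a = 0.75, b = 4 / 3, c = 1),
    zeta_transform("stretched_exp", a = 0.6, b = 1, c = 0.8),
    zeta_transform("jukes_cantor", k = 4),
    zeta_transform("jukes_cantor", k = 20),
    zeta_transform("neg_log", s = 10, m = 1)
  )
  set.seed(3)
  t <- c(0, sort(runif(50, 1e-6, 3)))
  for (z in fams) {
    expect_identical(zeta_eval(z, 0), 0)
    d <- zeta_eval(z, t)
    expect_true(all(diff(d) > 0))         # strictly increasing
    expect_lt(max(abs(zeta_inverse_eval(z, d) - t)), 1e-10)
  }
})

test_that("saturating families refuse values at or past their ceiling", {
  z <- zeta_transform("stretched_exp", a = 0.75, b = 1, c = 1)
  expect_error(zeta_inverse_eval(z, 0.75), "saturated")
  expect_error(zeta_inverse_eval(z, 0.9), "saturated")
  # the saturation level itself is the t -> Inf limit
  expect_equal(zeta_eval(z, 1e6), 0.75, tolerance = 1e-12)
  zk <- zeta_transform("jukes_cantor", k = 4)
  expect_equal(zeta_eval(zk, 1e6), 3 / 4, tolerance = 1e-12)
})

test_that("the negative-log inverse reproduces the printed worked entries", {
  expect_equal(zeta_inverse_eval(neg_log_10, 0.503), 6.991653,
               tolerance = 1e-6)
  Tm <- zeta_invert(neg_log_10, eq3)
  expect_true(check_four_point(Tm, tol = 0.05)$holds)
  # forward of the inverse returns the original entries
  expect_lt(max(abs(zeta_apply(neg_log_10, Tm) - eq3)), 1e-12)
})

test_that("entrywise application keeps labels and a zero diagonal", {
  z <- zeta_transform("stretched_exp", a = 2, b = 1, c = 0.7)
  out <- zeta_apply(z, eq3)
  expect_identical(rownames(out), rownames(eq3))
  expect_identical(unname(diag(out)), rep(0, 4))
  expect_error(zeta_invert(zeta_transform("neg_log", s = 1, m = 0.5), eq3),
               "saturated")
})

test_that("concave amenable families pass the grid preserving check", {
  rep1 <- check_preserving(zeta_transform("stretched_exp",
                                          a = 3 / 4, b = 4 / 3, c = 1))
  expect_true(all(rep1$holds))
  rep2 <- check_preserving(zeta_transform("affine", alpha = 1, beta = 0))
  expect_true(all(rep2$holds))
})

test_that("a convex function fails subadditivity with a witness", {
  zsq <- zeta_transform("custom", fn = function(t) t^2)
  rep <- check_preserving(zsq, grid_max = 2, grid_n = 64)
  z2 <- rep[rep$property == "Z2", ]
  expect_false(z2$holds)
  expect_gt(z2$worst_violation, 0)
  wit <- z2$witness[[1]]
  expect_true(all(wit > 0))  # violation needs t, u > 0
})

test_that("custom families invert numerically to 1e-10", {
  z <- zeta_transform("custom", fn = function(t) t / (1 + t), saturation = 1)
  d <- c(0, 0.1, 0.5, 0.9)
  expect_lt(max(abs(zeta_eval(z, zeta_inverse_eval(z, d)) - d)), 1e-10)
})

test_that("affine maps preserve additivity; nonlinear maps break it", {
  for (seed in 1:5) {
    D <- rand_additive(8, 100 + seed)$D
    aff <- zeta_transform("affine", alpha = 1.7, beta = 0.01)
    expect_true(check_four_point(zeta_apply(aff, D), tol = 1e-9)$holds)
  }
  # a strictly concave distortion generically destroys additivity
  D <- rand_additive(8, 200, mean_len = 0.5)$D
  zc <- zeta_transform("stretched_exp", a = 3, b = 1, c = 1)
  expect_false(check_four_point(zeta_apply(zc, D), tol = 1e-6)$holds)
})

test_that("concave distortions of metrics are still metrics", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 7
    # random metric: shortest-path closure of a random symmetric matrix
    M <- matrix(runif(n * n, 0.2, 1), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    for (k in 1:n) M <- pmin(M, outer(M[, k], M[k, ], "+"))
    D <- distance_matrix(M)
    expect_true(all(check_metric(D)$holds))
    z <- zeta_transform("stretched_exp", a = 1.5, b = 1, c = runif(1, 0.5, 1))
    expect_true(all(check_metric(zeta_apply(z, D))$holds))
  }
})

test_that("monotone distortions preserve strong monotonicity", {
  D <- rand_additive(7, 77)$D
  for (z in list(zeta_transform("jukes_cantor", k = 4),
                 zeta_transform("stretched_exp", a = 5, b = 0.3, c = 0.7))) {
    expect_true(check_monotone_consistency(D, zeta_apply(z, D), "m1")$holds)
  }
})

test_that("the quartet flip phenomenon is reproducible from the fixture", {
  Tm <- zeta_invert(neg_log_10, eq3)  # additive up to rounding
  q_before <- quadruple(Tm, "u", "v", "x", "y")
  q_after <- quadruple(zeta_apply(neg_log_10, Tm), "u", "v", "x", "y")
  expect_identical(q_before$topology, "uv|xy")
  expect_identical(q_after$topology, "uy|vx")
})

test_that("feature combination follows the linear-plus-discrete form", {
  D <- rand_additive(6, 55)$D
  # single feature, unit weight: identity
  expect_equal(unclass(combine_metrics(list(D), 1, 0)), unclass(D),
               ignore_attr = TRUE)
  # two additive matrices from one tree stay additive under linear mixing
  D2 <- distance_matrix(3 * unclass(D), labels = rownames(D))
  comb <- combine_metrics(list(D, D2), c(1, 1), c(0, 0))
  expect_true(check_four_point(comb, tol = 1e-9)$holds)
  # pure discrete weights count positive features
  disc <- combine_metrics(list(D, D2), c(0, 0), c(1, 1))
  expect_true(all(offdiag_vals <- disc[upper.tri(disc)] == 2))
  expect_error(combine_metrics(list(D, D2), c(1, 0), c(0, 0)), "positive")
  expect_error(combine_metrics(list(D, eq3), c(1, 1), c(0, 0)), "label")
})

test_that("transform specs parse to working transforms", {
  z <- parse_transform_spec("stretched_exp a=0.75 b=1.0 c=1.0")
  expect_identical(z$family, "stretched_exp")
  expect_equal(z$params$a, 0.75)
  expect_equal(zeta_eval(z, 1), 0.75 * (1 - exp(-1)))
  expect_error(parse_transform_spec("stretched_exp a=eh"), "non-numeric")
  expect_error(parse_transform_spec(""), "empty")
})
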