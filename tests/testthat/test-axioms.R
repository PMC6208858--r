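test_that("metric axioms hold for the worked matrix and the discrete metric", {
  rep <- check_metric(eq3)
  expect_true(all(rep$holds))
  rep2 <- check_metric(distance_matrix(matrix(c(0, 1, 1, 0), 2),
                                       labels = c("a", "b")))
  expect_true(all(rep2$holds))
})

test_that("triangle violations are found with magnitude and witness", {
  M <- matrix(c(0, 5, 10,
                5, 0, 1,
                10, 1, 0), 3, 3, byrow = TRUE)
  D <- distance_matrix(M, labels = c("x", "y", "z"))
  rep <- check_metric(D)
  m3 <- rep[rep$axiom == "M3", ]
  expect_false(m3$holds)
  expect_equal(m3$worst_violation, 4)  # 10 - 5 - 1
  expect_setequal(m3$witnesses[[1]], c("x", "y", "z"))
})

test_that("zero off-diagonal entries violate M1 only", {
  M <- matrix(c(0, 0, 1,
                0, 0, 1,
                1, 1, 0), 3, 3)
  rep <- check_metric(distance_matrix(M, labels = c("a", "b", "c")))
  expect_false(rep$holds[rep$axiom == "M1"])
  expect_true(rep$holds[rep$axiom == "M3"])
})

test_that("four-point condition separates tree metrics from the worked matrix", {
  # any tree metric satisfies it tightly
  for (seed in 1:5) {
    D <- rand_additive(sample(4:10, 1), seed)$D
    expect_true(check_four_point(D, tol = 1e-9)$holds)
  }
  # the worked matrix fails at strict tolerance: largest - middle = 0.090
  rep <- check_four_point(eq3, tol = 0.01)
  expect_false(rep$holds)
  expect_equal(rep$worst_violation, 0.090, tolerance = 1e-9)
  # its back-transform is additive up to printed rounding
  Tm <- zeta_invert(neg_log_10, eq3)
  expect_true(check_four_point(Tm, tol = 0.05)$holds)
  expect_false(check_four_point(Tm, tol = 1e-6)$holds)
})

test_that("matrices with fewer than four taxa pass the four-point check", {
  D <- distance_matrix(matrix(c(0, 3, 3, 0), 2), labels = c("a", "b"))
  rep <- check_four_point(D)
  expect_true(rep$holds)
  expect_identical(rep$worst_violation, 0)
})

test_that("ultrametricity: clock trees pass, the worked matrix fails", {
  U <- balanced_ultrametric()
  expect_true(check_ultrametric(U)$holds)
  expect_false(check_ultrametric(eq3)$holds)
  two <- distance_matrix(matrix(c(0, 7, 7, 0), 2), labels = c("a", "b"))
  expect_true(check_ultrametric(two)$holds)
})

test_that("ultrametric implies additive on clock-like matrices", {
  U <- balanced_ultrametric(c(0.5, 1.7, 3.1))
  expect_true(check_ultrametric(U)$holds)
  expect_true(check_four_point(U, tol = 1e-9)$holds)
})

test_that("the quartet relation resolves by strict minimal pair-sum", {
  q <- quadruple(eq3, "u", "v", "x", "y")
  expect_identical(q$topology, "uy|vx")
  q2 <- quadruple(zeta_invert(neg_log_10, eq3), "u", "v", "x", "y")
  expect_identical(q2$topology, "uv|xy")
  # perfect tie -> unresolved
  E <- distance_matrix(matrix(1, 4, 4) - diag(4), labels = letters[1:4])
  expect_identical(quadruple(E, "a", "b", "c", "d")$topology, "unresolved")
  expect_error(quadruple(eq3, "u", "u", "x", "y"), "distinct")
  expect_error(quadruple(eq3, "u", "v", "x", "zz"), "unknown")
})

test_that("quartet calls are invariant under taxon permutation", {
  set.seed(5)
  D <- rand_additive(6, 21)$D
  lab <- rownames(D)
  for (i in 1:10) {
    perm <- sample(lab)
    Dp <- distance_matrix(unclass(D)[perm, perm], labels = perm)
    four <- sample(lab, 4)
    q1 <- quadruple(D, four[1], four[2], four[3], four[4])
    q2 <- quadruple(Dp, four[1], four[2], four[3], four[4])
    expect_identical(q1$topology, q2$topology)
  }
})

test_that("additive matrices agree with tree topology on every quartet", {
  fx <- rand_additive(7, 31)
  D <- fx$D
  lab <- rownames(D)
  quartets <- combn(lab, 4)
  for (i in seq_len(ncol(quartets))) {
    q <- quadruple(D, quartets[1, i], quartets[2, i],
                   quartets[3, i], quartets[4, i])
    if (q$topology == "unresolved") next
    sub <- distance_matrix(unclass(D)[quartets[, i], quartets[, i]])
    tr <- neighbor_joining(sub)
    nj_splits <- vapply(tree_splits(tr), `[[`, character(1), "key")
    expect_true(split_key(q$split[[1]], q$split[[2]]) %in% nj_splits)
  }
})

test_that("monotone consistency holds for increasing maps, fails on rank swaps", {
  D1 <- rand_additive(6, 41)$D
  D2 <- distance_matrix(2 * unclass(D1), labels = rownames(D1))
  expect_true(check_monotone_consistency(D1, D2, "m0")$holds)
  expect_true(check_monotone_consistency(D1, D2, "m1")$holds)
  z <- zeta_transform("stretched_exp", a = 3, b = 0.7, c = 0.9)
  expect_true(check_monotone_consistency(D1, zeta_apply(z, D1), "m1")$holds)

  # push one entry past its rank neighbour
  v <- sort(unclass(D1)[upper.tri(D1)])
  M <- unclass(D1)
  idx <- which(M == v[1], arr.ind = TRUE)[1, ]
  M[idx[1], idx[2]] <- M[idx[2], idx[1]] <- v[2] + (v[3] - v[2]) / 2
  Dswap <- distance_matrix(M, labels = rownames(D1))
  rep <- check_monotone_consistency(D1, Dswap, "m1")
  expect_false(rep$holds)
  expect_gt(rep$worst_violation, 0)
  expect_error(check_monotone_consistency(D1, eq3, "m1"), "label")
})
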