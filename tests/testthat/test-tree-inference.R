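test_that("path metrics: star tree and a hand-summed quartet", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a:1,b:1,c:1,d:1);", f)
  star <- read_newick(f)
  D <- tree_to_distances(star)
  expect_true(all(D[upper.tri(D)] == 2))

  writeLines("((u:6,v:1):1,x:2,y:7);", f)
  qt <- read_newick(f)
  Dq <- tree_to_distances(qt)
  expect_equal(unname(Dq["u", "v"]), 7)
  expect_equal(unname(Dq["u", "x"]), 9)
  expect_equal(unname(Dq["u", "y"]), 14)
  expect_equal(unname(Dq["v", "x"]), 4)
  expect_equal(unname(Dq["v", "y"]), 9)
  expect_equal(unname(Dq["x", "y"]), 9)
})

test_that("path metrics agree with the cophenetic oracle and are additive", {
  for (seed in 1:5) {
    fx <- rand_additive(sample(5:15, 1), 400 + seed)
    ours <- unclass(fx$D)
    oracle <- ape::cophenetic.phylo(fx$tree)[rownames(ours), colnames(ours)]
    expect_lt(max(abs(ours - oracle)), 1e-10)
    expect_true(check_four_point(fx$D, tol = 1e-9)$holds)
  }
})

test_that("neighbor joining recovers simulated trees exactly", {
  fx <- rand_additive(10, 50)
  tr <- neighbor_joining(fx$D)
  expect_identical(rf_distance(fx$tree, tr), 0L)
  Dr <- tree_to_distances(tr)[rownames(fx$D), colnames(fx$D)]
  expect_lt(max(abs(Dr - fx$D)), 1e-9)
})

test_that("three-taxon metrics yield the closed-form star", {
  M <- matrix(c(0, 5, 8,
                5, 0, 7,
                8, 7, 0), 3, 3)
  D <- distance_matrix(M, labels = c("a", "b", "c"))
  tr <- neighbor_joining(D)
  expect_identical(length(tr$tip.label), 3L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens["a"]), (5 + 8 - 7) / 2)
  expect_equal(unname(lens["b"]), (5 + 7 - 8) / 2)
  expect_equal(unname(lens["c"]), (8 + 7 - 5) / 2)
})

test_that("the back-transformed worked matrix yields the uv|xy quartet", {
  tr <- neighbor_joining(zeta_invert(neg_log_10, eq3))
  keys <- vapply(tree_splits(tr), `[[`, character(1), "key")
  expect_true(split_key(c("u", "v"), c("x", "y")) %in% keys)
  # while raw distances attract the long branches u and y
  tr_raw <- neighbor_joining(eq3)
  keys_raw <- vapply(tree_splits(tr_raw), `[[`, character(1), "key")
  expect_true(split_key(c("u", "y"), c("v", "x")) %in% keys_raw)
})

test_that("neighbor joining matches the reference implementation topology", {
  for (seed in 1:5) {
    set.seed(600 + seed)
    n <- sample(5:12, 1)
    M <- matrix(runif(n * n, 0.3, 1.5), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    for (k in 1:n) M <- pmin(M, outer(M[, k], M[k, ], "+"))
    D <- distance_matrix(M)
    ours <- neighbor_joining(D)
    ref <- ape::nj(stats::as.dist(unclass(D)))
    expect_identical(rf_distance(ours, ref), 0L)
  }
})

test_that("metric violations warn but do not stop the agglomeration", {
  M <- matrix(c(0, 5, 10,
                5, 0, 1,
                10, 1, 0), 3, 3)
  D <- distance_matrix(M, labels = c("a", "b", "c"))
  expect_warning(neighbor_joining(D), "triangle")
})

test_that("negative length estimates are clamped to nonnegative edges", {
  # a star-like metric drives internal NJ estimates slightly negative
  M <- matrix(2, 5, 5) - 2 * diag(5)
  M[1, 2] <- M[2, 1] <- 2.1
  D <- distance_matrix(M, labels = letters[1:5])
  tr <- suppressWarnings(neighbor_joining(D))
  expect_true(all(tr$edge.length >= 0))
})

test_that("the additive projection is idempotent and fixes additive inputs", {
  fx <- rand_additive(9, 71)
  for (method in c("nj", "splits")) {
    out <- tau(fx$D, method)
    expect_lt(max(abs(out - fx$D)), 1e-9)
  }
  # the worked matrix moves, and its projection is additive and stable
  for (method in c("nj", "splits")) {
    p <- tau(eq3, method)
    expect_gt(max(abs(p - eq3)), 0)
    expect_true(check_four_point(p, tol = 1e-9)$holds)
    expect_lt(max(abs(tau(p, method) - p)), 1e-9)
  }
  # 3-taxon metrics are always additive
  M <- matrix(c(0, 5, 8, 5, 0, 7, 8, 7, 0), 3, 3)
  D3 <- distance_matrix(M, labels = c("a", "b", "c"))
  expect_lt(max(abs(tau(D3, "nj") - D3)), 1e-12)
})

test_that("split distance counts the asymmetric topology difference", {
  fx <- rand_additive(8, 81)
  expect_identical(rf_distance(fx$tree, fx$tree), 0L)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:1,d:1);", f)
  t1 <- read_newick(f)
  writeLines("((a:1,c:1):1,b:1,d:1);", f)
  t2 <- read_newick(f)
  expect_identical(rf_distance(t1, t2), 2L)
  writeLines("((a:1,e:1):1,b:1,d:1);", f)
  t3 <- read_newick(f)
  expect_error(rf_distance(t1, t3), "leaf")
})

test_that("Newick IO round-trips topology and lengths", {
  for (seed in 1:10) {
    fx <- rand_additive(sample(4:20, 1), 500 + seed)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(fx$tree, f)
    back <- read_newick(f)
    expect_identical(rf_distance(fx$tree, back), 0L)
    D2 <- tree_to_distances(back)[rownames(fx$D), colnames(fx$D)]
    expect_lt(max(abs(D2 - fx$D)), 1e-10)
  }
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2:1,c:1,d:1);", f)
  expect_error(read_newick(f), "parse")
})
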