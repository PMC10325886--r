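test_that("matrix distance is the Euclidean norm of the difference", {
  A <- matrix(0, 2, 2); B <- matrix(1, 2, 2)
  expect_equal(matrix_distance(A, A), 0)
  expect_equal(matrix_distance(A, B), 2)
  set.seed(8)
  for (i in 1:10) {
    x <- matrix(rnorm(9), 3); y <- matrix(rnorm(9), 3); z <- matrix(rnorm(9), 3)
    # brute-force entrywise oracle
    expect_equal(matrix_distance(x, y), sqrt(sum((x - y)^2)), tolerance = 1e-12)
    # metric axioms
    expect_equal(matrix_distance(x, y), matrix_distance(y, x))
    expect_lte(matrix_distance(x, z),
               matrix_distance(x, y) + matrix_distance(y, z) + 1e-12)
  }
  expect_error(matrix_distance(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  A_na <- A; A_na[1, 1] <- NA
  expect_error(matrix_distance(A_na, B), "different positions")
  B_na <- B; B_na[1, 1] <- NA
  expect_equal(matrix_distance(A_na, B_na), sqrt(3))
})

test_that("Ward clustering is deterministic and separates planted groups", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- ward_clustering(d2)
  expect_equal(hc2$height, 3)
  d3 <- as.matrix(dist(c(a = 0, b = 1, c = 10)))
  hc3 <- ward_clustering(d3)
  expect_equal(sort(hc3$labels[-hc3$merge[1, ]]), c("a", "b"))
  # planted 6-point fixture, between/within ratio 10:1
  set.seed(10)
  pts <- c(rnorm(3, 0, 0.5), rnorm(3, 10, 0.5))
  names(pts) <- letters[1:6]
  hc6 <- ward_clustering(as.matrix(dist(pts)))
  top <- cutree(hc6, 2)
  expect_equal(unname(top), c(1, 1, 1, 2, 2, 2))
  expect_error(ward_clustering(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("SIMPROF keeps exchangeable tables in one cluster", {
  set.seed(21)
  X <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(letters[1:8], NULL))
  res <- simprof(X, alpha = 0.01, n_perm = 199, seed = 5)
  expect_equal(res$n_clusters, 1)
  # identical objects: no structure whatsoever
  X0 <- matrix(1, 5, 10, dimnames = list(letters[1:5], NULL))
  expect_equal(simprof(X0, n_perm = 99, seed = 1)$n_clusters, 1)
  # alpha = 0 can never split (add-one estimator keeps p > 0)
  Xs <- rbind(matrix(rnorm(5 * 20), 5, 20),
              matrix(rnorm(5 * 20, 10), 5, 20))
  rownames(Xs) <- letters[1:10]
  expect_equal(simprof(Xs, alpha = 0, n_perm = 99, seed = 2)$n_clusters, 1)
})

test_that("SIMPROF recovers two planted groups shifted by 10 sd", {
  set.seed(31)
  X <- rbind(matrix(rnorm(5 * 40), 5, 40),
             matrix(rnorm(5 * 40, mean = 10), 5, 40))
  rownames(X) <- paste0(rep(c("lo", "hi"), each = 5), 1:5)
  res <- simprof(X, alpha = 0.01, n_perm = 999, seed = 3)
  expect_equal(res$n_clusters, 2)
  expect_equal(length(unique(res$clusters[paste0("lo", 1:5)])), 1)
  expect_equal(length(unique(res$clusters[paste0("hi", 1:5)])), 1)
})

test_that("classification is invariant to input order and seed-reproducible", {
  mats <- c(
    lapply(1:3, function(i) archetype_matrices("uniform", n_w = 15, seed = i)),
    lapply(4:6, function(i) archetype_matrices("block", n_w = 15, seed = i)),
    lapply(7:10, function(i) archetype_matrices("noisy", n_w = 15, seed = i)))
  names(mats) <- c(paste0("u", 1:3), paste0("b", 1:3), paste0("n", 1:4))
  r1 <- classify_indicators(mats, n_perm = 199, seed = 17)
  r2 <- classify_indicators(mats[sample(10)], n_perm = 199, seed = 17)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$node_p, r2$node_p)
  r3 <- classify_indicators(mats, n_perm = 199, seed = 17)
  expect_identical(r1$clusters, r3$clusters)
})

test_that("degenerate classification inputs are handled", {
  m <- archetype_matrices("uniform", n_w = 10, seed = 1)
  same <- list(a = m, b = m, c = m, d = m)
  expect_equal(classify_indicators(same, n_perm = 99, seed = 1)$n_clusters, 1)
  expect_warning(
    two <- classify_indicators(list(a = m, b = m + 1), n_perm = 99, seed = 1),
    "untestable")
  expect_equal(two$n_clusters, 1)
})

test_that("cluster table pairs each indicator with its stopping p-value", {
  set.seed(31)
  X <- rbind(matrix(rnorm(5 * 40), 5, 40),
             matrix(rnorm(5 * 40, mean = 10), 5, 40))
  rownames(X) <- paste0(rep(c("lo", "hi"), each = 5), 1:5)
  res <- simprof(X, alpha = 0.01, n_perm = 199, seed = 3)
  tab <- cluster_table(res)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$cluster %in% seq_len(res$n_clusters)))
  expect_true(all(tab$node_p > res$alpha, na.rm = TRUE))  # stopped nodes
})
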