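# Histogram entropies, mutual information, weighted adjacency and
# threshold selection.

test_that("entropy matches closed forms and stays within bounds", {
  expect_equal(channel_entropy(rep(c(0, 1), 50), B = 2), 1)
  expect_equal(channel_entropy(rep(5, 100), B = 8), 0)
  set.seed(1)
  for (s in 1:3) {
    x <- runif(1000)
    h <- channel_entropy(x, B = 16)
    expect_gte(h, 3.9)
    expect_lte(h, 4.0)
  }
  expect_lte(channel_entropy(rnorm(500), B = 8), 3)
  expect_error(channel_entropy(numeric(0)), "length")
})

test_that("joint entropy obeys dependence bounds", {
  set.seed(2)
  x <- rnorm(600)
  expect_equal(joint_entropy(x, x, 16), channel_entropy(x, 16))
  # independent fair coins approach 2 bits jointly
  a <- rep(c(0, 1), 500)
  b <- rep(c(0, 0, 1, 1), 250)
  expect_equal(joint_entropy(a, b, 2), 2, tolerance = 1e-9)
  for (s in 1:5) {
    u <- rnorm(400)
    v <- rnorm(400) + 0.5 * u
    hu <- channel_entropy(u, 8)
    hv <- channel_entropy(v, 8)
    huv <- joint_entropy(u, v, 8)
    expect_gte(huv + 1e-9, max(hu, hv))
    expect_lte(huv, hu + hv + 1e-9)
  }
  expect_error(joint_entropy(1:10, 1:9), "equal length")
})

test_that("mutual information is symmetric, non-negative, and self = H", {
  set.seed(3)
  x <- rnorm(500)
  y <- rnorm(500)
  expect_equal(mutual_information(x, x, 16), channel_entropy(x, 16))
  expect_equal(mutual_information(x, y, 16), mutual_information(y, x, 16))
  expect_gte(mutual_information(x, y, 16), 0)
  expect_equal(mutual_information(x, x, 16, normalize = TRUE), 1)
})

test_that("MI matches the joint-bin enumeration oracle exactly", {
  # integer-valued toy series: bins coincide with values at matching B
  s <- c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1, 2, 3)
  q <- c(1, 2, 1, 2, 3, 3, 3, 1, 2, 2, 1, 3)
  for (B in c(3, 4)) {
    expect_equal(mutual_information(s, q, B), bf_mutual_information(s, q, B))
  }
  set.seed(4)
  for (i in 1:5) {
    a <- sample(0:7, 200, replace = TRUE)
    b <- (a + sample(0:3, 200, replace = TRUE)) %% 8
    expect_equal(mutual_information(a, b, 8), bf_mutual_information(a, b, 8))
  }
})

test_that("the weighted MI matrix has the contracted structure", {
  set.seed(5)
  seg <- matrix(rnorm(300 * 3), ncol = 3)
  colnames(seg) <- paste0("V", 1:3)
  W <- build_mi_matrix(list(seg), B = 8)
  expect_equal(dim(W$w), c(3, 3))
  expect_equal(W$w, t(W$w))
  expect_equal(diag(W$w), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(W$w >= 0 & W$w <= 1))
  # identical channels -> 1 under geometric normalization
  seg2 <- cbind(V1 = seg[, 1], V2 = seg[, 1])
  expect_equal(build_mi_matrix(list(seg2))$w[1, 2], 1)
  # channel-set mismatch
  segb <- seg
  colnames(segb) <- paste0("W", 1:3)
  expect_error(build_mi_matrix(list(seg, segb)), "channel set")
})

test_that("planted two-group structure is recovered in the MI matrix", {
  cfg <- sim_config(n_channels = 6, group_assignment = rep(1:2, each = 3),
                    group_strength = 0.8, global_strength = 0,
                    n_repetitions = 2, seed = 11)
  rec <- generate_recording(cfg)$recording
  W <- build_mi_matrix(segment_phase(rec, "lift"))$w
  within <- mean(c(W[1, 2], W[1, 3], W[2, 3], W[4, 5], W[4, 6], W[5, 6]))
  between <- mean(W[1:3, 4:6])
  expect_gt(within, between)
})

test_that("min-max normalization spans [0, 1]", {
  set.seed(6)
  seg <- matrix(rnorm(300 * 4), ncol = 4)
  W <- build_mi_matrix(list(seg), B = 8, normalization = "minmax")$w
  off <- W[upper.tri(W)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
})

test_that("binarize applies the strict rule w > TH", {
  w <- matrix(c(0, 0.4, 0.6,
                0.4, 0, 0.6,
                0.6, 0.6, 0), 3, 3)
  net <- binarize(w, 0.55)
  expect_equal(sum(net$adj) / 2, 2) # only the 0.6 entries
  expect_equal(sum(binarize(w, 0)$adj) / 2, 3)
  expect_equal(sum(binarize(w, 1)$adj), 0)
  expect_equal(sum(binarize(w, 0.6)$adj), 0) # strict inequality
  expect_error(binarize(w, 1.2), "\\[0, 1\\]")
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(7)
  w <- matrix(runif(100), 10, 10)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  counts <- vapply(seq(0, 1, 0.05), function(th) sum(binarize(w, th)$adj),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold selection picks the largest feasible grid value", {
  w <- matrix(0.7, 5, 5)
  diag(w) <- 0
  sel <- select_threshold(w)
  expect_equal(sel$th, 0.69)
  expect_equal(sel$degree_bound, 2 * log(5))
  # brute-force scan oracle on a random weighted matrix
  set.seed(8)
  w2 <- matrix(runif(64, 0.2, 0.9), 8, 8)
  w2 <- (w2 + t(w2)) / 2
  diag(w2) <- 0
  grid <- seq(0, 1, 0.01)
  feas <- vapply(grid, function(th) {
    adj <- (w2 > th) * 1
    diag(adj) <- 0
    fw_connected(adj) && mean(rowSums(adj)) > 2 * log(8)
  }, logical(1))
  expect_equal(select_threshold(w2)$th, max(grid[feas]))
})

test_that("infeasible weight matrices raise an error carrying the trace", {
  w <- matrix(0, 6, 6) # empty at every threshold
  err <- tryCatch(select_threshold(w), error = function(e) e)
  expect_s3_class(err, "musclenet_threshold_error")
  expect_true(is.data.frame(err$trace))
  expect_equal(nrow(err$trace), 101)
})

test_that("networks export to GraphML and edge lists", {
  net <- binary_net(path_graph(3), labels = c("a", "b", "c"))
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".csv")
  write_network(net, f1, "graphml")
  write_network(net, f2, "edgelist")
  expect_true(file.exists(f1))
  el <- read.csv(f2)
  expect_equal(nrow(el), 2)
  g <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
  unlink(c(f1, f2))
})
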