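# Directed information-flow networks and sensor selection.

test_that("a clean driver-response-independent triple is recovered", {
  drv <- generate_coupled_logistic(coupling_spec(beta_yx = 0.32,
                                                 length = 1100,
                                                 burn_in = 100, seed = 21))
  ind <- generate_coupled_logistic(coupling_spec(length = 1100,
                                                 burn_in = 100, seed = 22))
  series <- list(cond1 = list(a = drv$x, b = drv$y, c = ind$x))
  dn <- build_directed_network(series, E = 3, tau = 1,
                               lib_sizes = c(200, 500, 900), repeats = 3,
                               seed = 5)
  expect_s3_class(dn, "directed_net")
  expect_lte(nrow(dn$edges), 3) # at most one call per unordered pair
  expect_true(any(dn$edges$from == "a" & dn$edges$to == "b"))
  expect_false(any(dn$edges$from == "b" & dn$edges$to == "a"))
})

test_that("the overall network is the union with bidirectional flags", {
  fwd <- generate_coupled_logistic(coupling_spec(beta_yx = 0.32,
                                                 length = 1100,
                                                 burn_in = 100, seed = 31))
  rev <- generate_coupled_logistic(coupling_spec(r_x = 3.5, r_y = 3.8,
                                                 beta_xy = 0.32,
                                                 length = 1100,
                                                 burn_in = 100, seed = 32))
  series <- list(c1 = list(a = fwd$x, b = fwd$y),
                 c2 = list(a = rev$x, b = rev$y))
  dn <- build_directed_network(series, E = 3, tau = 1,
                               lib_sizes = c(200, 900), repeats = 3,
                               seed = 6)
  expect_equal(nrow(dn$edges), 2)
  expect_equal(nrow(dn$overall), 2)
  expect_true(all(dn$overall$bidirectional))
  g <- as_igraph(dn)
  expect_equal(igraph::gsize(g), 2)
})

test_that("node subsets and unknown nodes are handled", {
  set.seed(40)
  series <- list(c1 = matrix(rnorm(900), ncol = 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  dn <- build_directed_network(series, nodes = c("a", "b"), E = 2, tau = 1,
                               lib_sizes = c(100, 290), repeats = 2, seed = 1)
  expect_equal(dn$labels, c("a", "b"))
  expect_error(build_directed_network(series, nodes = "zz"), "unknown")
})

test_that("ranking follows depth, out-minus-in, then label order", {
  labels <- c("a", "b", "c")
  am <- area_map(labels, c(1, 1, 2), rep("front", 3))
  chain <- make_directed_net(labels, data.frame(
    from = c("a", "b"), to = c("b", "c"), stringsAsFactors = FALSE))
  sel <- rank_and_select_sensors(chain, am, m = 2)
  expect_equal(sel$selected, c("a", "b"))
  rk <- sel$ranking
  expect_equal(rk$label, c("a", "b", "c"))
  expect_equal(rk$depth, c(0, 1, 2))
  # a node with no edges ranks with the sources but after positive out-flow
  labels4 <- c("a", "b", "c", "d")
  am4 <- area_map(labels4, c(1, 1, 2, 2), c("front", "front", "back", "back"))
  chain4 <- make_directed_net(labels4, data.frame(
    from = c("a", "b"), to = c("b", "c"), stringsAsFactors = FALSE))
  rk4 <- rank_and_select_sensors(chain4, am4, m = 2)$ranking
  expect_equal(rk4$label, c("a", "d", "b", "c"))
  # hub: star of out-edges
  hub <- make_directed_net(labels4, data.frame(
    from = c("b", "b", "b"), to = c("a", "c", "d"), stringsAsFactors = FALSE))
  expect_equal(rank_and_select_sensors(hub, am4, m = 1)$selected, "b")
})

test_that("ties in the rank key are reported as equal rank", {
  labels <- c("a", "b", "c")
  am <- area_map(labels, c(1, 1, 1), rep("front", 3))
  dn <- make_directed_net(labels, data.frame(
    from = c("a", "b"), to = c("c", "c"), stringsAsFactors = FALSE))
  rk <- rank_and_select_sensors(dn, am, m = 2)$ranking
  expect_equal(rk$rank[rk$label %in% c("a", "b")], c(1, 1))
  expect_gt(rk$rank[rk$label == "c"], 1)
})

test_that("surface coverage swaps in the best node of a missing surface", {
  labels <- c("f1", "f2", "f3", "s1", "b1")
  am <- area_map(labels, c(1, 1, 1, 2, 3),
                 c("front", "front", "front", "side", "back"))
  # two-source DAG: front nodes dominate the ranking; naive top-3 misses
  # the side and back surfaces
  dn <- make_directed_net(labels, data.frame(
    from = c("f1", "f1", "f2", "f3", "b1"),
    to = c("f2", "f3", "s1", "s1", "s1"), stringsAsFactors = FALSE))
  sel <- rank_and_select_sensors(dn, am, m = 3)
  expect_true(all(c("front", "side", "back") %in%
                    am$surface[match(sel$selected, am$channel)]))
  expect_equal(length(sel$selected), 3)
  # the selection keeps the best-ranked representative of each surface
  expect_true("f1" %in% sel$selected)
})

test_that("cycles are ranked through their condensation", {
  labels <- c("a", "b", "c")
  am <- area_map(labels, c(1, 1, 1), rep("front", 3))
  dn <- make_directed_net(labels, data.frame(
    from = c("a", "b", "b"), to = c("b", "a", "c"), stringsAsFactors = FALSE))
  rk <- rank_and_select_sensors(dn, am, m = 1)$ranking
  # a and b form one strongly connected component at depth 0; c hangs below
  expect_equal(rk$depth[rk$label %in% c("a", "b")], c(0, 0))
  expect_equal(rk$depth[rk$label == "c"], 1)
})

test_that("an empty directed network still yields a ranked selection", {
  labels <- paste0("V", 1:4)
  am <- area_map(labels, c(1, 1, 2, 2), c("front", "front", "side", "side"))
  dn <- make_directed_net(labels, data.frame(from = character(),
                                             to = character(),
                                             stringsAsFactors = FALSE))
  sel <- rank_and_select_sensors(dn, am, m = 2)
  expect_length(sel$selected, 2)
  expect_setequal(unique(am$surface[match(sel$selected, am$channel)]),
                  c("front", "side"))
})
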