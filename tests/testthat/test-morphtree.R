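test_that("SWC parsing builds cylinders with Euclidean lengths", {
  tree <- read_swc(swc3())
  expect_equal(nrow(tree$nodes), 3L)
  expect_equal(tree$nodes$length, c(0, 10, 10))
  expect_equal(tree$root, 1L)
  expect_equal(tree$nodes$radius, c(5, 1, 1))
})

test_that("SWC validation rejects malformed files", {
  expect_error(read_swc(write_swc_text(c("1 1 0 0 0 5 -1",
                                         "2 3 10 0 0 1 7"))),
               "parent id does not exist")
  expect_error(read_swc(write_swc_text(c("1 1 0 0 0 5 -1",
                                         "1 3 10 0 0 1 1"))),
               "duplicate")
  expect_error(read_swc(write_swc_text(c("1 1 0 0 0 5 -1",
                                         "2 3 10 0 0 0 1"))),
               "radius")
})

test_that("multi-point somas collapse and zero-length segments merge", {
  f <- write_swc_text(c("1 1 0 0 0 5 -1",
                        "2 1 0 5 0 5 1",
                        "3 1 0 -5 0 5 1",
                        "4 3 10 0 0 1 1"))
  expect_warning(tree <- read_swc(f), "soma")
  expect_equal(nrow(tree$nodes), 2L)
  expect_equal(tree$nodes$radius[1L], 5)  # 3-point convention: same sphere
  f2 <- write_swc_text(c("1 1 0 0 0 5 -1",
                         "2 3 10 0 0 1 1",
                         "3 3 10 0 0 1 2",
                         "4 3 20 0 0 1 3"))
  expect_warning(tree2 <- read_swc(f2), "zero-length")
  expect_equal(nrow(tree2$nodes), 3L)
  expect_equal(unname(soma_distance(tree2, c(4, 1))), 20)
})

test_that("SWC round-trip reproduces topology, radii and coordinates", {
  for (tree in list(read_swc(swc3()), make_rall_tree(),
                    make_ball_and_stick())) {
    f <- tempfile(fileext = ".swc")
    write_swc(tree, f)
    tree2 <- read_swc(f)
    expect_equal(tree2$nodes[c("index", "parent", "type", "radius")],
                 tree$nodes[c("index", "parent", "type", "radius")])
    expect_equal(tree2$nodes$length, tree$nodes$length, tolerance = 1e-6)
    expect_equal(tree2$nodes[c("x", "y", "z")], tree$nodes[c("x", "y", "z")],
                 tolerance = 1e-6)
  }
  bad <- read_swc(swc3())
  bad$nodes$parent[1L] <- 3
  expect_error(write_swc(bad, tempfile()), "root")
})

test_that("generator contracts: node counts and Rall taper", {
  expect_equal(nrow(make_ball_and_stick(n_points = 21)$nodes), 22L)
  rt <- make_rall_tree(depth = 2, d_root = 2)
  kids <- rt$nodes$radius[rt$nodes$parent %in%
                            rt$nodes$index[rt$nodes$length > 0 &
                                           !is.na(rt$nodes$parent)]]
  expect_equal(2 * rt$nodes$radius[3L], 2 / 2^(2 / 3), tolerance = 1e-12)
  # 3/2 power rule at every bifurcation
  for (id in rt$nodes$index) {
    ch <- rt$children[[dendrocable:::.node_row(rt, id)]]
    if (length(ch) == 2L && id != rt$root) {
      dp <- 2 * rt$nodes$radius[dendrocable:::.node_row(rt, id)]
      dc <- 2 * rt$nodes$radius[dendrocable:::.node_row(rt, ch)]
      expect_equal(dp^1.5, sum(dc^1.5), tolerance = 1e-12)
    }
  }
})

test_that("path lengths follow the unique tree path", {
  tree <- read_swc(swc3())
  expect_equal(path_length(tree, c(3, 0.5), c(1, 0)), 15)
  expect_equal(path_length(tree, c(2, 0.3), c(2, 0.3)), 0)
  ty <- make_y_tree(stem = 100, branch = 50)
  expect_equal(path_length(ty, c(3, 1), c(4, 1)), 100)
  expect_equal(path_length(ty, c(3, 1), c(1, 0)), 150)
  # symmetry on random location pairs of the Rall tree
  rt <- make_rall_tree()
  set.seed(7)
  ids <- rt$nodes$index[-1L]
  for (k in 1:12) {
    a <- c(sample(ids, 1), runif(1))
    b <- c(sample(ids, 1), runif(1))
    expect_equal(path_length(rt, a, b), path_length(rt, b, a))
  }
})

test_that("location canonicalization identifies junction points", {
  tree <- read_swc(swc3())
  a <- as_locations(tree, c(3, 0))
  expect_equal(a$node, 2L)
  expect_equal(a$x, 1)
  expect_equal(as_locations(tree, c(2, 0))$node, 1L)   # root
  expect_error(as_locations(tree, c(2, 1.2)), "outside")
  expect_error(as_locations(tree, c(9, 0.5)), "invalid node")
})

test_that("uniform location distribution spaces by arc length", {
  cb <- make_cable(L = 100, R = 1, n_points = 2, passive = FALSE)
  u <- distribute_locations_uniform(cb, 50)
  expect_equal(unname(soma_distance(cb, u)), c(50, 100))
  expect_equal(nrow(distribute_locations_uniform(cb, 1000)), 0L)
  ty <- make_y_tree(stem = 100, branch = 50)
  uy <- distribute_locations_uniform(ty, 50)
  expect_equal(nrow(uy), 4L)   # stem midpoint, junction, two tips
  expect_equal(sort(unname(soma_distance(ty, uy))), c(50, 100, 150, 150))
  # junction point is in the parent's x = 1 representation
  expect_true(any(uy$node == 2 & uy$x == 1))
  expect_error(distribute_locations_uniform(ty, -1), "spacing")
})

test_that("random locations are area-weighted and reproducible", {
  expect_equal(nrow(distribute_locations_random(make_y_tree(), 0)), 0L)
  ty <- make_y_tree(stem = 100, branch = 100, R_branch = 1)
  ty$nodes$radius[4L] <- 2   # second branch has twice the area
  r1 <- distribute_locations_random(ty, 200, seed = 42)
  r2 <- distribute_locations_random(ty, 200, seed = 42)
  expect_identical(r1, r2)
  n <- 10000
  r <- distribute_locations_random(ty, n, seed = 1,
                                   node_filter = function(nd)
                                     nd$index %in% c(3, 4))
  n2 <- sum(r$node == 4)
  p <- 2 / 3
  expect_lt(abs(n2 - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("minimal spanning subtree covers the paths between locations", {
  ty <- make_y_tree()
  m1 <- minimal_spanning_subtree(ty, c(3, 0.5))
  expect_equal(m1$node, c(1, 2, 3))
  expect_equal(m1$x1[m1$node == 3], 0.5)
  m2 <- minimal_spanning_subtree(ty, data.frame(node = c(3, 4), x = 1))
  expect_equal(m2$node, 1:4)
  expect_true(all(m2$x1 == 1))
  expect_error(minimal_spanning_subtree(ty, data.frame(node = integer(0),
                                                       x = numeric(0))),
               "location")
})

test_that("computational tree merges runs and preserves geometry", {
  bs <- make_ball_and_stick()
  expect_error(build_computational_tree(make_cable(passive = FALSE)),
               "has not been set")
  bs <- build_computational_tree(bs)
  expect_equal(nrow(bs$comp$tree$nodes), 2L)  # soma + one merged cylinder
  expect_equal(sum(bs$comp$tree$nodes$length), sum(bs$nodes$length))
  expect_equal(membrane_area(bs$comp$tree), membrane_area(bs))
  # radius step splits the run
  cb <- make_cable(n_points = 10)
  cb$nodes$radius[7:11] <- 2
  cb <- set_physiology(cb, "c_m", 1)
  cb <- build_computational_tree(cb)
  expect_equal(nrow(cb$comp$tree$nodes), 3L)
  # Y-tree: 3 cylinders + soma
  ty <- build_computational_tree(make_y_tree())
  expect_equal(nrow(ty$comp$tree$nodes), 4L)
  # round-trip of locations through the coordinate maps is the identity
  locs <- data.frame(node = c(2, 11, 22), x = c(0.25, 0.5, 1))
  back <- bs$comp$comp2orig(bs$comp$orig2comp(locs))
  expect_equal(back$node, locs$node)
  expect_equal(back$x, locs$x, tolerance = 1e-9)
  # any physiology mutation discards the computational tree
  bs2 <- set_physiology(bs, "g_leak", 4e-5)
  expect_null(bs2$comp)
})

test_that("uniform distribution is invariant to the computational tree", {
  bs <- make_ball_and_stick()
  u1 <- distribute_locations_uniform(bs, 97)
  u2 <- distribute_locations_uniform(build_computational_tree(bs), 97)
  expect_identical(u1, u2)
})
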