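# Memory-effect imaging: cross-correlation displacements, graph building,
# least-squares stitching, rendering, and the MDS alternative.

test_that("autocorrelation peaks at zero shift with maximal score", {
  set.seed(3)
  p <- Mod(speckle_field(64, 64, 2))^2
  cc <- cross_correlate(p, p)
  expect_identical(cc$u, c(0L, 0L))
  expect_equal(cc$peak, 1, tolerance = 1e-9)
  expect_gt(cc$score, 20)
  expect_error(cross_correlate(matrix(1, 8, 8), matrix(1, 8, 8)), "flat")
  expect_error(cross_correlate(p, p[1:32, ]), "shape")
})

test_that("planted within-ME shifts are recovered pixel-exactly, far pairs rejected", {
  sc <- simulation_config(3, 16, grid = c(64, 64), n_patterns = 4,
                          me_range = 15, seed = 9)
  em <- emitter_map(rbind(c(20, 20), c(28, 25), c(13, 33)))
  W <- make_intensity_tm(sc, em)
  g <- build_displacement_graph(W)
  expect_equal(nrow(g$edges), 3)               # all three pairs within ME
  e12 <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_identical(c(e12$du_row, e12$du_col), c(8L, 5L))
  e13 <- g$edges[g$edges$i == 1 & g$edges$j == 3, ]
  expect_identical(c(e13$du_row, e13$du_col), c(-7L, 13L))
  # far pair: no edge
  sc2 <- simulation_config(2, 16, grid = c(64, 64), n_patterns = 4,
                           me_range = 4, seed = 10)
  W2 <- make_intensity_tm(sc2, emitter_map(rbind(c(10, 10), c(54, 54))))
  g2 <- build_displacement_graph(W2)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(length(unique(g2$membership)), 2)
  expect_error(build_displacement_graph(W$matrix[, 1, drop = FALSE],
                                        grid = c(64, 64)), "at least 2")
})

test_that("displacements are antisymmetric and triangle-consistent", {
  sc <- simulation_config(4, 16, grid = c(64, 64), n_patterns = 4,
                          me_range = 15, seed = 13)
  em <- emitter_map(rbind(c(25, 20), c(31, 28), c(20, 31), c(36, 18)))
  W <- make_intensity_tm(sc, em)
  mats <- lapply(1:4, function(k) matrix(W$matrix[, k], 64, 64))
  for (i in 1:3) for (j in (i + 1):4) {
    fw <- cross_correlate(mats[[i]], mats[[j]])
    bw <- cross_correlate(mats[[j]], mats[[i]])
    expect_identical(fw$u, -bw$u)              # u_ij = -u_ji
  }
  g <- build_displacement_graph(W)
  e <- g$edges
  u <- function(a, b) {
    k <- which(e$i == a & e$j == b)
    if (length(k)) return(c(e$du_row[k], e$du_col[k]))
    k <- which(e$i == b & e$j == a)
    -c(e$du_row[k], e$du_col[k])
  }
  for (tri in combn(4, 3, simplify = FALSE)) {
    cyc <- u(tri[1], tri[2]) + u(tri[2], tri[3]) + u(tri[3], tri[1])
    if (length(cyc) == 2) expect_lte(sqrt(sum(cyc^2)), 2)
  }
})

test_that("stitching solves edge constraints exactly and respects components", {
  # two nodes, one edge
  g2 <- structure(list(edges = data.frame(i = 1, j = 2, du_row = 3,
                                          du_col = -4, score = 10, peak = 0.9),
                       n_nodes = 2L, membership = c(1L, 1L)),
                  class = "displacement_graph")
  om2 <- stitch_positions(g2)
  expect_equal(unlist(om2$positions[2, c("row", "col")]), c(row = 3, col = -4))
  # consistent triangle reproduced exactly
  g3 <- structure(list(edges = data.frame(
    i = c(1, 2, 1), j = c(2, 3, 3),
    du_row = c(5, 2, 7), du_col = c(1, 6, 7),
    score = rep(10, 3), peak = rep(0.9, 3)),
    n_nodes = 3L, membership = rep(1L, 3)), class = "displacement_graph")
  om3 <- stitch_positions(g3)
  expect_equal(om3$positions$row, c(0, 5, 7), tolerance = 1e-10)
  expect_equal(om3$positions$col, c(0, 1, 7), tolerance = 1e-10)
  # an inconsistent low-weight edge is rejected, not averaged in
  g4 <- g3
  g4$edges <- rbind(g3$edges, data.frame(i = 2, j = 3, du_row = 20,
                                         du_col = 20, score = 6, peak = 0.5))
  om4 <- stitch_positions(g4)
  expect_equal(om4$n_rejected, 1L)
  expect_equal(om4$positions$row, c(0, 5, 7), tolerance = 1e-10)
  expect_error(stitch_positions(structure(list(edges = g3$edges[0, ],
    n_nodes = 2L, membership = 1:2), class = "displacement_graph")),
    "no edges")
})

test_that("a chain object spanning 3x the ME range is stitched to within one grain", {
  sc <- simulation_config(20, 16, grid = c(96, 96), n_patterns = 4,
                          me_range = 10, speckle_grain = 2, seed = 17)
  em <- chain_emitters(20, spacing = 9, grid = c(96, 96), seed = 18)
  span <- max(dist(cbind(em$row, em$col)))
  expect_gte(span, 3 * sc$me_range)
  W <- make_intensity_tm(sc, em)
  g <- build_displacement_graph(W)
  expect_equal(length(unique(g$membership)), 1)   # overlapping patches chain up
  om <- stitch_positions(g)
  errs <- align_positions(om, cbind(em$row, em$col))
  expect_true(all(errs$err <= sc$speckle_grain))
})

test_that("breaking the chain overlap splits components and reports unlocated nodes", {
  sc <- simulation_config(6, 16, grid = c(96, 96), n_patterns = 4,
                          me_range = 6, speckle_grain = 2, seed = 19)
  pos <- rbind(c(20, 20), c(20, 26), c(26, 23),      # cluster A
               c(70, 70), c(70, 76),                 # cluster B, far away
               c(45, 90))                            # isolated
  W <- make_intensity_tm(sc, emitter_map(pos))
  g <- build_displacement_graph(W)
  expect_gte(length(unique(g$membership)), 3)
  om <- stitch_positions(g)
  expect_false(om$positions$located[6])             # isolated: unlocated
  expect_true(all(om$positions$located[1:5]))
  errs <- align_positions(om, pos)
  expect_true(all(errs$err[1:5] <= 2))
})

test_that("assemble_image renders located spots that match the emitter map", {
  sc <- simulation_config(10, 16, grid = c(80, 80), n_patterns = 4,
                          me_range = 10, seed = 23)
  em <- chain_emitters(10, spacing = 8, grid = c(80, 80), seed = 24)
  W <- make_intensity_tm(sc, em)
  om <- stitch_positions(build_displacement_graph(W))
  img <- assemble_image(om, grid = c(80, 80), spot_sigma = 1.5)
  truth <- assemble_image(structure(list(positions = data.frame(
    node = 1:10, component = 1L, row = em$row, col = em$col,
    located = TRUE)), class = "object_map"),
    grid = c(80, 80), spot_sigma = 1.5)
  expect_gt(cor(as.vector(img), as.vector(truth)), 0.9)
  # single located node: one spot at the grid centre
  single <- structure(list(positions = data.frame(node = 1, component = 1L,
    row = 5, col = 9, located = TRUE)), class = "object_map")
  s <- assemble_image(single, grid = c(21, 21), spot_sigma = 1)
  expect_equal(as.vector(arrayInd(which.max(s), dim(s))), c(11, 11))
})

test_that("classical MDS is exact on Euclidean distances and planar Gram rank is 2", {
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  Dm <- as.matrix(dist(tri))
  pos <- mds_localize(Dm)
  pr <- procrustes_align(pos, tri)
  expect_lt(pr$rmse, 1e-8)
  # double-centered Gram matrix of planar points has rank 2
  set.seed(31)
  pts <- cbind(runif(15, 0, 50), runif(15, 0, 50))
  D2 <- as.matrix(dist(pts))^2
  J <- diag(15) - 1 / 15
  G <- -0.5 * J %*% D2 %*% J
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) > max(abs(ev)) * 1e-9), 2)
  expect_error(mds_localize(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(mds_localize(-Dm), "non-negative")
})

test_that("shortest-path completion treats zero-length displacements as edges", {
  # duplicates sit at zero distance; their edge must still carry connectivity
  Dm <- matrix(NA_real_, 4, 4); diag(Dm) <- 0
  Dm[1, 2] <- Dm[2, 1] <- 0          # duplicate pair
  Dm[2, 3] <- Dm[3, 2] <- 3
  Dm[1, 3] <- Dm[3, 1] <- 3
  Dm[3, 4] <- Dm[4, 3] <- 4
  pos <- mds_localize(Dm)
  expect_identical(dim(pos), c(4L, 2L))
  expect_lt(sqrt(sum((pos[1, ] - pos[2, ])^2)), 1e-6)
  expect_equal(sqrt(sum((pos[3, ] - pos[4, ])^2)), 4, tolerance = 0.5)
})

test_that("MDS degrades gracefully under noise; robust stitching rejects outliers", {
  set.seed(37)
  truth <- cbind(runif(15, 0, 40), runif(15, 0, 40))
  sigma_n <- 0.5
  res <- replicate(8, {
    edges <- NULL; Dn <- matrix(0, 15, 15)
    for (i in 1:14) for (j in (i + 1):15) {
      du <- truth[j, ] - truth[i, ] + rnorm(2, sd = sigma_n)
      if (runif(1) < 0.1) du <- runif(2, -40, 40)   # wrong-peak outlier
      Dn[i, j] <- Dn[j, i] <- sqrt(sum(du^2))
      edges <- rbind(edges, data.frame(i = i, j = j, du_row = du[1],
                                       du_col = du[2], score = 10, peak = 0.9))
    }
    g <- structure(list(edges = edges, n_nodes = 15L,
                        membership = rep(1L, 15)),
                   class = "displacement_graph")
    naive <- stitch_positions(g, resid_tol = Inf)
    rob <- stitch_positions(g, resid_tol = 2)
    c(mds = procrustes_align(mds_localize(Dn), truth)$rmse,
      naive = procrustes_align(cbind(naive$positions$row,
                                     naive$positions$col), truth)$rmse,
      robust = procrustes_align(cbind(rob$positions$row,
                                      rob$positions$col), truth)$rmse)
  })
  m <- rowMeans(res)
  expect_lt(m["robust"], m["naive"])     # outlier rejection pays off
  expect_lt(m["robust"], 2 * sigma_n)
  expect_lt(m["mds"], 12)                # MDS stays bounded, not exact
})

test_that("graph distances feed MDS after shortest-path completion", {
  # compact cluster: most pairs measured directly, few completed
  sc <- simulation_config(8, 16, grid = c(72, 72), n_patterns = 4,
                          me_range = 10, seed = 41)
  set.seed(42)
  pos <- cbind(sample(20:50, 8), sample(20:50, 8))
  W <- make_intensity_tm(sc, emitter_map(pos))
  g <- build_displacement_graph(W)
  # MDS embeds one connected component at a time
  comp <- which(g$membership == as.integer(names(which.max(
    table(g$membership)))))
  Dm <- graph_distance_matrix(g)[comp, comp]
  expect_true(anyNA(Dm))                  # some pairs need completion
  pos_est <- mds_localize(Dm)
  pr <- procrustes_align(pos_est, pos[comp, ])
  # shortest-path completion stretches the few missing long distances
  expect_lt(pr$rmse, 3 * sc$speckle_grain)
  # disconnected input cannot be completed
  expect_error(mds_localize(graph_distance_matrix(g)), "disconnected")
})
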