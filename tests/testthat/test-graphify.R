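test_that("a straight cylinder thins to a single unbranched path", {
  ph <- generate_phantom(straight_tube_spec(radius = 3, n = 50))
  sk <- skeletonize(ph$vessel_masks[[1]])
  adj <- microvasc:::skeleton_adjacency(sk)
  expect_true(all(adj$degree <= 2))
  expect_equal(sum(adj$degree == 1), 2L)
  # path length close to the rasterized tube length (~46/0.99 voxels)
  expect_lt(abs(nrow(sk$voxels) - 46) , 6)
  # one voxel thick: no voxel with a full 3x3x3 neighbourhood
  expect_true(all(adj$degree < 26))
  expect_error(skeletonize(binary_mask(array(FALSE, c(5, 5, 5)), iso)), "empty")
})

test_that("a sphere collapses to a near-point skeleton", {
  m <- sphere_mask(c(10, 10, 10) * 0.99, 6, c(21, 21, 21), iso)
  sk <- skeletonize(binary_mask(m, iso))
  expect_lte(nrow(sk$voxels), 10)
})

test_that("Y-phantom skeleton and graph recover ground-truth topology", {
  ph <- generate_phantom(y_spec())
  sk <- prune_hairs(skeletonize(ph$vessel_masks[[1]]))
  adj <- microvasc:::skeleton_adjacency(sk)
  expect_gte(sum(adj$degree >= 3), 1L)
  g <- build_graph(sk)
  expect_equal(length(g$edges), 3L)
  expect_equal(sum(g$nodes$degree >= 3), 1L)
  expect_equal(sum(g$nodes$degree == 1), 3L)
  # edge lengths within 5% of the analytic arm lengths
  truth <- sort(vapply(ph$graph$edges, `[[`, 0, "length"))
  est <- sort(vapply(g$edges, `[[`, 0, "length"))
  expect_true(all(abs(est - truth) / truth < 0.1))
  # vertex spacing on the 0.99 grid
  for (e in g$edges) {
    st <- sqrt(rowSums(diff(e$path)^2))
    expect_true(all(st >= 0.98 & st <= 1.74))
  }
})

test_that("hair pruning follows the 20-um threshold and merge rule", {
  # main path along x with a short spur: spur < 20 um removed
  main <- cbind(5:56, 30, 30)
  spur15 <- cbind(30, 31:45, 30)   # ~15 um
  sk <- skeleton_from_indices(rbind(main, spur15), c(60, 60, 60))
  pr <- prune_hairs(sk)
  g <- build_graph(pr)
  expect_equal(length(g$edges), 1L)
  expect_equal(sum(g$nodes$degree >= 3), 0L)

  # 25 um branch: kept
  spur25 <- cbind(30, 31:56, 30)
  sk2 <- skeleton_from_indices(rbind(main, spur25), c(60, 60, 60))
  g2 <- build_graph(prune_hairs(sk2))
  expect_equal(length(g2$edges), 3L)

  # junction with terminal branches of ~8 and ~30 um: short one removed,
  # long one merged with the main branch, junction dissolved
  main2 <- cbind(5:30, 30, 30)      # terminates at the junction
  long <- cbind(30, 31:60, 30)      # ~30 um terminal
  short <- cbind(31:38, 30, 31)     # ~8 um terminal (diagonal attach)
  sk3 <- skeleton_from_indices(rbind(main2, long, short), c(64, 64, 64))
  g3 <- build_graph(prune_hairs(sk3))
  expect_equal(length(g3$edges), 1L)
  expect_equal(sum(g3$nodes$degree >= 3), 0L)
  expect_gt(g3$edges[[1]]$length, 50)

  # idempotence
  pr2 <- prune_hairs(pr)
  expect_identical(pr$voxels, pr2$voxels)
})

test_that("pruning never disconnects the non-hair core", {
  ph <- generate_phantom(y_spec())
  sk <- skeletonize(ph$vessel_masks[[1]])
  pr <- prune_hairs(sk)
  adj <- microvasc:::skeleton_adjacency(pr)
  # single connected component via flood fill over adjacency
  n <- nrow(pr$voxels)
  seen <- rep(FALSE, n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    for (nb in adj$neigh[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; stack <- c(stack, nb) }
  }
  expect_true(all(seen))
})

test_that("graph construction handles chains, loops and isolated voxels", {
  # open chain of 40 voxels: 2 endpoints, 1 edge, 40 vertices
  chain <- cbind(5:44, 10, 10)
  g <- build_graph(skeleton_from_indices(chain, c(50, 20, 20)))
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(length(g$edges), 1L)
  expect_equal(nrow(g$edges[[1]]$path), 40L)
  expect_equal(g$edges[[1]]$length,
               sum(sqrt(rowSums(diff(sweep(chain - 1, 2, iso, "*"))^2))))

  # closed octagonal loop (chamfered corners keep every voxel degree 2):
  # anchor node + one self-edge
  loop <- rbind(cbind(8:12, 5, 5),
                cbind(c(13, 14), c(6, 7), 5),
                cbind(15, 8:12, 5),
                cbind(c(14, 13), c(13, 14), 5),
                cbind(12:8, 15, 5),
                cbind(c(7, 6), c(14, 13), 5),
                cbind(5, 12:8, 5),
                cbind(c(6, 7), c(7, 6), 5))
  gl <- build_graph(skeleton_from_indices(loop, c(20, 20, 10)))
  expect_equal(nrow(gl$nodes), 1L)
  expect_equal(length(gl$edges), 1L)
  expect_equal(gl$edges[[1]]$from, gl$edges[[1]]$to)
})

test_that("smoothing is exact on straight lines and tangents are unit vectors", {
  chain <- cbind(seq(2, 41), 10, 10)
  g <- smooth_and_tangents(build_graph(skeleton_from_indices(chain, c(45, 20, 20))))
  e <- g$edges[[1]]
  expect_equal(e$smoothed, e$path, tolerance = 1e-6)
  expect_true(all(abs(sqrt(rowSums(e$tangents^2)) - 1) < 1e-6))
  expect_true(all(abs(e$tangents %*% c(1, 0, 0)) > 0.999))

  # quarter-circle arc of radius 30 um: tangents orthogonal to radii within 5 deg
  th <- seq(0, pi / 2, length.out = 48)
  arc <- cbind(35 + 30 * cos(th), 35 + 30 * sin(th), 5)
  edges <- list(list(id = 1L, from = 1L, to = 2L, path = arc,
                     length = sum(sqrt(rowSums(diff(arc)^2)))))
  nodes <- data.frame(id = 1:2, x = arc[c(1, 48), 1], y = arc[c(1, 48), 2],
                      z = 5, degree = 1L)
  ga <- smooth_and_tangents(microvasc:::new_vascular_graph(nodes, edges, iso,
                                                           c(70, 70, 10)))
  tg <- ga$edges[[1]]$tangents
  rad <- sweep(ga$edges[[1]]$smoothed, 2, c(35, 35, 5))
  inner <- abs(rowSums(tg * rad / sqrt(rowSums(rad^2))))
  ang <- 90 - acos(pmin(inner, 1)) * 180 / pi
  expect_true(all(abs(ang[5:44]) < 5))

  bad <- microvasc:::new_vascular_graph(nodes,
                                        list(list(id = 1, from = 1, to = 1,
                                                  path = arc[1, , drop = FALSE],
                                                  length = 0)), iso, c(70, 70, 10))
  expect_error(smooth_and_tangents(bad), "single vertex")
})
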