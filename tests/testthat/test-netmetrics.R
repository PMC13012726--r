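# line graphs for toy topologies are built directly
toy_graph <- function(edge_list, n_nodes, lengths = NULL) {
  edges <- lapply(seq_len(nrow(edge_list)), function(k) {
    p <- rbind(c(0, 0, 0), c(if (is.null(lengths)) 10 else lengths[k], 0, 0))
    list(id = k, from = edge_list[k, 1], to = edge_list[k, 2], path = p,
         length = if (is.null(lengths)) 10 else lengths[k])
  })
  nodes <- data.frame(id = seq_len(n_nodes), x = 0, y = 0, z = 0,
                      degree = tabulate(as.integer(edge_list), n_nodes))
  microvasc:::new_vascular_graph(nodes, edges, iso, c(10, 10, 10))
}

test_that("line graph counts links between junction-sharing vessels", {
  # Y-junction: 3 vessels at one node -> 3 links
  g <- toy_graph(cbind(c(1, 1, 1), c(2, 3, 4)), 4)
  lg <- vessel_line_graph(g, setNames(c(1, 2, 3), 1:3))
  expect_equal(length(lg$nodes), 3L)
  expect_equal(nrow(lg$links), 3L)

  # chain A-B: one shared junction -> 1 link
  g2 <- toy_graph(cbind(c(1, 2), c(2, 3)), 3)
  lg2 <- vessel_line_graph(g2, setNames(c(1, 5), 1:2))
  expect_equal(nrow(lg2$links), 1L)

  # disconnected vessels: no links
  g3 <- toy_graph(cbind(c(1, 3), c(2, 4)), 4)
  lg3 <- vessel_line_graph(g3, setNames(c(1, 5), 1:2))
  expect_equal(nrow(lg3$links), 0L)
})

test_that("assortativity matches brute-force Pearson on constructed graphs", {
  # two dumbbells with values (1,1) and (5,5) -> q = 1
  g <- toy_graph(cbind(c(1, 2, 4, 5), c(2, 3, 5, 6)), 6)
  lg <- vessel_line_graph(g, setNames(c(1, 1, 5, 5), 1:4))
  expect_equal(assortativity(lg), 1)

  # star line graph: centre vessel +1 linked to three leaves at -1 -> q = -1
  star <- structure(list(nodes = 1:4, values = c(1, -1, -1, -1),
                         links = cbind(c(1, 1, 1), c(2, 3, 4))),
                    class = "line_graph")
  expect_equal(assortativity(star), -1)
  expect_equal(assortativity(star),
               assortativity_oracle(star$values, star$links))

  gp <- toy_graph(cbind(c(1, 2), c(2, 3)), 3)
  lgp <- vessel_line_graph(gp, setNames(c(1, -1), 1:2))
  expect_error(assortativity(lgp), ">= 2 links")

  # path with values (1,2,3): ordered pairs {(1,2),(2,1),(2,3),(3,2)} -> q 0
  gq <- toy_graph(cbind(c(1, 2, 3), c(2, 3, 4)), 4)
  lgq <- vessel_line_graph(gq, setNames(c(1, 2, 3), 1:3))
  expect_equal(assortativity(lgq), 0)
  expect_equal(assortativity(lgq),
               assortativity_oracle(c(1, 2, 3), lgq$links))

  # affine invariance
  lgq2 <- vessel_line_graph(gq, setNames(c(1, 2, 3) * 7 - 2, 1:3))
  expect_equal(assortativity(lgq2), assortativity(lgq), tolerance = 1e-12)

  # zero variance errors, never a silent 0
  lgz <- vessel_line_graph(gq, setNames(c(2, 2, 2), 1:3))
  expect_error(assortativity(lgz), "variance")
})

test_that("edge resistance follows the Poiseuille R^-4 law in SI units", {
  rho <- edge_resistance(100, 4, 4)
  expect_equal(rho, 8 * 0.004 * 1e-4 / (pi * (4e-6)^4), tolerance = 1e-12)
  expect_equal(rho, 3.98e15, tolerance = 0.01)
  expect_equal(edge_resistance(200, 4, 4) / rho, 2)
  expect_equal(rho / edge_resistance(100, 8, 4), 16)
  expect_error(edge_resistance(100, 0), "radius")
})

test_that("capillary efficiency matches closed forms and is monotone", {
  # two junctions, one capillary: E = 1/rho
  g1 <- toy_graph(cbind(1, 2), 2, lengths = 50)
  E1 <- capillary_efficiency(g1, setNames(3, "1"))
  expect_equal(as.numeric(E1), 1 / edge_resistance(50, 3), tolerance = 1e-12)

  # three-node path: enumerate the 6 ordered pairs
  g2 <- toy_graph(cbind(c(1, 2), c(2, 3)), 3, lengths = c(40, 60))
  r <- c(2.5, 3.5)
  rho <- edge_resistance(c(40, 60), r)
  E2 <- capillary_efficiency(g2, setNames(r, 1:2))
  expect_equal(as.numeric(E2),
               (2 / rho[1] + 2 / rho[2] + 2 / (rho[1] + rho[2])) / 6,
               tolerance = 1e-12)

  # uniform +10% dilation: %dE = 1.1^4 - 1
  E2b <- capillary_efficiency(g2, setNames(r * 1.1, 1:2))
  ch <- efficiency_change(E2, E2b)
  expect_equal(ch$pct, 100 * (1.1^4 - 1), tolerance = 1e-9)
  chm <- efficiency_change(E2, capillary_efficiency(g2, setNames(r * 0.9, 1:2)))
  expect_equal(chm$pct, 100 * (0.9^4 - 1), tolerance = 1e-9)

  # triangle: increasing one edge radius strictly increases E
  g3 <- toy_graph(cbind(c(1, 2, 3), c(2, 3, 1)), 3, lengths = c(30, 40, 50))
  r3 <- c(2, 3, 2.5)
  Ea <- capillary_efficiency(g3, setNames(r3, 1:3))
  r3b <- r3; r3b[2] <- r3[2] * 1.2
  Eb <- capillary_efficiency(g3, setNames(r3b, 1:3))
  expect_gt(as.numeric(Eb), as.numeric(Ea))

  # vessels > 10 um diameter excluded
  g4 <- toy_graph(cbind(c(1, 2), c(2, 3)), 3, lengths = c(40, 60))
  E4 <- capillary_efficiency(g4, setNames(c(3, 5.5), 1:2))  # 11 um excluded
  expect_equal(attr(E4, "n_nodes"), 2L)
  expect_equal(as.numeric(E4), 1 / edge_resistance(40, 3), tolerance = 1e-12)

  # disconnected pairs contribute zero
  g5 <- toy_graph(cbind(c(1, 3), c(2, 4)), 4, lengths = c(40, 40))
  E5 <- capillary_efficiency(g5, setNames(c(3, 3), 1:2))
  rho5 <- edge_resistance(40, 3)
  expect_equal(as.numeric(E5), (4 / rho5) / (4 * 3), tolerance = 1e-12)

  expect_error(efficiency_change(E1, E2), "node sets")
})

test_that("responder gate sits exactly at twice the baseline SD", {
  s <- data.frame(edge = 1:5, length = c(60, 60, 60, 15, 60),
                  baseline_radius_sd = c(0.2, 0.2, 0.2, 0.1, 0.2),
                  delta_radius = c(0.5, 0.3, -0.5, -0.5, 0.4000001))
  out <- classify_responders(s)
  expect_equal(as.character(out$responder),
               c("dilator", "none", "constrictor", "none", "dilator"))
  # exactly 2x SD is not a response (strict inequality)
  s2 <- data.frame(edge = 1, length = 60, baseline_radius_sd = 0.2,
                   delta_radius = 0.4)
  expect_equal(as.character(classify_responders(s2)$responder), "none")
  # single baseline time point: excluded with warning
  s3 <- data.frame(edge = 1, length = 60, baseline_radius_sd = NA_real_,
                   delta_radius = 1)
  expect_warning(out3 <- classify_responders(s3), "single baseline")
  expect_true(is.na(out3$responder))
})

test_that("morphometrics reproduce count and density arithmetic", {
  ph <- generate_phantom(y_spec())
  g <- ph$graph
  rec <- do.call(rbind, lapply(g$edges, function(e)
    data.frame(edge = e$id, vertex = seq_len(nrow(e$path)),
               x = e$path[, 1], y = e$path[, 2], z = e$path[, 3],
               timepoint = 1, radius = 2.5, radius_sd = 0.05, retained = 36)))
  mm <- compute_morphometrics(g, rec, fov_volume_mm3 = 0.01,
                              neuron_mask = ph$neuron_mask)
  expect_equal(mm$vessel_count, 3L)
  expect_equal(mm$junction_count, 1L)
  expect_equal(mm$vessel_density_mm3, 300)
  expect_equal(mm$junction_density_mm3, 100)
  expect_equal(mm$neuron_count, 0L)
  expect_equal(mm$mean_baseline_radius_um, 2.5)

  # single 100-um tube in 0.001 mm^3: length density 0.1 m/mm^3
  g2 <- toy_graph(cbind(1, 2), 2, lengths = 100)
  rec2 <- data.frame(edge = 1, vertex = 1:2, x = c(0, 100), y = 0, z = 0,
                     timepoint = 1, radius = 3, radius_sd = 0, retained = 36)
  mm2 <- compute_morphometrics(g2, rec2, 0.001)
  expect_equal(mm2$cumulative_length_density_m_mm3, 0.1)
  # densities scale inversely with FOV volume
  mm3 <- compute_morphometrics(g2, rec2, 0.002)
  expect_equal(mm2$vessel_density_mm3 / mm3$vessel_density_mm3, 2)
  expect_error(compute_morphometrics(g2, rec2, 0), "FOV")
})
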