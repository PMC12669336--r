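test_that("network ASCII round-trips and validates", {
  g <- straight_capillary(n_nodes = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_capillary_network(g, f)
  g2 <- read_capillary_network(f)
  expect_equal(g2$nodes, g$nodes, ignore_attr = TRUE)
  expect_equal(g2$segments$radius_um, g$segments$radius_um)
  expect_equal(g2$inlets, g$inlets)
  expect_equal(g2$outlets, g$outlets)

  ## negative radius rejected with the offending line number
  bad <- readLines(f)
  bad[5] <- "1 1 2 -4"          # first segment line
  fb <- withr::local_tempfile(fileext = ".txt")
  writeLines(bad, fb)
  expect_error(read_capillary_network(fb), "line 5")

  ## disconnected graph rejected
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5), c(6, 5, 5))
  seg <- data.frame(n1 = c(1, 3), n2 = c(2, 4), radius_um = 2)
  expect_error(capillary_graph(nodes, seg), "connected")
})

test_that("synthetic generator: deterministic, Murray radii, inside box", {
  g1 <- generate_synthetic_network(seed = 5, levels = 3)
  g2 <- generate_synthetic_network(seed = 5, levels = 3)
  expect_identical(g1, g2)
  box <- c(150, 160, 140)
  expect_true(all(g1$nodes >= 0 & g1$nodes <= rep(box,
                                                  each = nrow(g1$nodes))))
  ## parent/child radius ratio 2^(1/gamma) at every tree bifurcation
  tree <- g1$segments[g1$segments$kind == "tree", ]
  n_bif <- 0
  for (nd in unique(tree$n1)) {
    parent_r <- tree$radius_um[tree$n2 == nd]
    child_r <- tree$radius_um[tree$n1 == nd]
    if (length(parent_r) == 1 && length(child_r) == 2) {
      n_bif <- n_bif + 1
      expect_equal(parent_r / child_r[1], 2^(1 / 3), tolerance = 1e-12)
      expect_equal(child_r[1], child_r[2])
    }
  }
  expect_gte(n_bif, 2 * (2^3 - 1) - 2)   # both trees fully bifurcate
  ## parses through the writer/reader and passes all invariants
  f <- withr::local_tempfile(fileext = ".txt")
  write_capillary_network(g1, f)
  expect_s3_class(read_capillary_network(f), "capillary_graph")
  expect_error(generate_synthetic_network(levels = 0), "levels")
})

test_that("zero inflow with a gauge gives the constant solution", {
  g <- straight_capillary()
  dom <- tissue_domain(grid = c(5, 5, 5))
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = 0, outlet_flows = 0)
  expect_equal(sol$p1, rep(30, length(sol$p1)), tolerance = 1e-9)
  expect_equal(sol$p3, rep(30, length(sol$p3)), tolerance = 1e-9)
  expect_equal(sum(abs(sol$exchange)), 0, tolerance = 1e-9)
})

test_that("Lp = 0 straight vessel reproduces the two-point closed form", {
  g <- straight_capillary(n_nodes = 11, L_um = 100, r_um = 4)
  dom <- tissue_domain(grid = c(5, 5, 5))
  K1 <- 5e4
  Qin <- 1e5   # um^3/s
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = Qin, K1 = K1, Lp = 0)
  ## p1 linear with slope -v/K1 (v = Q/(pi R^2)); tissue decoupled
  v <- Qin / (pi * 4^2)
  dp_dz <- diff(sol$p1) / diff(g$nodes[, 1])
  expect_equal(dp_dz, rep(-v / K1, 10), tolerance = 1e-8)
  expect_equal(stats::sd(sol$p3), 0, tolerance = 1e-10)
  ## analytic solution exact at any resolution: refinement error stays at
  ## machine level (order >= 1 trivially)
  g2 <- straight_capillary(n_nodes = 21)
  sol2 <- solve_pressure_3d1d(g2, dom, inlet_flows = Qin, K1 = K1, Lp = 0)
  dp2 <- diff(sol2$p1) / diff(g2$nodes[, 1])
  expect_equal(dp2, rep(-v / K1, 20), tolerance = 1e-8)
})

test_that("discrete conservation: wall exchange balances throttled flow", {
  g <- straight_capillary(n_nodes = 9)
  dom <- tissue_domain(grid = c(6, 6, 6))
  Qin <- 1e5
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = Qin,
                             outlet_flows = 0.4 * Qin, Lp = 1e-2,
                             gauge_at = "cell3d", allow_imbalance = TRUE)
  expect_equal(sum(sol$exchange), 0.6 * Qin, tolerance = 1e-6)
})

test_that("interior solve residual is tiny and solution is gauge invariant", {
  g <- generate_synthetic_network(seed = 3, levels = 3)
  dom30 <- tissue_domain(grid = c(8, 8, 8), gauge_mmHg = 30)
  dom40 <- tissue_domain(grid = c(8, 8, 8), gauge_mmHg = 40)
  qin <- c(6e4, 4e4)
  s30 <- solve_pressure_3d1d(g, dom30, inlet_flows = qin)
  s40 <- solve_pressure_3d1d(g, dom40, inlet_flows = qin)
  expect_lt(s30$residual, 1e-8)
  expect_equal(s40$p1 - s30$p1, rep(10, length(s30$p1)), tolerance = 1e-7)
  expect_equal(s40$p3 - s30$p3, rep(10, length(s30$p3)), tolerance = 1e-7)
  v30 <- compute_velocities(s30); v40 <- compute_velocities(s40)
  expect_equal(v30$v_seg, v40$v_seg, tolerance = 1e-9)
})

test_that("mirror-symmetric network yields mirror-symmetric pressures", {
  ## Y-shaped network symmetric about y = 50
  nodes <- rbind(c(0, 50, 50), c(40, 50, 50), c(80, 70, 50),
                 c(80, 30, 50), c(120, 70, 50), c(120, 30, 50))
  seg <- data.frame(n1 = c(1, 2, 2, 3, 4), n2 = c(2, 3, 4, 5, 6),
                    radius_um = c(4, 3, 3, 3, 3))
  g <- capillary_graph(nodes, seg, inlets = 1L, outlets = c(5L, 6L))
  ## odd cell count across the symmetry plane so the nearest-cell
  ## quadrature respects the mirror
  dom <- tissue_domain(box = c(120, 100, 100), grid = c(6, 7, 6))
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = 1e5)
  expect_equal(sol$p1[3], sol$p1[4], tolerance = 1e-9)
  expect_equal(sol$p1[5], sol$p1[6], tolerance = 1e-9)
  p3 <- array(sol$p3, dim = dom$grid)
  expect_equal(p3, p3[, dom$grid[2]:1, ], tolerance = 1e-8)
})

test_that("velocities follow the pressure gradient", {
  g <- straight_capillary(n_nodes = 5)
  dom <- tissue_domain(grid = c(5, 5, 5))
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = 1e5, Lp = 0, K1 = 1e4)
  vel <- compute_velocities(sol)
  ## uniform two-point gradient: v = K1 dp/L, positive towards the outlet
  dp <- sol$p1[1] - sol$p1[2]
  L <- g$segments$length_um[1]
  expect_equal(vel$v_seg[1], 1e4 * dp / L, tolerance = 1e-9)
  expect_true(all(vel$v_seg > 0))
  ## uniform pressure: zero velocities
  s0 <- solve_pressure_3d1d(g, dom, inlet_flows = 0, outlet_flows = 0)
  v0 <- compute_velocities(s0)
  expect_equal(max(abs(v0$v_seg)), 0, tolerance = 1e-9)
  expect_equal(max(abs(v0$v_cell)), 0, tolerance = 1e-9)
})

test_that("transport: quiescence, advection speed and mass conservation", {
  g <- straight_capillary(n_nodes = 41, L_um = 200)
  dom <- tissue_domain(box = c(200, 100, 100), grid = c(5, 5, 5))
  ## quiescent medium, uniform concentration: unchanged
  c1 <- rep(2, 41); c3 <- rep(2, prod(dom$grid))
  out <- solve_transport(g, dom, NULL, c1, c3, dt = 0.01, n_steps = 50)
  expect_equal(out$c1, c1)
  expect_equal(out$c3, c3)

  ## pure advection of a pulse: centroid moves at v_c t
  sol <- solve_pressure_3d1d(g, dom, inlet_flows = 1e4, Lp = 0, K1 = 1e4)
  vel <- compute_velocities(sol)
  v <- vel$v_seg[1]
  x <- g$nodes[, 1]
  c1 <- exp(-((x - 50) / 10)^2)
  dt <- 0.5 * min(g$segments$length_um) / v
  n_steps <- 24   # centroid travels ~60 um, staying interior
  out <- solve_transport(g, dom, sol, c1, rep(0, prod(dom$grid)),
                         dt = dt, n_steps = n_steps)
  cen0 <- sum(x * c1) / sum(c1)
  cen1 <- sum(x * out$c1) / sum(out$c1)
  expect_equal(cen1 - cen0, v * dt * n_steps, tolerance = 0.05)

  ## closed system (no flow, diffusion + exchange on): mass drift < 1e-6
  ## per 1000 steps
  c1 <- exp(-((x - 100) / 20)^2)
  out <- solve_transport(g, dom, NULL, c1, rep(0.1, prod(dom$grid)),
                         dt = 0.01, n_steps = 1000, D1 = 50, D3 = 100,
                         eta_w = 1)
  expect_lt(abs(out$mass1 - out$mass0) / out$mass0, 1e-6)
})

test_that("radius modulation rescales conductance as configured", {
  g <- straight_capillary(n_nodes = 5)
  expect_identical(apply_radius_modulation(g, 1), g)
  dom <- tissue_domain(grid = c(5, 5, 5))
  ## same pressure drop, dilated vessel: flow grows as factor^4 with
  ## Poiseuille K1 (K1 ~ R^2 and section ~ R^2)
  s1 <- solve_pressure_3d1d(g, dom, inlet_flows = 1e5, Lp = 0,
                            viscosity = "constant")
  gd <- apply_radius_modulation(g, 1.2)
  s2 <- solve_pressure_3d1d(gd, dom, inlet_flows = 1e5, Lp = 0,
                            viscosity = "constant")
  drop1 <- s1$p1[1] - s1$p1[5]
  drop2 <- s2$p1[1] - s2$p1[5]
  expect_equal(drop1 / drop2, 1.2^4, tolerance = 1e-6)
  ## flow-driven BCs: total throughput preserved under modulation
  expect_equal(sum(s2$Q_seg[1]), sum(s1$Q_seg[1]), tolerance = 1e-9)
  expect_error(apply_radius_modulation(g, -1))
})
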