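cst <- ngvu_constants

test_that("tube law: zero at reference area, Table-2 stiffness oracle", {
  expect_equal(young_laplace_pressure(2.5, 2.5, 1e5), 0)
  expect_equal(young_laplace_pressure(4 * 1.3, 1.3, 7e4), 7e4)
  expect_error(young_laplace_pressure(-1, 1, 1), "positive")
  ## strictly increasing in A
  A <- seq(0.5, 3, length.out = 50)
  expect_true(all(diff(young_laplace_pressure(A, 1.5, 1e5)) > 0))
  ## brainstem branch vessel: h0 = 0.034 cm, E = 0.8e6 Pa, R0 = 0.08 cm;
  ## independent arithmetic for G0 with nu = 1/2
  A0 <- pi * 0.08^2
  G0_hand <- sqrt(pi) * 0.034 * 0.8e6 / ((1 - 0.25) * sqrt(A0))
  expect_equal(tube_stiffness(0.034, 0.8e6, A0), G0_hand)
  expect_equal(young_laplace_pressure(2 * A0, A0, G0_hand),
               G0_hand * (sqrt(2) - 1))
})

test_that("half-sine inflow matches its printed branches", {
  expect_equal(inlet_flow(0, 1, 485), 0)
  expect_equal(inlet_flow(0.15, 1, 485), 485)
  expect_equal(inlet_flow(0.5, 1, 485), 0)   # second branch
  expect_equal(inlet_flow(1.15, 1, 485), 485) # periodic extension
  ## continuity at 0.3 T
  expect_equal(inlet_flow(0.3 - 1e-9, 1, 485), 0, tolerance = 1e-5)
  expect_error(inlet_flow(0.1, -1, 485), "positive")
  expect_error(inlet_flow(0.1, 1, -5), "non-negative")
})

test_that("vessel table parses with invariants and paper rows", {
  tab <- read_vessel_table()
  expect_equal(nrow(tab), 37)
  expect_identical(tab$provenance[tab$id %in% c(14, 17, 34:37)],
                   rep("paper", 6))
  v37 <- tab[tab$id == 37, ]
  expect_equal(c(v37$L_cm, v37$R0_cm, v37$h0_cm, v37$E_Pa),
               c(6.0, 0.08, 0.034, 8e5))
  net <- build_arterial_network(tab)
  expect_equal(net$A0, pi * tab$R0_cm^2)
  expect_true(all(net$n_cells >= 2))
  ## every non-outlet z=L end and every z=0 end except the inlet is at
  ## exactly one junction
  ends <- unlist(net$junctions)
  expect_equal(sort(ends[ends > 0]), sort(tab$id[tab$outlet_flag == 0]))
  expect_equal(sort(-ends[ends < 0]), sort(tab$id[tab$id != 1]))
})

test_that("rest state is preserved and closed ends conserve area", {
  net <- single_vessel_net()
  probes <- data.frame(vessel = 1L, z_frac = 0.5)
  r <- macro_run(net, probes, t_end = 0.01, extra_bc = list(
    inlet_type = "closed"))
  expect_true(all(abs(r$A - net$A0[1]) < 1e-14))
  expect_true(all(abs(r$Q) < 1e-14))
})

test_that("periodic single vessel conserves integral of A to machine eps", {
  net <- single_vessel_net(dz_cm = 0.2)
  n <- net$n_cells[1]
  z <- (seq_len(n) - 0.5) * net$dz[1]
  A_init <- net$A0[1] * (1 + 0.05 * exp(-((z - 10) / 2)^2))
  init <- list(list(A = A_init, Q = rep(0, n)))
  probes <- data.frame(vessel = 1L, z_frac = 0.5)
  r <- macro_run(net, probes, t_end = 0.02, init = init,
                 extra_bc = list(periodic_vessels = 1L))
  A_final <- r$state[[1]]$A
  expect_equal(sum(A_final) * net$dz[1], sum(A_init) * net$dz[1],
               tolerance = 1e-14)
})

test_that("small pulses propagate at the analytic characteristic speed", {
  net <- single_vessel_net(L = 40, dz_cm = 0.05)
  c0 <- net$c0[1]
  n <- net$n_cells[1]
  z <- (seq_len(n) - 0.5) * net$dz[1]
  init <- list(list(A = net$A0[1] * (1 + 1e-3 * exp(-((z - 8) / 1.5)^2)),
                    Q = rep(0, n)))
  probes <- data.frame(vessel = 1L, z_frac = 0.5)
  t_end <- 10 / c0   # pulse travels ~10 cm
  r <- macro_run(net, probes, t_end = t_end, init = init,
                 extra_bc = list(inlet_type = "closed"))
  A_final <- r$state[[1]]$A
  ## right-moving half of the split pulse
  right <- z > 10
  peak_z <- z[right][which.max(A_final[right])]
  ## the pulse splits at t=0; the right-moving peak starts at z = 8
  measured_c <- (peak_z - 8) / t_end
  expect_lt(abs(measured_c - c0) / c0, 0.05)
})

test_that("scheme self-converges at order >= 1 under grid refinement", {
  run_at <- function(dz) {
    net <- single_vessel_net(L = 20, dz_cm = dz)
    n <- net$n_cells[1]
    z <- (seq_len(n) - 0.5) * net$dz[1]
    init <- list(list(A = net$A0[1] * (1 + 0.02 * exp(-((z - 10) / 2)^2)),
                      Q = rep(0, n)))
    r <- macro_run(net, data.frame(vessel = 1L, z_frac = 0.5),
                   t_end = 4 / net$c0[1], init = init,
                   extra_bc = list(inlet_type = "closed"))
    r$state[[1]]$A
  }
  A1 <- run_at(0.2); A2 <- run_at(0.1); A4 <- run_at(0.05)
  restrict <- function(A) (A[seq(1, length(A), 2)] +
                             A[seq(2, length(A), 2)]) / 2
  e1 <- sqrt(mean((A1 - restrict(A2))^2))
  e2 <- sqrt(mean((A2 - restrict(A4))^2))
  expect_gte(log2(e1 / e2), 1)
})

test_that("junction coupling: symmetry, pass-through and residuals", {
  ## symmetric bifurcation: identical children receive identical flows
  tab <- data.frame(
    id = 1:3, name = c("p", "c1", "c2"),
    parent_ids = c("", "1", "1"), child_ids = c("2:3", "", ""),
    L_cm = c(10, 8, 8), R0_cm = c(0.3, 0.22, 0.22),
    h0_cm = c(0.05, 0.04, 0.04), E_Pa = 4e5,
    outlet_flag = c(0L, 1L, 1L), provenance = "synthetic")
  tab$parents <- list(integer(0), 1L, 1L)
  tab$children <- list(c(2L, 3L), integer(0), integer(0))
  net <- build_arterial_network(tab, dz_cm = 0.2, Qmax = 100)
  probes <- data.frame(vessel = c(2L, 3L), z_frac = c(0.5, 0.5))
  r <- macro_run(net, probes, t_end = 0.5)
  expect_equal(r$Q[, 1], r$Q[, 2], tolerance = 1e-9)

  ## asymmetric bifurcation: solver-reported junction residual is tiny
  tab$R0_cm <- c(0.3, 0.25, 0.15)
  net2 <- build_arterial_network(tab, dz_cm = 0.2, Qmax = 100)
  r2 <- macro_run(net2, probes, t_end = 0.5)
  ptypical <- 100 * cst$mmHg_to_barye
  expect_lt(r2$max_junction_residual / ptypical, 1e-10)

  ## two-vessel junction with identical properties is transparent:
  ## the split vessel behaves like one continuous vessel
  tabs <- data.frame(
    id = 1:2, name = c("a", "b"), parent_ids = c("", "1"),
    child_ids = c("2", ""), L_cm = c(10, 10), R0_cm = 0.3,
    h0_cm = 0.05, E_Pa = 4e5, outlet_flag = c(0L, 1L),
    provenance = "synthetic")
  tabs$parents <- list(integer(0), 1L)
  tabs$children <- list(2L, integer(0))
  net_split <- build_arterial_network(tabs, dz_cm = 0.1, Qmax = 100)
  net_whole <- build_arterial_network({
    t2 <- single_vessel_tab(L = 20, R0 = 0.3); t2$outlet_flag <- 1L; t2
  }, dz_cm = 0.1, Qmax = 100)
  rs <- macro_run(net_split, data.frame(vessel = 2L, z_frac = 1),
                  t_end = 0.4)
  rw <- macro_run(net_whole, data.frame(vessel = 1L, z_frac = 1),
                  t_end = 0.4)
  expect_equal(rs$Q[, 1], rw$Q[, 1], tolerance = 5e-3)
})

test_that("windkessel update follows the RC closed forms", {
  cst <- ngvu_constants
  wk <- list(R1 = 1e4, R2 = 1e5, C = 1e-5, pven = 5 * cst$mmHg_to_barye,
             p = 80 * cst$mmHg_to_barye)
  ## free decay with Q = 0: exponential with time constant R2 C = 1 s
  dt <- 1e-4
  p <- wk
  for (i in 1:10000) p <- windkessel_update(0, p, dt)
  analytic <- wk$pven + (wk$p - wk$pven) * exp(-1 / (wk$R2 * wk$C))
  expect_equal(p$p, analytic, tolerance = 1e-3)
  ## constant inflow: boundary pressure -> pven + Q (R1 + R2)
  p <- wk
  for (i in 1:80000) p <- windkessel_update(2, p, 1e-3)
  expect_equal(p$p_boundary, wk$pven + 2 * (wk$R1 + wk$R2),
               tolerance = 1e-3)
  ## enormous compliance: state pressure frozen over a beat
  p <- wk; p$C <- 1e3
  p0 <- p$p
  for (i in 1:1000) p <- windkessel_update(5, p, 1e-3)
  expect_equal(p$p, p0, tolerance = 1e-4)
  expect_error(windkessel_update(1, list(R1 = -1, R2 = 1, C = 1,
                                         pven = 0, p = 0), 0.1))
})
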