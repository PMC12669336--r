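syn <- calibrate_rest(synapse_params(TRUE))

test_that("HH rate expressions match printed values and limits", {
  r <- hh_rates(-70)
  expect_equal(r$beta_n, 0.125)
  expect_equal(r$beta_m, 4)
  expect_equal(r$alpha_h, 0.07)
  ## removable singularities handled by their limits
  expect_equal(hh_rates(-60)$alpha_n, 0.1)
  expect_equal(hh_rates(-45)$alpha_m, 1)
  ## continuity across the singular points
  expect_equal(hh_rates(-60 + 1e-9)$alpha_n, 0.1, tolerance = 1e-6)
  expect_equal(hh_rates(-45 - 1e-9)$alpha_m, 1, tolerance = 1e-6)
})

test_that("HH neuron: quiescent at rest, periodic under drive, gates in [0,1]", {
  s <- hh_rest_state(syn)
  ## I_app = 0: no spike within 100 ms
  Vmax <- -Inf
  for (i in 1:10000) {
    s <- hh_step(s, 0, 0.01, syn)
    Vmax <- max(Vmax, s[["V"]])
  }
  expect_lt(Vmax, -50)

  ## sustained suprathreshold drive: stable inter-spike interval, checked
  ## across integrator step sizes (1 percent)
  isi_of <- function(dt) {
    s <- hh_rest_state(syn)
    crossings <- numeric(0)
    prevV <- s[["V"]]
    t <- 0
    gates_ok <- TRUE
    while (t < 150) {
      s <- hh_step(s, 10, dt, syn)
      t <- t + dt
      if (prevV < 0 && s[["V"]] >= 0) crossings <- c(crossings, t)
      prevV <- s[["V"]]
      gates_ok <- gates_ok && all(s[c("n", "m", "h")] >= 0) &&
        all(s[c("n", "m", "h")] <= 1)
    }
    expect_true(gates_ok)
    mean(diff(crossings[-1]))
  }
  isi1 <- isi_of(0.01)
  isi2 <- isi_of(0.005)
  expect_gt(isi1, 5)
  expect_lt(abs(isi1 - isi2) / isi2, 0.01)
})

test_that("Nernst potential arithmetic", {
  expect_equal(nernst_potential(2, 2), 0)
  ## ratio e at z = 2, T = 300 K: R T / (2 F) = 12.93 mV
  expect_equal(nernst_potential(exp(1) * 1, 1, 300, 2), 12.93,
               tolerance = 1e-3)
  base <- nernst_potential(4, 1, 310, 1)
  expect_equal(nernst_potential(8, 1, 310, 1) - base,
               1e3 * ngvu_constants$R_gas * 310 / ngvu_constants$F_const *
                 log(2))
  expect_error(nernst_potential(-1, 1), "> 0")
})

test_that("N-type channel: Boltzmann midpoint, reversal, relaxation", {
  r <- ntype_channel(0.2, syn[["V_mCa"]], dt = 1e-9, p = syn)
  ## steady state is 1/2 at the Boltzmann midpoint
  r2 <- ntype_channel(0.5, syn[["V_mCa"]], dt = 1e6, p = syn)
  expect_equal(r2$m_Ca, 0.5, tolerance = 1e-6)
  ## zero current at the Nernst reversal
  VCa <- nernst_potential(syn[["c_ext"]], syn[["c_i_rest"]])
  expect_equal(ntype_channel(0.3, VCa, 0.1, syn)$I_Ca, 0, tolerance = 1e-9)
  ## closed-form exponential relaxation at constant V
  m0 <- 0.9; V <- -30; tt <- 2.5
  m_inf <- 1 / (1 + exp((syn[["V_mCa"]] - V) / syn[["k_mCa"]]))
  expect_equal(ntype_channel(m0, V, tt, syn)$m_Ca,
               m_inf + (m0 - m_inf) * exp(-tt / syn[["tau_mCa"]]))
})

test_that("fast calcium balance: midpoints, leak zero and calibrated rest", {
  p <- syn
  ## PMCA at half maximum when c_i = K_PM_Ca: check via difference of terms
  leakless <- function(ci) {
    fast_calcium_rhs(ci, 0, p) - p[["v_leak"]] * (p[["c_ext"]] - ci)
  }
  expect_equal(leakless(p[["K_PM_Ca"]]),
               -ngvu:::current_to_flux(p[["v_PM_Ca"]] / 2, p))
  ## leak term vanishes at external concentration
  expect_equal(fast_calcium_rhs(p[["c_ext"]], 0, p),
               leakless(p[["c_ext"]]))
  ## rest is a fixed point after calibration (I_Ca at rest potential)
  mc <- ntype_channel(0, -70, 1e9, p)
  expect_equal(fast_calcium_rhs(p[["c_i_rest"]], mc$I_Ca, p), 0,
               tolerance = 1e-12)
})

test_that("slow calcium subsystem: flux zeros and the ER pairing identity", {
  p <- syn
  ## c_i = c_ER: channel and leak vanish; only the pump remains
  d <- slow_calcium_rhs(c_i = p[["k3"]], c_ER = p[["k3"]], p_ip3 = 0.3,
                        q = 0.5, g_a = 0, p = p)
  expect_equal(d[["dc_slow"]], -p[["v3"]] / 2)
  ## dc_ER = -dc_slow / c1 identically (volume-ratio pairing)
  for (ci in c(0.1, 1, 5)) {
    d <- slow_calcium_rhs(ci, 150, 0.4, 0.6, 0.01, p)
    expect_equal(d[["dc_ER"]], -d[["dc_slow"]] / p[["c1_er"]])
  }
  ## with membrane fluxes absent, c_slow + c1 c_ER is conserved along a
  ## trajectory of the slow subsystem
  st <- c(cs = 0.05, cer = 120, pip = 0.2, q = 0.7)
  inv0 <- st[["cs"]] + p[["c1_er"]] * st[["cer"]]
  for (i in 1:2000) {
    d <- slow_calcium_rhs(st[["cs"]], st[["cer"]], st[["pip"]], st[["q"]],
                          0.01, p)
    st <- st + 0.1 * c(d[["dc_slow"]], d[["dc_ER"]], d[["dp"]], d[["dq"]])
  }
  expect_equal(st[["cs"]] + p[["c1_er"]] * st[["cer"]], inv0,
               tolerance = 1e-10)
})

test_that("stochastic sensors match the master-equation distribution", {
  set.seed(42)
  ci <- 5
  Q <- sensor_generator(ci, syn)
  ## all binding propensities vanish without calcium
  Q0 <- sensor_generator(0, syn)
  expect_equal(Q0[1, 2], 0)
  expect_equal(Q0[cbind(1:5, 2:6)], rep(0, 5))
  ## doubling calcium doubles every forward binding propensity
  Q2 <- sensor_generator(2 * ci, syn)
  expect_equal(Q2[cbind(1:5, 2:6)], 2 * Q[cbind(1:5, 2:6)])

  ## mean occupancy over replicas vs the master-equation ODE at
  ## checkpoints, within 3 standard errors (release disabled via lockout)
  n_rep <- 4000
  states <- rep(1L, n_rep)
  pvec <- c(1, rep(0, 6))
  dt <- 0.05
  lock <- rep(TRUE, n_rep)
  for (chk in 1:10) {
    res <- sensor_step(states, ci, dt, lockout = lock, p = syn)
    states <- res$states
    ## master equation advanced by dense sub-stepping
    for (k in 1:50) pvec <- pvec + (dt / 50) * as.numeric(pvec %*% Q)
    emp <- tabulate(states, 7) / n_rep
    se <- sqrt(pmax(pvec * (1 - pvec), 1e-12) / n_rep)
    expect_true(all(abs(emp - pvec) <= 3 * se + 1e-3),
                info = paste("checkpoint", chk))
  }
})

test_that("spontaneous release rate: midpoint, saturation, monotone", {
  expect_equal(spontaneous_rate(15, 15, 2, 0.003), 0.0015)
  expect_equal(spontaneous_rate(1e6, 15, 2, 0.003), 0.003)
  ci <- seq(0, 40, by = 0.5)
  expect_true(all(diff(spontaneous_rate(ci, 15, 2, 0.003)) > 0))
  expect_error(spontaneous_rate(1, 1, 0, 1))
})

test_that("vesicle pools: conservation, decay closed form, lockout", {
  pools <- c(R = 0.6, E = 0.2, t_last_release = -1e9)
  ## R + E + I = 1 preserved across many steps
  for (i in 1:500) {
    pools <- tm_pool_step(pools, 0, 0.1, t = i * 0.1)
    expect_equal(pools[["R"]] + pools[["E"]] + pools[["I"]], 1,
                 tolerance = 1e-12)
  }
  ## f_r = 0: E decays exponentially with tau_inact
  pools <- c(R = 0.3, E = 0.5, t_last_release = -1e9)
  n <- 400; dt <- 0.05
  for (i in 1:n) pools <- tm_pool_step(pools, 0, dt, t = i * dt,
                                       tau_inact = 3)
  expect_equal(pools[["E"]], 0.5 * exp(-n * dt / 3), tolerance = 1e-9)
  ## a release at t0 blocks further release before t0 + 6.34 ms
  pools <- c(R = 1, E = 0, t_last_release = -1e9)
  pools <- tm_pool_step(pools, 0.5, 0.01, t = 10)
  R_after <- pools[["R"]]
  expect_lt(R_after, 1)
  pools2 <- tm_pool_step(pools, 1, 0.01, t = 10 + 6.0)   # inside lockout
  expect_equal(pools2[["R"]], R_after + 0.01 * pools[["I"]] / 800,
               tolerance = 1e-9)
  pools3 <- tm_pool_step(pools, 1, 0.01, t = 10 + 6.5)   # outside lockout
  expect_lt(pools3[["R"]], R_after / 2)
})

test_that("cleft transmitter: decay, steady state and vesicular defaults", {
  p <- syn
  ## registry carries the 60 mM Glu / 20 mM GABA vesicular concentrations
  expect_equal(p[["g_v_glu"]], 60)
  expect_equal(p[["g_v_gaba"]], 20)
  d <- cleft_transmitter_rhs(0.5, 0, E = 0, E_a = 0, p = p)
  expect_equal(d[["dg"]], -p[["g_c"]] * 0.5)
  ## constant E: steady state n_v g_v E / g_c
  E <- 0.3
  gstar <- p[["n_v"]] * p[["g_v_glu"]] * E / p[["g_c"]]
  expect_equal(cleft_transmitter_rhs(gstar, 0, E, 0, p)[["dg"]], 0)
})

test_that("G-ChI astrocyte: Hill midpoint, deterministic limit, ER link", {
  expect_equal(hill(0.7, 0.7, 1), 0.5)
  p <- syn
  ## enormous cluster: stochastic path matches the deterministic ODE
  set.seed(1)
  s1 <- c(c_a = 0.2, p_a = 0.3, h_a = 0.7)
  s2 <- s1
  for (i in 1:2000) {
    s1 <- gchi_step(s1, 0.01, 1, within(as.list(p), N_IP3 <- 1e12))
    d <- gchi_rhs(s2[["c_a"]], s2[["p_a"]], s2[["h_a"]], 0.01, p)
    s2 <- c(c_a = max(s2[["c_a"]] + d[["dc_a"]], 0),
            p_a = max(s2[["p_a"]] + d[["dp_a"]], 0),
            h_a = min(max(s2[["h_a"]] + d[["dh_a"]], 0), 1))
  }
  expect_equal(s1, s2, tolerance = 1e-4)
  ## astrocytic ER concentration stays positive below c0
  ca <- seq(0, p[["c0_a"]] - 1e-6, length.out = 50)
  expect_true(all((p[["c0_a"]] - ca) / p[["c1_a"]] > 0))
})

test_that("gchi_step parameter vector accepts list or vector", {
  ## (guard for the deterministic-limit trick above)
  p <- syn
  set.seed(2)
  s <- gchi_step(c(c_a = 0.1, p_a = 0.2, h_a = 0.8), 0, 0.5, p)
  expect_true(all(is.finite(s)))
  expect_true(s[["h_a"]] >= 0 && s[["h_a"]] <= 1)
})

test_that("IP3R channel-noise variance scales as 1/N_IP3", {
  ## frozen (c_a, p_a): h_a is an Ornstein-Uhlenbeck-like process whose
  ## stationary variance must scale as 1/N; slope -1 +- 0.1 on log-log
  p <- syn
  ca <- 0.3; pa <- 0.4
  Ns <- c(10, 100, 1000, 10000)
  vars <- vapply(Ns, function(N) {
    pN <- p; pN[["N_IP3"]] <- N
    set.seed(100 + N)
    s <- c(c_a = ca, p_a = pa, h_a = 0.6)
    h <- numeric(20000)
    for (i in seq_along(h)) {
      s <- gchi_step(s, 0, 20, pN)
      s[["c_a"]] <- ca; s[["p_a"]] <- pa
      h[i] <- s[["h_a"]]
    }
    stats::var(h[-(1:2000)])
  }, numeric(1))
  slope <- stats::coef(stats::lm(log10(vars) ~ log10(Ns)))[2]
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("gliotransmitter gates and pools behave as specified", {
  p <- syn
  ## c_a = 0: all gates decay exponentially at k_minus
  g0 <- c(0.5, 0.5, 0.5)
  out <- glio_release_step(g0, c(R_a = 1, E_a = 0), c_a = 0, dt = 100,
                           p = p)
  expect_equal(out$gates,
               0.5 * exp(-100 * c(p[["k1_minus"]], p[["k2_minus"]],
                                  p[["k3_minus"]])))
  ## at c_a equal to a gate's dissociation constant the steady open
  ## probability is 1/2
  out <- glio_release_step(c(0, 0, 0), c(R_a = 1, E_a = 0),
                           c_a = p[["Kd1_a"]], dt = 1e9, p = p)
  expect_equal(out$gates[1], 0.5, tolerance = 1e-9)
  ## below threshold the releasable pool never decreases
  pools <- c(R_a = 0.7, E_a = 0.1)
  for (i in 1:50) {
    prev <- pools[["R_a"]]
    st <- glio_release_step(c(0.9, 0.9, 0.9), pools,
                            c_a = p[["c_a_thresh"]] - 0.05, dt = 10, p = p)
    pools <- st$pools[c("R_a", "E_a")]
    expect_gte(pools[["R_a"]], prev)
    expect_equal(sum(st$pools), 1, tolerance = 1e-12)
  }
})
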