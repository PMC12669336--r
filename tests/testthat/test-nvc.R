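nvc <- nvc_params(TRUE)

test_that("KIR flux: zero driving force, fitted-line root, linearity", {
  r <- kir_flux(v_i = nvc[["z1"]] * 4 - nvc[["z2"]], K_p = 4, p = nvc)
  expect_equal(r$J_KIR, 0)
  r0 <- kir_flux(0, K_p = nvc[["z2"]] / nvc[["z1"]], p = nvc)
  expect_equal(r0$v_KIR, 0)
  ## linear in the driving force
  g <- nvc[["F_KIR"]] * nvc[["g_KIR"]] / nvc[["gamma_i"]]
  for (dv in c(-20, 5, 37)) {
    r <- kir_flux(r0$v_KIR + dv, K_p = nvc[["z2"]] / nvc[["z1"]], p = nvc)
    expect_equal(r$J_KIR, g * dv)
  }
})

test_that("heterocellular coupling is antisymmetric and relaxing", {
  J <- hetero_coupling(0.3, 0.3, -40, -40, 1, 1, nvc)
  expect_equal(unname(J), c(0, 0, 0))
  J1 <- hetero_coupling(0.5, 0.2, -30, -50, 2, 1, nvc)
  J2 <- hetero_coupling(0.2, 0.5, -50, -30, 1, 2, nvc)
  expect_equal(unname(J1), -unname(J2))
  ## isolated two-compartment calcium relaxes as exp(-2 P t)
  P <- nvc[["P_Ca"]]
  x <- c(1, 0.2); dt <- 0.5; n <- 2000
  for (i in 1:n) {
    J <- hetero_coupling(x[1], x[2], 0, 0, 0, 0, nvc)[["J_Ca_cpl"]]
    x <- x + dt * c(J, -J)
  }
  expect_equal(x[1] - x[2], 0.8 * exp(-2 * P * dt * n), tolerance = 1e-2)
  expect_equal(sum(x), 1.2, tolerance = 1e-12)
})

test_that("cross-bridge kinetics: conservation, zero-calcium state, cGMP", {
  cb <- c(M = 0.4, Mp = 0.3, AMp = 0.2, AM = 0.1)
  d <- crossbridge_rhs(cb, Ca_i = 0.3, cGMP = 2, p = nvc)
  expect_equal(sum(d), 0, tolerance = 1e-15)
  ## Ca = 0: unique steady state is fully detached free myosin
  ss <- crossbridge_steady(0, 0, nvc)
  expect_equal(unname(ss), c(1, 0, 0, 0))
  d0 <- crossbridge_rhs(c(M = 1, Mp = 0, AMp = 0, AM = 0), 0, 0, nvc)
  expect_equal(unname(d0), rep(0, 4))
  ## cGMP at the Michaelis constant halves into the regulated branch
  expect_equal(crossbridge_K2(nvc[["K_m_mlcp"]], nvc),
               nvc[["delta_i"]] * (nvc[["k_mlpc_b"]] +
                                     nvc[["k_mlpc_c"]] / 2))
  ## steady solver agrees with the ODE (long relaxation)
  ss2 <- crossbridge_steady(0.4, 1, nvc)
  cb <- c(M = 1, Mp = 0, AMp = 0, AM = 0)
  for (i in 1:400000) {
    cb <- cb + 1 * crossbridge_rhs(cb, 0.4, 1, nvc)
  }
  expect_equal(cb, ss2, tolerance = 1e-6)
})

test_that("attached fraction: normalisation endpoints and monotone rise", {
  expect_equal(attached_fraction(c(AMp = 0, AM = 0), nvc), 0)
  ss <- crossbridge_steady(nvc[["Ca_ref_max"]], 0, nvc)
  expect_equal(attached_fraction(ss, nvc), 1, tolerance = 1e-12)
  ## F_r rises monotonically to its new equilibrium after a calcium step
  cb <- crossbridge_steady(0.15, 0, nvc)
  fr_prev <- attached_fraction(cb, nvc)
  ok <- TRUE
  for (i in 1:3000) {
    cb <- cb + 10 * crossbridge_rhs(cb, 0.35, 0, nvc)
    fr <- attached_fraction(cb, nvc)
    ok <- ok && (fr >= fr_prev - 1e-12)
    fr_prev <- fr
  }
  expect_true(ok)
  expect_gt(fr_prev, attached_fraction(crossbridge_steady(0.15, 0, nvc),
                                       nvc))
})

test_that("Kelvin-Voigt wall: equilibria and interpolation endpoints", {
  p <- nvc
  w0 <- wall_interp(0, p); w1 <- wall_interp(1, p)
  expect_equal(w0$E, p[["E_pas"]]); expect_equal(w0$R0, p[["R0_pas"]])
  expect_equal(w1$E, p[["E_act"]]); expect_equal(w1$R0, p[["R0_act"]])
  ## dp = 0 at the reference radius: equilibrium
  expect_equal(wall_radius_rhs(w0$R0, 0, dp = 0, p = p), 0)
  ## steady radius R* = R0 (1 + 10 dp / E) to 1e-6 relative
  for (Fr in c(0, 0.4, 0.9)) {
    w <- wall_interp(Fr, p)
    Rstar <- w$R0 * (1 + 10 * p[["dp_wall"]] / w$E)
    R <- 15
    for (i in 1:200000) R <- R + 1 * wall_radius_rhs(R, Fr, p = p)
    expect_equal(R, Rstar, tolerance = 1e-6)
  }
})

test_that("NMDA opening probabilities and subtype weighting", {
  w <- nmda_open_prob(nvc[["K_mA"]], nvc)
  expect_equal(w[["w_NR2A"]], 0.5)
  expect_equal(unname(nmda_open_prob(0, nvc)), c(0, 0))
  glu <- seq(0, 5000, by = 100)
  wa <- vapply(glu, function(g) nmda_open_prob(g, nvc)[["w_NR2A"]],
               numeric(1))
  expect_true(all(diff(wa) > 0))
  expect_true(all(wa <= 1))
  ## weighted calcium current: NR2B/NR2A contribution ratio 11 w_B/(0.63 w_A)
  w1 <- nmda_open_prob(800, nvc)
  i1 <- nmda_calcium_current(-60, w1, nvc)
  only_a <- nmda_calcium_current(-60, c(w_NR2A = w1[["w_NR2A"]],
                                        w_NR2B = 0), nvc)
  only_b <- nmda_calcium_current(-60, c(w_NR2A = 0,
                                        w_NR2B = w1[["w_NR2B"]]), nvc)
  expect_equal(only_b$I_Ca_tot / only_a$I_Ca_tot,
               11 * w1[["w_NR2B"]] / (0.63 * w1[["w_NR2A"]]))
  expect_equal(i1$I_Ca_tot, only_a$I_Ca_tot + only_b$I_Ca_tot)
})

test_that("NO production laws: substrate limits and shear monotonicity", {
  expect_equal(no_production_neuron(0, nvc), 0)
  ## both substrates at their Michaelis constants: quarter of maximal
  p <- nvc
  p[["O2_n"]] <- p[["K_m_O2_n"]]; p[["LArg_n"]] <- p[["K_m_LArg_n"]]
  expect_equal(no_production_neuron(1, p),
               p[["V_max_NO_n"]] / 4)
  taus <- seq(0, 10, by = 0.5)
  pj <- vapply(taus, function(tw) no_production_ec(0.3, tw, nvc)$p_NO_j,
               numeric(1))
  expect_true(all(diff(pj) >= 0))
  pe <- nvc; pe[["e_base"]] <- 0; pe[["e_Ca"]] <- 0; pe[["g_wss"]] <- 0
  expect_equal(no_production_ec(0.3, 1, pe)$p_NO_j, 0)
})

test_that("NO compartment chain: equilibrium, tau arithmetic, dissipation", {
  p <- nvc
  p[["lam_NO_n"]] <- p[["lam_NO_a"]] <- p[["lam_NO_s"]] <-
    p[["lam_NO_e"]] <- 0
  NO <- c(n = 0.2, a = 0.2, s = 0.2, e = 0.2)
  expect_equal(unname(no_transport_rhs(NO, 0, 0, p)), rep(0, 4))
  ## Einstein-Smoluchowski time for 25 um at D = 3.3 um^2/ms
  expect_equal(25^2 / (2 * 3.3), 94.697, tolerance = 1e-4)
  d <- no_transport_rhs(c(n = 1, a = 0, s = 0, e = 0), 0, 0, p)
  expect_equal(d[["n"]], -1 / (p[["dx_na"]]^2 / (2 * p[["D_NO"]])))
  ## with production off, scavenging makes total NO decay monotonically
  p2 <- nvc
  NO <- c(n = 0.5, a = 0.3, s = 0.2, e = 0.1)
  tot_prev <- sum(NO)
  for (i in 1:200) {
    NO <- NO + 10 * no_transport_rhs(NO, 0, 0, p2)
    expect_lt(sum(NO), tot_prev + 1e-12)
    tot_prev <- sum(NO)
  }
})

test_that("cGMP-shifted BK opening and SR uptake", {
  r0 <- cgmp_bk_modulation(0, -40, nvc)
  expect_equal(r0$c_w, 1 / (nvc[["eps_bk"]] + nvc[["alpha_bk"]]))
  ## gamma < 0: higher cGMP -> larger c_w -> larger open probability
  cg <- seq(0, 10, by = 0.5)
  cw <- vapply(cg, function(x) cgmp_bk_modulation(x, -40, nvc)$c_w,
               numeric(1))
  wbk <- vapply(cg, function(x) cgmp_bk_modulation(x, -40, nvc)$w_BK,
                numeric(1))
  expect_true(all(diff(cw) > 0))
  expect_true(all(diff(wbk) > 0))
  ## SR uptake: zero at zero, half-max at c_bi, saturates at B_i
  expect_equal(sr_uptake(0, nvc), 0)
  expect_equal(sr_uptake(nvc[["c_bi"]], nvc), nvc[["B_i"]] / 2)
  expect_equal(sr_uptake(1e9, nvc), nvc[["B_i"]], tolerance = 1e-6)
})

test_that("qualitative coupling chain: Glu up -> astro Ca, cGMP up, F_r down, radius up", {
  syn <- calibrate_rest(synapse_params(TRUE))
  glu_levels <- c(1e-4, 5e-3, 5e-2)   # sustained cleft glutamate (mM)
  astro_ca <- cgmp_s <- fr_s <- rstar <- numeric(3)
  for (k in seq_along(glu_levels)) {
    g <- glu_levels[k]
    ## astrocyte driven to (possibly oscillatory) regime: time-average Ca
    s <- c(c_a = 0.1, p_a = 0.2, h_a = 0.8)
    cas <- numeric(4000)
    for (i in seq_along(cas)) {
      d <- gchi_rhs(s[["c_a"]], s[["p_a"]], s[["h_a"]], g, syn)
      s <- c(c_a = max(s[["c_a"]] + 20 * d[["dc_a"]], 0),
             p_a = max(s[["p_a"]] + 20 * d[["dp_a"]], 0),
             h_a = min(max(s[["h_a"]] + 20 * d[["dh_a"]], 0), 1))
      cas[i] <- s[["c_a"]]
    }
    astro_ca[k] <- mean(cas[-(1:1000)])
    ## NO pathway at fixed postsynaptic potential
    w <- nmda_open_prob(g * 1e3, nvc)
    ic <- nmda_calcium_current(-60, w, nvc)
    nNOS <- nvc[["k_act_nNOS"]] * abs(ic$I_Ca_tot) * nvc[["nNOS_tot"]] /
      (nvc[["k_act_nNOS"]] * abs(ic$I_Ca_tot) + nvc[["k_deact_nNOS"]])
    p_n <- no_production_neuron(nNOS, nvc)
    ## steady linear NO chain
    NO <- c(n = 0, a = 0, s = 0, e = 0)
    for (i in 1:40000) NO <- NO + 5 * no_transport_rhs(NO, p_n, 0, nvc)
    cgmp_s[k] <- nvc[["V_cGMP"]] * NO[["s"]] /
      (nvc[["K_NO_sGC"]] + NO[["s"]]) / nvc[["k_pde"]]
    ## wall response at fixed SMC calcium
    ss <- crossbridge_steady(0.25, cgmp_s[k], nvc)
    fr_s[k] <- attached_fraction(ss, nvc)
    w_i <- wall_interp(fr_s[k], nvc)
    rstar[k] <- w_i$R0 * (1 + 10 * nvc[["dp_wall"]] / w_i$E)
  }
  expect_true(all(diff(astro_ca) > 0))
  expect_true(all(diff(cgmp_s) > 0))
  expect_true(all(diff(fr_s) < 0))
  expect_true(all(diff(rstar) > 0))
})
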