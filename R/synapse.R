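## Quadripartite synapse (0D): presynaptic Hodgkin-Huxley spiking, bouton
## calcium (fast N-type influx + slow ER release), stochastic vesicle
## sensors, Tsodyks-Markram fusion/recycling pools, cleft/extrasynaptic
## transmitter, and stochastic astrocyte G-ChI dynamics with three-gate
## gliotransmitter release.
##
## Conventions: time in ms, voltages mV, intracellular Ca/IP3 in uM,
## transmitter concentrations in mM. Rate parameters quoted per second in
## the registry are converted on load.

#' Synapse and neurovascular parameter registry
#'
#' Returns the default parameter set as a data.frame (name, value, units,
#' source) or as a named vector of values. Sources: "paper" (printed in the
#' source model), "literature" (cited model family), "calibrated"
#' (determined at startup so that rest is a fixed point).
#'
#' @param as_vector return a named numeric vector of values.
#' @return data.frame or named numeric vector.
#' @export
synapse_params <- function(as_vector = FALSE) {
  path <- system.file("params", "synapse_defaults.csv", package = "ngvu")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (as_vector) stats::setNames(d$value, d$name) else d
}

#' Hodgkin-Huxley gate rate functions
#'
#' The six alpha/beta expressions of the squid-axon model shifted to a
#' resting potential of -70 mV; the removable 0/0 singularities of alpha_n
#' (at -60 mV) and alpha_m (at -45 mV) are replaced by their limits.
#'
#' @param V membrane potential (mV).
#' @return named list alpha_n, beta_n, alpha_m, beta_m, alpha_h, beta_h
#'   (1/ms), each vectorised over V.
#' @export
hh_rates <- function(V) {
  safe_exp_ratio <- function(a, k) {
    ## a / (exp(a/k) - 1), with limit k at a = 0
    out <- ifelse(abs(a) < 1e-7, k - a / 2, a / (exp(a / k) - 1))
    out
  }
  list(
    alpha_n = 0.01 * safe_exp_ratio(-V - 60, 10),
    beta_n  = 0.125 * exp((-V - 70) / 80),
    alpha_m = 0.1 * safe_exp_ratio(-V - 45, 10),
    beta_m  = 4 * exp((-V - 70) / 18),
    alpha_h = 0.07 * exp((-V - 70) / 20),
    beta_h  = 1 / (exp((-V - 40) / 10) + 1))
}

## right-hand side of the 4-variable HH system
hh_rhs <- function(s, I_app, p) {
  r <- hh_rates(s[["V"]])
  INa <- p[["g_Na"]] * s[["m"]]^3 * s[["h"]] * (s[["V"]] - p[["V_Na"]])
  IK <- p[["g_K"]] * s[["n"]]^4 * (s[["V"]] - p[["V_K"]])
  IL <- p[["g_L"]] * (s[["V"]] - p[["V_L"]])
  c(V = (I_app - IK - INa - IL) / p[["C_m"]],
    n = r$alpha_n * (1 - s[["n"]]) - r$beta_n * s[["n"]],
    m = r$alpha_m * (1 - s[["m"]]) - r$beta_m * s[["m"]],
    h = r$alpha_h * (1 - s[["h"]]) - r$beta_h * s[["h"]])
}

#' Advance the Hodgkin-Huxley neuron by one RK4 step
#'
#' @param state named vector (V, n, m, h).
#' @param I_app applied current density (uA/cm^2).
#' @param dt step (ms), default 0.01.
#' @param p parameter vector (see \code{\link{synapse_params}}).
#' @return updated state.
#' @export
hh_step <- function(state, I_app, dt = 0.01, p = synapse_params(TRUE)) {
  if (any(!is.finite(state))) stop("non-finite neuron state")
  k1 <- hh_rhs(state, I_app, p)
  k2 <- hh_rhs(state + dt / 2 * k1, I_app, p)
  k3 <- hh_rhs(state + dt / 2 * k2, I_app, p)
  k4 <- hh_rhs(state + dt * k3, I_app, p)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Resting Hodgkin-Huxley state
#' @param p parameter vector.
#' @param V resting potential (mV).
#' @return named state vector with gates at their steady-state values.
#' @export
hh_rest_state <- function(p = synapse_params(TRUE), V = -70) {
  r <- hh_rates(V)
  c(V = V, n = r$alpha_n / (r$alpha_n + r$beta_n),
    m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Nernst reversal potential
#'
#' (R_gas T / z F) ln(c_out/c_in), returned in mV.
#'
#' @param c_out,c_in outer/inner concentrations (> 0, same unit).
#' @param T_K absolute temperature (K); @param z ion valence.
#' @export
nernst_potential <- function(c_out, c_in, T_K = 300, z = 2) {
  if (any(c_out <= 0) || any(c_in <= 0)) stop("concentrations must be > 0")
  1e3 * ngvu_constants$R_gas * T_K / (z * ngvu_constants$F_const) *
    log(c_out / c_in)
}

#' N-type calcium channel
#'
#' Boltzmann steady state m_inf = 1/(1+exp((V_mCa - V)/k_mCa)), first-order
#' relaxation with time constant tau_mCa, and single-protein current
#' I_Ca = rho_Ca m_Ca^2 g_Ca (V - V_Ca) (fA/um^2).
#'
#' @param m_Ca current gate value; @param V_pre membrane potential (mV).
#' @param dt step (ms); @param p parameter vector.
#' @return list(m_Ca, I_Ca).
#' @export
ntype_channel <- function(m_Ca, V_pre, dt, p = synapse_params(TRUE)) {
  m_inf <- 1 / (1 + exp((p[["V_mCa"]] - V_pre) / p[["k_mCa"]]))
  m_new <- m_inf + (m_Ca - m_inf) * exp(-dt / p[["tau_mCa"]])
  V_Ca <- nernst_potential(p[["c_ext"]], p[["c_i_rest"]])
  I <- p[["rho_Ca"]] * m_new^2 * p[["g_Ca"]] * (V_pre - V_Ca)
  list(m_Ca = m_new, I_Ca = I)
}

## conversion from a membrane current density (fA/um^2) on the bouton
## surface to a cytosolic concentration rate (uM/ms)
current_to_flux <- function(I, p) {
  ## total current I*A_btn [fA = 1e-15 C/s] over z F gives mol/s; dividing
  ## by the bouton volume [1 um^3 = 1e-15 L] cancels the 1e-15; the factor
  ## 1e3 converts M/s to uM/ms.
  I * p[["A_btn"]] / (2 * ngvu_constants$F_const * p[["V_btn"]]) * 1e3
}

#' Fast bouton calcium balance
#'
#' dc_fast/dt = -I_Ca A/(zFV) + v_leak (c_ext - c_i)
#'              - I_PMCA(c_i) A/(zFV), with the PMCA current following
#' Michaelis-Menten kinetics v_PM c^2/(c^2 + K^2).
#'
#' @param c_i total bouton calcium (uM); @param I_Ca N-type current
#'   density (fA/um^2); @param p parameter vector.
#' @return dc_fast/dt (uM/ms).
#' @export
fast_calcium_rhs <- function(c_i, I_Ca, p = synapse_params(TRUE)) {
  I_pmca <- p[["v_PM_Ca"]] * c_i^2 / (c_i^2 + p[["K_PM_Ca"]]^2)
  -current_to_flux(I_Ca, p) + p[["v_leak"]] * (p[["c_ext"]] - c_i) -
    current_to_flux(I_pmca, p)
}

#' Calibrate the PMCA ceiling so that rest is a fixed point
#'
#' Solves v_PM_Ca from fast_calcium_rhs = 0 at (c_i_rest, I_Ca at rest).
#'
#' @param p parameter vector; @param V_rest resting potential.
#' @return updated parameter vector with calibrated \code{v_PM_Ca}.
#' @export
calibrate_rest <- function(p = synapse_params(TRUE), V_rest = -70) {
  m_inf <- 1 / (1 + exp((p[["V_mCa"]] - V_rest) / p[["k_mCa"]]))
  V_Ca <- nernst_potential(p[["c_ext"]], p[["c_i_rest"]])
  I_rest <- p[["rho_Ca"]] * m_inf^2 * p[["g_Ca"]] * (V_rest - V_Ca)
  cr <- p[["c_i_rest"]]
  mm <- cr^2 / (cr^2 + p[["K_PM_Ca"]]^2)
  ## -flux(I_rest) + v_leak (c_ext - cr) = flux(v_PM * mm)
  lhs <- -current_to_flux(I_rest, p) + p[["v_leak"]] * (p[["c_ext"]] - cr)
  fac <- current_to_flux(1, p) * mm
  p[["v_PM_Ca"]] <- lhs / fac
  ## v3 (SERCA ceiling) from the slow-pool rest balance
  q_rest <- with(as.list(p), {
    aq <- a2 * d2 * (p0 + d1) / (p0 + d3); bq <- a2 * cr
    aq / (aq + bq)
  })
  m_inf_s <- p[["p0"]] / (p[["p0"]] + p[["d1"]])
  n_inf_s <- cr / (cr + p[["d5"]])
  gate <- (m_inf_s * n_inf_s * q_rest)^3
  dCa <- cr - p[["c_ER0"]]
  Jchan <- p[["c1_er"]] * p[["v1"]] * gate * dCa
  Jleak <- p[["c1_er"]] * p[["v2"]] * dCa
  p[["v3"]] <- -(Jchan + Jleak) * (cr^2 + p[["k3"]]^2) / cr^2
  p
}

#' Slow (ER-driven) bouton calcium subsystem
#'
#' Right-hand sides for (c_slow, c_ER, p_IP3, q): IP3-receptor channel flux
#' J_chan = c1 v1 m_inf^3 n_inf^3 q^3 (c_i - c_ER), SERCA pump
#' J_pump = v3 c_i^2/(k3^2 + c_i^2), leak J_leak = c1 v2 (c_i - c_ER);
#' dc_ER/dt = -(1/c1) dc_slow/dt; IP3 production driven by extrasynaptic
#' glutamate with a 0.3-order Hill term and linear decay tau_p (p - p0);
#' q follows alpha_q (1-q) - beta_q q with alpha_q = a2 d2 (p+d1)/(p+d3),
#' beta_q = a2 c_i.
#'
#' @param c_i total calcium (uM); @param c_ER ER calcium (uM);
#' @param p_ip3 bouton IP3 (uM); @param q IP3R activation in [0,1];
#' @param g_a extrasynaptic glutamate (mM); @param p parameter vector.
#' @return named vector of derivatives (dc_slow, dc_ER, dp, dq) per ms.
#' @export
slow_calcium_rhs <- function(c_i, c_ER, p_ip3, q, g_a,
                             p = synapse_params(TRUE)) {
  m_inf <- p_ip3 / (p_ip3 + p[["d1"]])
  n_inf <- c_i / (c_i + p[["d5"]])
  J_chan <- p[["c1_er"]] * p[["v1"]] * (m_inf * n_inf * q)^3 * (c_i - c_ER)
  J_pump <- p[["v3"]] * c_i^2 / (p[["k3"]]^2 + c_i^2)
  J_leak <- p[["c1_er"]] * p[["v2"]] * (c_i - c_ER)
  dcs <- -J_chan - J_pump - J_leak
  ga03 <- max(g_a, 0)^0.3
  dp <- p[["v_g"]] * ga03 / (p[["k_g"]]^0.3 + ga03) -
    p[["tau_p"]] * (p_ip3 - p[["p0"]])
  aq <- p[["a2"]] * p[["d2"]] * (p_ip3 + p[["d1"]]) / (p_ip3 + p[["d3"]])
  bq <- p[["a2"]] * c_i
  c(dc_slow = dcs, dc_ER = -dcs / p[["c1_er"]],
    dp = dp, dq = aq * (1 - q) - bq * q)
}

## ---- stochastic vesicle sensor (5 binding sites + isomerisation) --------

#' Sensor transition rates
#'
#' 7-state chain: X0..X5 (number of bound calcium ions) and the isomerised
#' release-ready state X5*. Forward binding (5-k) alpha c_i from state k,
#' unbinding (k) beta, isomerisation gamma / delta.
#'
#' @param c_i calcium (uM); @param p parameter vector.
#' @return 7x7 generator matrix Q (1/ms), rows = from-state.
#' @export
sensor_generator <- function(c_i, p = synapse_params(TRUE)) {
  a <- p[["alpha_s"]] * c_i; b <- p[["beta_s"]]
  Q <- matrix(0, 7, 7)
  for (k in 0:4) {
    Q[k + 1, k + 2] <- (5 - k) * a
    Q[k + 2, k + 1] <- (k + 1) * b
  }
  Q[6, 7] <- p[["gamma_s"]]
  Q[7, 6] <- p[["delta_s"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact stochastic step of the vesicle sensors
#'
#' Advances each docked vesicle's sensor through the 7-state chain by the
#' Gillespie algorithm over a window dt at (frozen) calcium c_i. A vesicle
#' whose sensor reaches the isomerised state X5* while outside the
#' refractory window releases: its sensor resets to the unbound state and
#' the release fraction f_r accumulates 1/n_vesicles per event.
#'
#' @param states integer vector in 1..7, one per docked vesicle.
#' @param c_i calcium (uM); @param dt window (ms);
#' @param lockout logical vector, TRUE while refractory;
#' @param p parameter vector.
#' @return list(states, n_released).
#' @export
sensor_step <- function(states, c_i, dt, lockout = rep(FALSE, length(states)),
                        p = synapse_params(TRUE)) {
  Q <- sensor_generator(c_i, p)
  n_rel <- 0L
  for (v in seq_along(states)) {
    t <- 0; s <- states[v]
    repeat {
      rates <- Q[s, ]; rates[s] <- 0
      tot <- sum(rates)
      if (tot <= 0) break
      t <- t + stats::rexp(1, tot)
      if (t > dt) break
      s <- sample.int(7, 1, prob = rates / tot)
      if (s == 7L && !lockout[v]) {
        n_rel <- n_rel + 1L
        s <- 1L
      }
    }
    states[v] <- s
  }
  list(states = states, n_released = n_rel)
}

#' Spontaneous release rate
#'
#' lambda(c_i) = a3 / (1 + exp((a1 - c_i)/a2)); sigmoidal in calcium,
#' saturating at a3.
#'
#' @param c_i calcium (uM); @param a1 midpoint (uM); @param a2 slope (uM);
#' @param a3 ceiling rate (1/ms).
#' @export
spontaneous_rate <- function(c_i, a1, a2, a3) {
  stopifnot(a2 != 0)
  a3 / (1 + exp((a1 - c_i) / a2))
}

#' Tsodyks-Markram vesicle pools
#'
#' Continuous recovery/inactivation dR/dt = I/tau_rec, dE/dt = -E/tau_inact
#' with I = 1 - R - E; a release of fraction f_r moves f_r R from the
#' releasable to the effective pool instantaneously and starts the
#' transmitter-specific refractory window (6.34 ms Glu, 7.2 ms GABA).
#'
#' @param pools named vector (R, E, t_last_release).
#' @param f_r release fraction in {0, 0.5, 1} applied at the start of the
#'   step (ignored while refractory).
#' @param dt step (ms); @param t current time (ms);
#' @param tau_rec,tau_inact,lockout time constants (ms).
#' @return updated pools (with \code{I} entry).
#' @export
tm_pool_step <- function(pools, f_r, dt, t = 0, tau_rec = 800,
                         tau_inact = 3, lockout = 6.34) {
  R <- pools[["R"]]; E <- pools[["E"]]
  tl <- pools[["t_last_release"]]
  if (f_r > 0 && (t - tl) >= lockout) {
    rel <- f_r * R
    R <- R - rel; E <- E + rel
    tl <- t
  }
  I <- 1 - R - E
  R <- R + dt * I / tau_rec
  E <- E * exp(-dt / tau_inact)
  c(R = R, E = E, I = 1 - R - E, t_last_release = tl)
}

#' Cleft / extrasynaptic transmitter balance
#'
#' dg/dt = n_v g_v E - g_c g for the synaptic cleft and the analogous
#' equation for the extrasynaptic pool driven by the astrocytic effective
#' fraction E_a.
#'
#' @param g,g_a concentrations (mM); @param E,E_a effective pool fractions;
#' @param p parameter vector; @param transmitter "glu" or "gaba" (selects
#'   the vesicular concentration, 60 mM Glu / 20 mM GABA).
#' @return c(dg, dg_a) in mM/ms.
#' @export
cleft_transmitter_rhs <- function(g, g_a, E, E_a,
                                  p = synapse_params(TRUE),
                                  transmitter = c("glu", "gaba")) {
  transmitter <- match.arg(transmitter)
  gv <- if (transmitter == "glu") p[["g_v_glu"]] else p[["g_v_gaba"]]
  gav <- if (transmitter == "glu") p[["g_av_glu"]] else p[["g_av_gaba"]]
  c(dg = p[["n_v"]] * gv * E - p[["g_c"]] * g,
    dg_a = p[["n_av"]] * gav * E_a - p[["g_ac"]] * g_a)
}

#' Generic Hill function
#'
#' Hill(x^n, K) = x^n / (x^n + K^n).
#'
#' @param x argument (>= 0); @param K half-saturation; @param n exponent.
#' @export
hill <- function(x, K, n = 1) {
  xn <- pmax(x, 0)^n
  xn / (xn + K^n)
}

#' Astrocyte G-ChI right-hand sides (deterministic part)
#'
#' dc_a/dt = (r_Ca m_inf^3 n_inf^3 h^3)(c0 - (1+c1a) c_a)
#'           - v_ER Hill(c_a^2, K_ER) + r_L (c0 - (1+c1a) c_a);
#' dp_a/dt: agonist-driven PLCbeta term (0.9-order Hill in cleft
#' glutamate with calcium-dependent inhibition), PLCdelta production,
#' IP3-3K and IP3-5P degradation;
#' dh_a/dt = alpha_h (1-h) - beta_h h (noise added separately).
#'
#' @param c_a,p_a,h_a state (uM, uM, -); @param g cleft glutamate (mM);
#' @param p parameter vector.
#' @return named derivative vector (per ms).
#' @export
gchi_rhs <- function(c_a, p_a, h_a, g, p = synapse_params(TRUE)) {
  m_inf <- hill(p_a, p[["d1"]])
  n_inf <- hill(c_a, p[["d5"]])
  drive <- p[["c0_a"]] - (1 + p[["c1_a"]]) * c_a
  dca <- (p[["r_Ca"]] * (m_inf * n_inf * h_a)^3) * drive -
    p[["v_ER_a"]] * hill(c_a, p[["K_ER_a"]], 2) + p[["r_L"]] * drive
  g_uM <- max(g, 0) * 1e3
  Kr_eff <- p[["K_R"]] * (1 + p[["K_p_a"]] / p[["K_R"]] *
                            hill(c_a, p[["K_pi"]]))
  dpa <- p[["v_beta"]] * hill(g_uM, Kr_eff, 0.9) +
    p[["v_delta"]] / (1 + p_a / p[["k_delta"]]) *
      hill(c_a, p[["K_PLCdelta"]], 2) -
    p[["v_3K"]] * hill(c_a, p[["K_D"]], 4) * hill(p_a, p[["K_3"]]) -
    p[["r_5P"]] * p_a
  ah <- p[["a2"]] * p[["d2"]] * (p_a + p[["d1"]]) / (p_a + p[["d3"]])
  bh <- p[["a2"]] * c_a
  c(dc_a = dca, dp_a = dpa, dh_a = ah * (1 - h_a) - bh * h_a,
    alpha_h = ah, beta_h = bh)
}

#' One Euler-Maruyama step of the stochastic G-ChI model
#'
#' The IP3R gating variable h_a carries channel noise with variance
#' (alpha_h (1-h) + beta_h h)/N_IP3 per unit time (cluster size N_IP3,
#' default 20); h_a is projected back into [0,1] after the noise kick.
#'
#' @param state named vector (c_a, p_a, h_a); @param g cleft glutamate
#'   (mM); @param dt step (ms); @param p parameter vector.
#' @return updated state.
#' @export
gchi_step <- function(state, g, dt, p = synapse_params(TRUE)) {
  d <- gchi_rhs(state[["c_a"]], state[["p_a"]], state[["h_a"]], g, p)
  h <- state[["h_a"]] + dt * d[["dh_a"]] +
    sqrt(pmax(d[["alpha_h"]] * (1 - state[["h_a"]]) +
                d[["beta_h"]] * state[["h_a"]], 0) * dt / p[["N_IP3"]]) *
      stats::rnorm(1)
  c(c_a = max(state[["c_a"]] + dt * d[["dc_a"]], 0),
    p_a = max(state[["p_a"]] + dt * d[["dp_a"]], 0),
    h_a = min(max(h, 0), 1))
}

#' Gliotransmitter release gates and pools
#'
#' Three independent calcium gates dO_j/dt = k_j+ c_a - (k_j+ c_a + k_j-)
#' O_j with dissociation constants 108/400/800 nM and closure time
#' constants 2.5 s / 1 s / 100 ms; release readiness f_r^a = O1 O2 O3;
#' Tsodyks-Markram pool update gated by Theta(c_a - c_a_thresh).
#'
#' @param gates numeric length 3 in [0,1]; @param pools named vector
#'   (R_a, E_a); @param c_a astrocyte calcium (uM); @param dt step (ms);
#' @param p parameter vector.
#' @return list(gates, pools (with I_a), f_r_a).
#' @export
glio_release_step <- function(gates, pools, c_a, dt,
                              p = synapse_params(TRUE)) {
  kminus <- c(p[["k1_minus"]], p[["k2_minus"]], p[["k3_minus"]])
  Kd <- c(p[["Kd1_a"]], p[["Kd2_a"]], p[["Kd3_a"]])
  kplus <- kminus / Kd
  o_inf <- kplus * c_a / (kplus * c_a + kminus)
  tau <- 1 / (kplus * c_a + kminus)
  gates <- o_inf + (gates - o_inf) * exp(-dt / tau)
  f_r_a <- prod(gates)
  theta <- as.numeric(c_a > p[["c_a_thresh"]])
  R <- pools[["R_a"]]; E <- pools[["E_a"]]
  I <- 1 - R - E
  dR <- I / p[["tau_rec_a"]] - theta * p[["k_rel_a"]] * f_r_a * R
  dE <- -E / p[["tau_inact_a"]] + theta * p[["k_rel_a"]] * f_r_a * R
  pools <- c(R_a = R + dt * dR, E_a = E + dt * dE)
  pools <- c(pools, I_a = 1 - pools[["R_a"]] - pools[["E_a"]])
  list(gates = gates, pools = pools, f_r_a = f_r_a)
}
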