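## Neurovascular coupling: KIR input, SMC/EC heterocellular exchange,
## Hai-Murphy cross-bridge kinetics with cGMP modulation, Kelvin-Voigt wall
## mechanics and the NO production/diffusion/consumption pathway.
## Conventions: time ms, Ca/IP3/NO/cGMP uM, voltages mV, radius um,
## pressure and moduli Pa.

#' Neurovascular-coupling parameter registry
#'
#' Defaults for the smooth-muscle/endothelial, cross-bridge, wall and NO
#' subsystems, provenance-tagged like \code{\link{synapse_params}}.
#'
#' @param as_vector return a named numeric vector.
#' @export
nvc_params <- function(as_vector = FALSE) {
  path <- system.file("params", "nvc_defaults.csv", package = "ngvu")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (as_vector) stats::setNames(d$value, d$name) else d
}

#' KIR channel flux
#'
#' J_KIR = (F_KIR g_KIR / gamma_i) (v_i - v_KIR) with the fitted Nernst
#' potential v_KIR = z1 K_p - z2 (mV); K_p is the perivascular potassium
#' concentration in mM.
#'
#' @param v_i SMC membrane potential (mV); @param K_p perivascular K+ (mM).
#' @param p parameter vector from \code{nvc_params(TRUE)}.
#' @return list(J_KIR, v_KIR); J_KIR in mV/ms.
#' @export
kir_flux <- function(v_i, K_p, p = nvc_params(TRUE)) {
  v_kir <- p[["z1"]] * K_p - p[["z2"]]
  list(J_KIR = p[["F_KIR"]] * p[["g_KIR"]] / p[["gamma_i"]] * (v_i - v_kir),
       v_KIR = v_kir)
}

#' Heterocellular SMC/EC coupling fluxes
#'
#' Linearised exchange -P (x_i - x_j) for calcium, voltage and IP3; the
#' flux into compartment i equals minus the flux into j.
#'
#' @param Ca_i,Ca_j,v_i,v_j,IP3_i,IP3_j compartment states (i = SMC,
#'   j = EC).
#' @param p parameter vector.
#' @return named vector (J_Ca_cpl, J_V_cpl, J_IP3_cpl): fluxes into i.
#' @export
hetero_coupling <- function(Ca_i, Ca_j, v_i, v_j, IP3_i, IP3_j,
                            p = nvc_params(TRUE)) {
  c(J_Ca_cpl = -p[["P_Ca"]] * (Ca_i - Ca_j),
    J_V_cpl = -p[["G_v"]] * (v_i - v_j),
    J_IP3_cpl = -p[["P_IP3"]] * (IP3_i - IP3_j))
}

#' Hai-Murphy cross-bridge kinetics
#'
#' Four myosin states: free (M), phosphorylated (Mp), attached
#' phosphorylated (AMp), attached latch (AM). Phosphorylation rates
#' K1 = K6 = gamma_cross Ca_i^3; dephosphorylation rates K2 = K5 follow
#' the cGMP-regulated myosin light-chain phosphatase law
#' delta_i (k_mlpc_b + k_mlpc_c R_cGMP), R_cGMP = cGMP^2/(K_m^2 + cGMP^2).
#'
#' @param cb named vector (M, Mp, AMp, AM).
#' @param Ca_i SMC calcium (uM); @param cGMP (uM); @param p parameters.
#' @return named derivative vector (per ms); the four sum to zero.
#' @export
crossbridge_rhs <- function(cb, Ca_i, cGMP, p = nvc_params(TRUE)) {
  K1 <- p[["gamma_cross"]] * Ca_i^3
  K2 <- crossbridge_K2(cGMP, p)
  K3 <- p[["K3_cb"]]; K4 <- p[["K4_cb"]]; K7 <- p[["K7_cb"]]
  M <- cb[["M"]]; Mp <- cb[["Mp"]]; AMp <- cb[["AMp"]]; AM <- cb[["AM"]]
  dMp  <- K4 * AMp + K1 * M - (K2 + K3) * Mp
  dAMp <- K3 * Mp + K1 * AM - (K4 + K2) * AMp   # K5 = K2, K6 = K1
  dAM  <- K2 * AMp - (K7 + K1) * AM
  c(M = -(dMp + dAMp + dAM), Mp = dMp, AMp = dAMp, AM = dAM)
}

#' @rdname crossbridge_rhs
#' @export
crossbridge_K2 <- function(cGMP, p = nvc_params(TRUE)) {
  R_cGMP <- cGMP^2 / (p[["K_m_mlcp"]]^2 + cGMP^2)
  p[["delta_i"]] * (p[["k_mlpc_b"]] + p[["k_mlpc_c"]] * R_cGMP)
}

#' Steady cross-bridge state at fixed calcium and cGMP
#'
#' Solves the linear 3x3 steady system (with M = 1 - Mp - AMp - AM).
#' Used both for initial conditions and for the normalisation constant
#' (AMp+AM)_max at the reference high-calcium level.
#'
#' @inheritParams crossbridge_rhs
#' @return named vector (M, Mp, AMp, AM).
#' @export
crossbridge_steady <- function(Ca_i, cGMP = 0, p = nvc_params(TRUE)) {
  K1 <- p[["gamma_cross"]] * Ca_i^3
  K2 <- crossbridge_K2(cGMP, p)
  K3 <- p[["K3_cb"]]; K4 <- p[["K4_cb"]]; K7 <- p[["K7_cb"]]
  if (K1 == 0) return(c(M = 1, Mp = 0, AMp = 0, AM = 0))
  ## unknowns (Mp, AMp, AM)
  A <- rbind(c(-(K2 + K3) - K1, K4 - K1, -K1),
             c(K3, -(K4 + K2), K1),
             c(0, K2, -(K7 + K1)))
  b <- c(-K1, 0, 0)
  x <- solve(A, b)
  c(M = 1 - sum(x), Mp = x[1], AMp = x[2], AM = x[3])
}

#' Fraction of attached cross-bridges
#'
#' F_r = (AMp + AM) / (AMp + AM)_max. The normalisation is the steady-state
#' attached fraction at the reference calcium level Ca_ref_max (cGMP = 0).
#'
#' @param cb named vector with AMp, AM.
#' @param p parameters; @param norm optional precomputed normalisation.
#' @export
attached_fraction <- function(cb, p = nvc_params(TRUE), norm = NULL) {
  if (is.null(norm)) {
    ss <- crossbridge_steady(p[["Ca_ref_max"]], 0, p)
    norm <- ss[["AMp"]] + ss[["AM"]]
  }
  stopifnot(norm > 0)
  (cb[["AMp"]] + cb[["AM"]]) / norm
}

#' Interpolated wall modulus and reference radius
#'
#' E(F_r) = E_pas + F_r (E_act - E_pas);
#' R0(F_r) = R0_pas + F_r (R0_act - R0_pas).
#'
#' @param F_r attached fraction in [0, 1]; @param p parameters.
#' @return list(E, R0).
#' @export
wall_interp <- function(F_r, p = nvc_params(TRUE)) {
  list(E = p[["E_pas"]] + F_r * (p[["E_act"]] - p[["E_pas"]]),
       R0 = p[["R0_pas"]] + F_r * (p[["R0_act"]] - p[["R0_pas"]]))
}

#' Kelvin-Voigt wall radius dynamics
#'
#' dR/dt = (R0_pas/eta) (R dp / h - E(F_r) (R - R0(F_r))/R0(F_r)) with
#' wall thickness h = 0.1 R, so the pressure term is the constant 10 dp.
#'
#' @param R radius (um); @param F_r attached fraction; @param dp
#'   transmural pressure (Pa; default from the registry); @param p
#'   parameters.
#' @return dR/dt in um/ms.
#' @export
wall_radius_rhs <- function(R, F_r, dp = NULL, p = nvc_params(TRUE)) {
  stopifnot(p[["eta_wall"]] > 0)
  if (is.null(dp)) dp <- p[["dp_wall"]]
  w <- wall_interp(F_r, p)
  (p[["R0_pas"]] / p[["eta_wall"]]) *
    (10 * dp - w$E * (R - w$R0) / w$R0) * 1e-3   # per ms
}

#' NMDA receptor opening probabilities
#'
#' Michaelis-Menten opening w = Glu/(K_m + Glu) for the NR2A and NR2B
#' subtypes.
#'
#' @param Glu_sc synaptic-cleft glutamate (uM).
#' @param p parameters (K_mA, K_mB in uM).
#' @return named vector (w_NR2A, w_NR2B).
#' @export
nmda_open_prob <- function(Glu_sc, p = nvc_params(TRUE)) {
  stopifnot(all(Glu_sc >= 0))
  c(w_NR2A = Glu_sc / (p[["K_mA"]] + Glu_sc),
    w_NR2B = Glu_sc / (p[["K_mB"]] + Glu_sc))
}

#' NMDA calcium current and subtype-weighted total
#'
#' I_Ca = 4 v G_M (P_Ca/P_M) ([Ca]_ex/[M]) / (1 + exp(alpha_v (v + beta_v)))
#'        * exp(2vF/RT) / (1 - exp(2vF/RT));
#' I_Ca_tot = I_Ca (0.63 w_NR2A + 11 w_NR2B).
#'
#' @param v_n postsynaptic membrane potential (mV); @param w named vector
#'   from \code{\link{nmda_open_prob}}; @param p parameters;
#' @param T_K temperature.
#' @return list(I_Ca, I_Ca_tot).
#' @export
nmda_calcium_current <- function(v_n, w, p = nvc_params(TRUE), T_K = 300) {
  vf <- 2 * (v_n * 1e-3) * ngvu_constants$F_const /
    (ngvu_constants$R_gas * T_K)
  ex <- exp(vf)
  I <- 4 * v_n * p[["G_M"]] * p[["PCa_PM"]] *
    (p[["Ca_ex_nmda"]] / p[["M_mono"]]) /
    (1 + exp(p[["alpha_v_nmda"]] * (v_n + p[["beta_v_nmda"]]))) *
    ex / (1 - ex)
  list(I_Ca = I,
       I_Ca_tot = I * (0.63 * w[["w_NR2A"]] + 11 * w[["w_NR2B"]]))
}

#' Neuronal NO production rate
#'
#' p_NO,n = V_max,NO,n [nNOS_act] * MM(O2) * MM(L-Arg) (uM/ms).
#'
#' @param nNOS_act activated nNOS concentration (uM); @param p parameters.
#' @export
no_production_neuron <- function(nNOS_act, p = nvc_params(TRUE)) {
  p[["V_max_NO_n"]] * nNOS_act *
    p[["O2_n"]] / (p[["K_m_O2_n"]] + p[["O2_n"]]) *
    p[["LArg_n"]] / (p[["K_m_LArg_n"]] + p[["LArg_n"]])
}

#' Endothelial NO production rate
#'
#' p_NO,j = V_max,NO,j [eNOS_act] * MM(O2) * MM(L-Arg); eNOS activation
#' combines a calcium-dependent part and a wall-shear-stress part (simple
#' saturating law behind this interface).
#'
#' @param Ca_j EC calcium (uM); @param tau_wss wall shear stress (Pa);
#' @param p parameters.
#' @return list(p_NO_j, eNOS_act).
#' @export
no_production_ec <- function(Ca_j, tau_wss, p = nvc_params(TRUE)) {
  eNOS <- p[["e_base"]] + p[["e_Ca"]] * hill(Ca_j, p[["K_eCa"]], 2) +
    p[["g_wss"]] * tau_wss / (tau_wss + p[["K_wss"]])
  list(p_NO_j = p[["V_max_NO_j"]] * eNOS *
         p[["O2_j"]] / (p[["K_m_O2_j"]] + p[["O2_j"]]) *
         p[["LArg_j"]] / (p[["K_m_LArg_j"]] + p[["LArg_j"]]),
       eNOS_act = eNOS)
}

#' Hagen-Poiseuille wall shear stress
#'
#' tau = 4 mu Q / (pi R^3) on the coupled vessel.
#'
#' @param Q flow (cm^3/s); @param R_um radius (um); @param mu viscosity
#'   (Pa s).
#' @return shear stress (Pa).
#' @export
wall_shear_stress <- function(Q, R_um, mu = 3.5e-3) {
  4 * mu * (Q * 1e-6) / (pi * (R_um * 1e-6)^3)   # Q m^3/s, R m
}

#' NO compartment transport
#'
#' Linear diffusion chain neuron <-> astrocyte <-> SMC <-> EC with
#' Einstein-Smoluchowski times tau = dx^2/(2 D), first-order scavenging
#' lambda_m [NO]_m, and production only in the neuron and EC compartments.
#'
#' @param NO named vector (n, a, s, e) of concentrations (uM).
#' @param p_n,p_e production rates (uM/ms); @param p parameters.
#' @return named derivative vector (uM/ms).
#' @export
no_transport_rhs <- function(NO, p_n = 0, p_e = 0, p = nvc_params(TRUE)) {
  tau_na <- p[["dx_na"]]^2 / (2 * p[["D_NO"]])
  tau_as <- p[["dx_as"]]^2 / (2 * p[["D_NO"]])
  tau_se <- p[["dx_se"]]^2 / (2 * p[["D_NO"]])
  c(n = p_n + (NO[["a"]] - NO[["n"]]) / tau_na - p[["lam_NO_n"]] * NO[["n"]],
    a = (NO[["n"]] - NO[["a"]]) / tau_na + (NO[["s"]] - NO[["a"]]) / tau_as -
      p[["lam_NO_a"]] * NO[["a"]],
    s = (NO[["a"]] - NO[["s"]]) / tau_as + (NO[["e"]] - NO[["s"]]) / tau_se -
      p[["lam_NO_s"]] * NO[["s"]],
    e = p_e + (NO[["s"]] - NO[["e"]]) / tau_se - p[["lam_NO_e"]] * NO[["e"]])
}

#' cGMP-dependent BK-channel modulation
#'
#' c_w,i = 1/(eps_i + alpha_i exp(gamma_i cGMP)) acts as a leftward shift
#' of the BK activation curve in voltage space (gamma_i < 0 by default so
#' that higher cGMP increases the shift, promoting BK opening and
#' hyperpolarisation).
#'
#' @param cGMP (uM); @param v_i SMC potential (mV); @param p parameters.
#' @return list(c_w, w_BK).
#' @export
cgmp_bk_modulation <- function(cGMP, v_i, p = nvc_params(TRUE)) {
  den <- p[["eps_bk"]] + p[["alpha_bk"]] * exp(p[["gamma_bk"]] * cGMP)
  stopifnot(all(den > 0))
  c_w <- 1 / den
  w <- 0.5 * (1 + tanh((v_i - p[["v3_BK"]] + p[["s_BK"]] * c_w) /
                         p[["v4_BK"]]))
  list(c_w = c_w, w_BK = w)
}

#' Sarcoplasmic-reticulum uptake flux
#'
#' J_SR = B_i Ca^2 / (c_bi^2 + Ca^2); in the coupled model the driving
#' calcium is the astrocytic concentration (the astrocyte-to-SMC conduit).
#'
#' @param Ca driving calcium (uM); @param p parameters.
#' @return flux (uM/ms).
#' @export
sr_uptake <- function(Ca, p = nvc_params(TRUE)) {
  p[["B_i"]] * Ca^2 / (p[["c_bi"]]^2 + Ca^2)
}
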