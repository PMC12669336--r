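## Driver for the coupled 0D cellular chain (quadripartite synapse +
## neurovascular coupling + wall mechanics).

#' Simulate the coupled 0D cellular chain
#'
#' Integrates the full cellular cascade: presynaptic Glu and GABA neurons
#' (Hodgkin-Huxley), bouton calcium, stochastic vesicle release,
#' cleft/extrasynaptic transmitter, stochastic astrocyte G-ChI dynamics and
#' gliotransmission, postsynaptic potential, NO/cGMP pathway, SMC/EC
#' exchange, Hai-Murphy cross-bridges and the Kelvin-Voigt vessel radius.
#'
#' Deterministic sub-systems advance with fixed steps (RK4 at
#' \code{dt_fast_ms} for the neurons, explicit updates at 10 x
#' \code{dt_fast_ms} for the slow block); vesicle sensors use an exact
#' Gillespie simulation and the astrocytic IP3R gate carries 1/N_IP3
#' channel noise (Euler-Maruyama). All randomness is drawn from R's RNG,
#' so \code{set.seed()} gives reproducible traces.
#'
#' @param t_end_s simulated time (s).
#' @param dt_fast_ms fast step (ms), default 0.01.
#' @param sample_ms output sampling interval (ms), default 1.
#' @param stochastic enable sensor/release/gate noise (default TRUE).
#' @param N_IP3 astrocytic IP3R cluster size (default from registry).
#' @param syn,nvc parameter vectors (defaults: calibrated registries).
#' @param seed optional RNG seed set before the run.
#' @return data.frame trace, one row per sample, with an attribute
#'   \code{Fr_norm} (cross-bridge normalisation used).
#' @export
simulate_ngvu_cell <- function(t_end_s = 60, dt_fast_ms = 0.01,
                               sample_ms = 1, stochastic = TRUE,
                               N_IP3 = NULL,
                               syn = calibrate_rest(synapse_params(TRUE)),
                               nvc = nvc_params(TRUE), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(N_IP3)) N_IP3 <- syn[["N_IP3"]]
  ctrl <- list(t_end_ms = t_end_s * 1e3, dt_fast_ms = dt_fast_ms,
               slow_every = 10L, sample_ms = sample_ms,
               stochastic = stochastic, N_IP3 = N_IP3)
  res <- .cell_chain_run(syn, nvc, ctrl)
  d <- as.data.frame(res$trace)
  names(d) <- as.character(res$cols)
  attr(d, "Fr_norm") <- res$Fr_norm
  d
}

#' Frozen-drive wall mechanics runner
#'
#' Integrates only the Hai-Murphy cross-bridge and Kelvin-Voigt wall
#' sub-system, driven by prescribed periodic SMC calcium and cGMP traces.
#' This is the default model runner of the sensitivity module: parameter
#' draws then differ only through the wall mechanics, with the cellular
#' drive frozen (the documented scaled-down protocol).
#'
#' @param dp,E_act,E_pas wall parameters (Pa); defaults from the registry.
#' @param t_end_s simulated time (default 60 s).
#' @param drive list with \code{ca}, \code{cg} (uM, sampled over one
#'   period) and \code{dt_ms}; default a 10-s period oscillation emulating
#'   the coupled chain's SMC calcium/cGMP excursions.
#' @param nvc parameter vector; @param dt_ms integration step (ms);
#' @param sample_ms output sampling.
#' @return data.frame (t_s, R_um, F_r).
#' @export
run_wall_model <- function(dp = NULL, E_act = NULL, E_pas = NULL,
                           t_end_s = 60, drive = default_wall_drive(),
                           nvc = nvc_params(TRUE), dt_ms = 1,
                           sample_ms = 10) {
  if (is.null(dp)) dp <- nvc[["dp_wall"]]
  if (is.null(E_act)) E_act <- nvc[["E_act"]]
  if (is.null(E_pas)) E_pas <- nvc[["E_pas"]]
  ctrl <- list(t_end_ms = t_end_s * 1e3, dt_ms = dt_ms,
               sample_ms = sample_ms, ca_drive = drive$ca,
               cg_drive = drive$cg, drive_dt_ms = drive$dt_ms,
               dp_wall = dp, E_act = E_act, E_pas = E_pas)
  res <- .wall_runner(nvc, ctrl)
  data.frame(t_s = res$t_ms / 1e3, R_um = res$R_um, F_r = res$F_r)
}

#' @rdname run_wall_model
#' @param period_s,ca_mean,ca_amp,cg_mean,cg_amp drive waveform parameters
#'   (defaults emulate the coupled chain: slow calcium oscillation around
#'   0.35 uM with +-0.15 uM excursions and a cGMP swing around 4 uM).
#' @export
default_wall_drive <- function(period_s = 10, ca_mean = 0.35,
                               ca_amp = 0.15, cg_mean = 4, cg_amp = 1.5) {
  dt_ms <- 50
  tt <- seq(0, period_s * 1e3 - dt_ms, by = dt_ms)
  ph <- 2 * pi * tt / (period_s * 1e3)
  list(ca = ca_mean + ca_amp * sin(ph),
       cg = cg_mean + cg_amp * sin(ph + pi / 3),
       dt_ms = dt_ms)
}
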