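## 1D macrovascular network: construction from the vessel table, tube-law
## helpers, Windkessel calibration and the run-to-periodicity driver (the
## time stepping itself lives in src/macro1d.cpp).

#' Young-Laplace tube-law pressure
#'
#' Pressure-area relation closing the 1D flow equations:
#' P = G0 (sqrt(A/A0) - 1). Strictly increasing in A; zero at A = A0.
#'
#' @param A current lumen area (cm^2), > 0.
#' @param A0 reference area at zero transmural pressure (cm^2).
#' @param G0 wall stiffness (same pressure unit as the result).
#' @return pressure in the unit of \code{G0}.
#' @export
young_laplace_pressure <- function(A, A0, G0) {
  if (any(A <= 0) || any(A0 <= 0)) stop("areas must be positive")
  stopifnot(all(G0 > 0))
  G0 * (sqrt(A / A0) - 1)
}

#' Wall stiffness parameter of the tube law
#'
#' G0 = sqrt(pi) h0 E / ((1 - nu^2) sqrt(A0)) with Poisson ratio nu = 1/2.
#'
#' @param h0 wall thickness (cm).
#' @param E elastic modulus (Pa).
#' @param A0 reference area (cm^2).
#' @param nu Poisson ratio, default 1/2.
#' @return G0 in Pa.
#' @export
tube_stiffness <- function(h0, E, A0, nu = 0.5) {
  sqrt(pi) * h0 * E / ((1 - nu^2) * sqrt(A0))
}

#' Characteristic wave speed of the 1D system
#'
#' c(A) = sqrt(G0/(2 rho) * sqrt(A/A0)).
#'
#' @param A area (cm^2); @param A0 reference area (cm^2).
#' @param G0 stiffness in barye (dyn/cm^2); @param rho density (g/cm^3).
#' @return wave speed (cm/s).
#' @export
wave_speed <- function(A, A0, G0, rho) {
  sqrt(G0 / (2 * rho)) * (A / A0)^0.25
}

#' Half-sine cardiac inflow
#'
#' Qmax sin(pi t / (0.3 T)) during the first 30 percent of the beat, zero
#' for the remainder; t is interpreted modulo T.
#'
#' @param t time (s), vectorised.
#' @param T_period beat period (s).
#' @param Qmax peak inflow (cm^3/s), >= 0.
#' @return inflow (cm^3/s).
#' @export
inlet_flow <- function(t, T_period = 1.0, Qmax = 485.0) {
  if (T_period <= 0) stop("T must be positive")
  if (Qmax < 0) stop("Qmax must be non-negative")
  tt <- t %% T_period
  ifelse(tt <= 0.3 * T_period, Qmax * sin(pi * tt / (0.3 * T_period)), 0)
}

#' Read the arterial vessel table
#'
#' CSV with header id,name,parent_ids,child_ids,L_cm,R0_cm,h0_cm,E_Pa,
#' outlet_flag,provenance. Multi-valued topology columns use ':' separators.
#' The bundled 37-vessel table (aorta, subclavian/carotid/vertebral arteries
#' and the circle of Willis, plus the two brainstem branches feeding the
#' capillary unit) is returned when \code{path} is missing; its vessels
#' 14, 17 and 34-37 carry provenance "paper", the rest "literature".
#'
#' @param path CSV file; default the bundled table.
#' @return data.frame of vessels with list-columns \code{parents},
#'   \code{children}.
#' @export
read_vessel_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vessels37.csv", package = "ngvu")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "parent_ids", "child_ids", "L_cm", "R0_cm", "h0_cm",
            "E_Pa", "outlet_flag")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("vessel table missing columns: ",
                         paste(miss, collapse = ", "))
  split_ids <- function(x) lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  })
  d$parents <- split_ids(as.character(d$parent_ids))
  d$children <- split_ids(as.character(d$child_ids))
  stopifnot(all(d$L_cm > 0), all(d$R0_cm > 0), all(d$h0_cm > 0),
            all(d$E_Pa > 0))
  d
}

## Junctions = connected components of the (parent end-L) -- (child end-0)
## relation. Returns list of signed id vectors (+id: z=L end, -id: z=0 end).
build_junctions <- function(tab) {
  labels <- character(0)
  edges <- list()
  for (i in seq_len(nrow(tab))) {
    v <- tab$id[i]
    for (ch in tab$children[[i]]) {
      edges[[length(edges) + 1L]] <- c(paste0("L", v), paste0("S", ch))
    }
  }
  if (!length(edges)) return(list())
  nodes <- unique(unlist(edges))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in edges) {
    a <- find(match(e[1], nodes)); b <- find(match(e[2], nodes))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  out <- lapply(split(nodes, comp), function(ns) {
    sgn <- ifelse(substr(ns, 1, 1) == "L", 1L, -1L)
    ids <- as.integer(substr(ns, 2, nchar(ns)))
    as.integer(sgn * ids)
  })
  unname(out)
}

## Outlet flows of the steady resistive surrogate of the network: each
## vessel is a resistor r_vessel between its end junctions, outlets drain
## through R_out to a common venous node, the inlet injects Q_in.
steady_outlet_flows <- function(tab, r_vessel, R_out, outlets, Q_in) {
  juncs <- build_junctions(tab)
  nj <- length(juncs)
  ## hydraulic node ids: 1..nj junctions, nj+1 inlet node, nj+2 venous (gnd)
  node_of_end <- function(vid, side) {   # side "L" (z=L) or "S" (z=0)
    for (j in seq_len(nj)) {
      e <- juncs[[j]]
      if (side == "L" && any(e == vid)) return(j)
      if (side == "S" && any(e == -vid)) return(j)
    }
    NA_integer_
  }
  n <- nj + 2
  G <- matrix(0, n, n)
  add <- function(a, b, g) {
    G[a, a] <<- G[a, a] + g; G[b, b] <<- G[b, b] + g
    G[a, b] <<- G[a, b] - g; G[b, a] <<- G[b, a] - g
  }
  out_node <- integer(length(outlets))
  for (k in seq_len(nrow(tab))) {
    a <- node_of_end(tab$id[k], "S")
    if (is.na(a)) a <- nj + 1                  # network inlet
    b <- node_of_end(tab$id[k], "L")
    if (is.na(b)) {                            # outlet end
      i <- match(k, outlets)
      ## vessel + windkessel in series to ground
      g <- 1 / (r_vessel[k] + R_out[i])
      add(a, nj + 2, g)
      out_node[i] <- a
      next
    }
    add(a, b, 1 / max(r_vessel[k], 1e-12))
  }
  rhs <- numeric(n); rhs[nj + 1] <- Q_in
  keep <- seq_len(n - 1)                       # ground the venous node
  p <- numeric(n)
  p[keep] <- solve(G[keep, keep], rhs[keep])
  vapply(seq_along(outlets), function(i) {
    k <- outlets[i]
    p[out_node[i]] / (r_vessel[k] + R_out[i])
  }, numeric(1))
}

#' Assemble the 1D arterial network
#'
#' Computes per-vessel reference areas, tube-law stiffness (Eq.-4 form),
#' discretisation and friction coefficients, derives the junction sets from
#' the topology columns and calibrates a Windkessel at every outlet.
#'
#' The printed blood density 1.028e-3 g/cm^3 in the source model is
#' dimensionally implausible in CGS; the default here is 1.028 g/cm^3 and
#' the choice is recorded in the returned object (\code{rho_note}).
#'
#' @param tab vessel table from \code{\link{read_vessel_table}}.
#' @param rho blood density, g/cm^3.
#' @param gamma_bar velocity-profile shape parameter (default 9).
#' @param viscosity \code{"pries"} or \code{"constant"}.
#' @param dz_cm target cell size (cm); at least 2 cells per vessel.
#' @param T_period beat period (s); @param Qmax peak inflow (cm^3/s).
#' @param p_target_mmHg target mean arterial pressure used to size total
#'   peripheral resistance (default 93).
#' @param p_ven_mmHg venous pressure (default 5).
#' @param tau_decay_s Windkessel diastolic decay time R2*C (default 1.3).
#' @return object of class \code{arterial_network}.
#' @export
build_arterial_network <- function(tab = read_vessel_table(),
                                   rho = 1.028, gamma_bar = 9,
                                   viscosity = c("pries", "constant"),
                                   dz_cm = 0.25,
                                   T_period = 1.0, Qmax = 485,
                                   p_target_mmHg = 93, p_ven_mmHg = 5,
                                   tau_decay_s = 1.3) {
  viscosity <- match.arg(viscosity)
  mu_fun <- viscosity_law(viscosity)
  cst <- ngvu_constants
  A0 <- pi * tab$R0_cm^2
  G0_Pa <- tube_stiffness(tab$h0_cm, tab$E_Pa, A0)
  G0 <- G0_Pa * cst$Pa_to_barye
  n_cells <- pmax(2L, as.integer(ceiling(tab$L_cm / dz_cm)))
  dz <- tab$L_cm / n_cells
  mu_Pa_s <- mu_fun(2 * tab$R0_cm * 1e4)       # diameter in um
  mu_cgs <- mu_Pa_s * 10                        # poise
  fric <- 2 * (gamma_bar + 2) * mu_cgs / rho    # paper form, no pi factor
  c0 <- wave_speed(A0, A0, G0, rho)

  outlets <- which(tab$outlet_flag == 1)
  A_out <- A0[outlets]
  Qbar <- 0.3 * (2 / pi) * Qmax
  if (length(outlets)) {
    R_tot <- (p_target_mmHg - p_ven_mmHg) * cst$mmHg_to_barye / Qbar
    R_i <- R_tot * sum(A_out) / A_out
    ## fixed point against the steady resistive network so the
    ## beat-averaged flow split is exactly area-weighted and the mean
    ## aortic pressure hits its target despite the 1D path resistances
    r_vessel <- fric * rho * tab$L_cm / A0^2
    Q_target <- Qbar * A_out / sum(A_out)
    for (it in 1:40) {
      Qs <- steady_outlet_flows(tab, r_vessel, R_i, outlets, Qbar)
      if (max(abs(Qs / Q_target - 1)) < 1e-10) break
      R_i <- pmax(R_i * Qs / Q_target, 1e-6)
    }
    R1 <- rho * c0[outlets] / A0[outlets]       # characteristic impedance
    R1 <- pmin(R1, 0.2 * R_i)
    R2 <- R_i - R1
    C <- tau_decay_s / R2
  } else {
    R1 <- R2 <- C <- numeric(0)
  }

  structure(list(
    tab = tab, A0 = A0, G0 = G0, n_cells = n_cells, dz = dz,
    fric = fric, c0 = c0, rho = rho, gamma_bar = gamma_bar,
    viscosity = viscosity, mu_Pa_s = mu_Pa_s,
    T_period = T_period, Qmax = Qmax,
    outlets = tab$id[outlets],
    wk = data.frame(vessel = tab$id[outlets], R1 = R1, R2 = R2, C = C,
                    pven = rep(p_ven_mmHg * cst$mmHg_to_barye,
                               length(outlets))),
    junctions = build_junctions(tab),
    rho_note = paste0("rho = ", rho, " g/cm^3 (source prints 1.028e-3, ",
                      "see package documentation)")),
    class = "arterial_network")
}

#' @export
print.arterial_network <- function(x, ...) {
  cat("1D arterial network:", nrow(x$tab), "vessels,",
      length(x$junctions), "junctions,", length(x$outlets),
      "Windkessel outlets\n")
  cat("  rho =", x$rho, "g/cm^3; viscosity law:", x$viscosity, "\n")
  invisible(x)
}

## Low-level call into the C++ kernel. `probes` is a data.frame
## (vessel, z_frac).
macro_run <- function(net, probes, beats_max = 25, tol = 1e-3,
                      cfl = 0.9, t_end = -1, init = NULL,
                      inlet_type = "sine", extra_bc = list()) {
  tab <- net$tab
  nv <- nrow(tab)
  vs <- vector("list", nv)
  for (k in seq_len(nv)) {
    n <- net$n_cells[k]
    if (is.null(init)) {
      Ak <- rep(net$A0[k], n); Qk <- rep(0, n)
    } else {
      Ak <- init[[k]]$A; Qk <- init[[k]]$Q
    }
    vs[[k]] <- list(n = n, dz = net$dz[k], A0 = net$A0[k], G0 = net$G0[k],
                    fric = net$fric[k], A = Ak, Q = Qk)
  }
  u_est <- 200  # cm/s headroom for advective speed in the CFL bound
  dt <- cfl * min(net$dz / (net$c0 * 1.15 + u_est))
  pm <- cbind(match(probes$vessel, tab$id),
              pmin(net$n_cells[match(probes$vessel, tab$id)] - 1L,
                   as.integer(round(probes$z_frac *
                                    (net$n_cells[match(probes$vessel, tab$id)] - 1L)))))
  storage.mode(pm) <- "integer"
  bc <- list(inlet_vessel = 1L, inlet_type = inlet_type, Qmax = net$Qmax,
             wk_vessels = as.integer(net$wk$vessel),
             wk_R1 = net$wk$R1, wk_R2 = net$wk$R2, wk_C = net$wk$C,
             wk_pven = net$wk$pven,
             periodic_vessels = integer(0))
  bc[names(extra_bc)] <- extra_bc
  control <- list(rho = net$rho, T = net$T_period, dt = dt,
                  beats_max = as.integer(beats_max), tol = tol,
                  t_end = t_end, probes = pm)
  res <- .macro1d_run(vs, net$junctions, bc, control)
  if (isTRUE(res$cfl_violation)) stop("CFL violation: step rejected")
  if (isTRUE(res$negative_area)) stop("negative area encountered")
  rows <- seq_len(res$rows_used)
  res$t <- res$t[rows]
  res$Q <- res$Q[rows, , drop = FALSE]
  res$P <- res$P[rows, , drop = FALSE]
  res$A <- res$A[rows, , drop = FALSE]
  res$probes <- probes
  res
}

#' Run the 1D-0D model to a periodic state
#'
#' Starting from A = A0, Q = 0 in every vessel, beats are simulated until
#' the relative L2 difference of pressure and flow between successive beats
#' at all monitored outlets falls below \code{tol}. The one-beat record at
#' the outlet of the vessel feeding the capillary unit (id
#' \code{couple_vessel}) is returned along with its period-averaged flow.
#'
#' @param net \code{arterial_network}.
#' @param couple_vessel vessel whose outlet feeds the mesoscale tree
#'   (default 37).
#' @param beats_max maximum number of beats (default 25).
#' @param tol periodicity tolerance (default 1e-3).
#' @return list with \code{t}, \code{Q_out}, \code{P_out_mmHg} (one beat at
#'   the coupling outlet), \code{Q0} (Eq.-13 average), convergence and
#'   volume-balance diagnostics, and the full probe record.
#' @export
run_to_periodicity <- function(net, couple_vessel = 37, beats_max = 25,
                               tol = 1e-3) {
  probes <- data.frame(
    vessel = c(1L, net$outlets),
    z_frac = c(0, rep(1, length(net$outlets))))
  res <- macro_run(net, probes, beats_max = beats_max, tol = tol)
  if (!isTRUE(res$converged)) {
    stop("no periodic state within ", beats_max,
         " beats (last relative beat-to-beat difference above ", tol, ")")
  }
  ip <- which(probes$vessel == couple_vessel & probes$z_frac == 1)
  cst <- ngvu_constants
  Qout <- res$Q[, ip]
  list(t = res$t, Q_out = Qout,
       P_out_mmHg = res$P[, ip] / cst$mmHg_to_barye,
       Q0 = average_period_flow(res$t, Qout, net$T_period),
       beats = res$beats, converged = res$converged,
       volume_change = res$volume_change,
       boundary_flux_integral = res$boundary_flux_integral,
       max_junction_residual = res$max_junction_residual,
       probe_record = res)
}

#' Advance a single 0D Windkessel outlet
#'
#' Implicit-Euler update of the RCR circuit: C dp/dt = Q - (p - pven)/R2;
#' the returned boundary pressure is p + R1 Q.
#'
#' @param Q_out flow entering the Windkessel (cm^3/s).
#' @param wk list/row with R1, R2, C, pven and state \code{p} (barye).
#' @param dt step (s).
#' @return updated \code{wk} with new state \code{p} and element
#'   \code{p_boundary}.
#' @export
windkessel_update <- function(Q_out, wk, dt) {
  stopifnot(wk$R1 > 0, wk$R2 > 0, wk$C > 0)
  a <- 1 + dt / (wk$R2 * wk$C)
  wk$p <- (wk$p + dt / wk$C * (Q_out + wk$pven / wk$R2)) / a
  wk$p_boundary <- wk$p + wk$R1 * Q_out
  wk
}
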