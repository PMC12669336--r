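## Workflow orchestration: macro (1D-0D) -> meso (Murray tree) -> per-beat
## cellular advance with radius feedback into the 3D-1D microcirculation,
## plus field/series export and a small CLI.

#' Default full-simulation configuration
#'
#' @param out_dir output directory.
#' @param seed RNG seed for all stochastic components.
#' @param n_beats number of heartbeat coupling cycles.
#' @param skip_macro reuse a prescribed averaged flow \code{Q0} instead of
#'   running the (minutes-long) macrovascular stage.
#' @param Q0 averaged coupling flow (cm^3/s) used when \code{skip_macro}.
#' @return nested configuration list.
#' @export
ngvu_config <- function(out_dir = tempfile("ngvu_run_"), seed = 1,
                        n_beats = 3, skip_macro = TRUE, Q0 = 0.46) {
  list(
    seed = seed, out_dir = out_dir, n_beats = n_beats,
    macro = list(run = !skip_macro, T = 1.0, Qmax = 485, tol = 1e-3,
                 beats_max = 25, Q0 = Q0, dz_cm = 0.25),
    meso = list(gamma = 3, root_vessel = 37L, n_inlets = 2L),
    micro = list(network = NULL, levels = 3L, grid = c(8L, 8L, 8L),
                 gauge_mmHg = 30, Lp = 1e-3),
    cell = list(dt_fast_ms = 0.01, sample_ms = 5, stochastic = TRUE,
                feedback = TRUE))
}

#' Run the full multiscale workflow
#'
#' Sequential coupling over heartbeats: (1) the 1D-0D macrovascular model
#' is run to periodicity (or a prescribed averaged flow is used) and
#' averaged at the outlet of the feeding vessel; (2) the Murray-law
#' surrogate tree converts that average into capillary inlet flows;
#' (3) per heartbeat, the 0D cellular chain advances for one period, the
#' resulting radius change rescales the capillary radii, and the
#' stationary 3D-1D pressure problem is re-solved (quasi-static coupling).
#'
#' @param config list from \code{\link{ngvu_config}}.
#' @return list with the manifest, mesoscale record, per-beat summaries and
#'   final fields; outputs are also written under \code{config$out_dir}.
#' @export
run_full_simulation <- function(config = ngvu_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ngvu")),
    seed = config$seed, n_beats = config$n_beats,
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    warnings = character(0), timings = list())
  ## warnings recorded before any stage output
  net <- build_arterial_network(dz_cm = config$macro$dz_cm,
                                T_period = config$macro$T,
                                Qmax = config$macro$Qmax)
  manifest$warnings <- c(manifest$warnings, net$rho_note)
  manifest$viscosity_law <- net$viscosity
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_manifest()

  ## ---- stage 1: macrocirculation -----------------------------------------
  t0 <- proc.time()[3]
  if (isTRUE(config$macro$run)) {
    macro <- run_to_periodicity(net, couple_vessel = config$meso$root_vessel,
                                beats_max = config$macro$beats_max,
                                tol = config$macro$tol)
    Q0 <- macro$Q0
    utils::write.csv(data.frame(t_s = macro$t, Q_cm3s = macro$Q_out,
                                P_mmHg = macro$P_out_mmHg),
                     file.path(config$out_dir, "macro_outlet_beat.csv"),
                     row.names = FALSE)
  } else {
    macro <- NULL
    Q0 <- config$macro$Q0
  }
  manifest$timings$macro_s <- proc.time()[3] - t0

  ## ---- stage 2: mesoscale coupling ---------------------------------------
  g <- if (is.null(config$micro$network)) {
    generate_synthetic_network(seed = config$seed,
                               levels = config$micro$levels)
  } else {
    read_capillary_network(config$micro$network)
  }
  inlet_r_um <- vapply(g$inlets, function(nd) {
    max(g$segments$radius_um[g$segments$n1 == nd | g$segments$n2 == nd])
  }, numeric(1))
  ord <- order(inlet_r_um, decreasing = TRUE)
  r0_cm <- net$tab$R0_cm[net$tab$id == config$meso$root_vessel]
  meso <- mesotree_couple(Q0, inlet_r_um[ord] * 1e-4, r0_cm,
                          config$meso$gamma)
  jsonlite::write_json(meso, file.path(config$out_dir, "meso.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- stage 3: per-beat cellular + microcirculation ---------------------
  dom <- tissue_domain(grid = config$micro$grid,
                       gauge_mmHg = config$micro$gauge_mmHg)
  syn <- calibrate_rest(synapse_params(TRUE))
  nvc <- nvc_params(TRUE)
  nvc[["Q_wss"]] <- meso$inlets$Q_cm3s[1]
  inlet_flows_um3 <- meso$inlets$Q_cm3s * 1e12   # cm^3/s -> um^3/s
  beats <- list()
  cell_trace <- NULL
  R_ref <- NULL
  t1 <- proc.time()[3]
  for (b in seq_len(config$n_beats)) {
    tr <- simulate_ngvu_cell(t_end_s = net$T_period,
                             dt_fast_ms = config$cell$dt_fast_ms,
                             sample_ms = config$cell$sample_ms,
                             stochastic = config$cell$stochastic,
                             syn = syn, nvc = nvc)
    tr$t_ms <- tr$t_ms + (b - 1) * net$T_period * 1e3
    cell_trace <- rbind(cell_trace, tr)
    R_end <- tr$R_um[nrow(tr)]
    if (is.null(R_ref)) R_ref <- tr$R_um[1]
    factor <- if (isTRUE(config$cell$feedback)) R_end / R_ref else 1
    gb <- apply_radius_modulation(g, factor)
    sol <- solve_pressure_3d1d(gb, dom, inlet_flows = inlet_flows_um3[ord],
                               Lp = config$micro$Lp)
    vel <- compute_velocities(sol)
    inlet_seg <- vapply(gb$inlets, function(nd) {
      which(gb$segments$n1 == nd | gb$segments$n2 == nd)[1]
    }, integer(1))
    beats[[b]] <- data.frame(
      beat = b, radius_factor = factor, R_um = R_end,
      p1_mean_mmHg = mean(sol$p1),
      inlet_v_um_s = mean(abs(vel$v_seg[inlet_seg])),
      residual = sol$residual)
    nvc[["R_init"]] <- R_end   # continue wall state across beats
  }
  manifest$timings$cell_micro_s <- proc.time()[3] - t1
  beat_summary <- do.call(rbind, beats)
  utils::write.csv(beat_summary,
                   file.path(config$out_dir, "beat_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cell_trace, file.path(config$out_dir, "cell_trace.csv"),
                   row.names = FALSE)
  export_fields(list(graph = g, dom = dom, sol = sol), "vtk",
                dir = config$out_dir)
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  manifest$field_ranges <- list(p1_mmHg = range(sol$p1),
                                p3_mmHg = range(sol$p3))
  write_manifest()
  invisible(list(manifest = manifest, meso = meso, beats = beat_summary,
                 cell_trace = cell_trace, pressure = sol, macro = macro))
}

#' Export fields and series
#'
#' Writes the tissue pressure as a legacy-VTK structured-points file, the
#' capillary graph with nodal pressures as legacy-VTK polylines, and/or
#' tidy CSV series.
#'
#' @param results list with \code{graph}, \code{dom} and \code{sol}
#'   (a \code{pressure_solution}).
#' @param format "vtk" or "csv".
#' @param dir output directory.
#' @return paths of the written files.
#' @export
export_fields <- function(results, format = c("vtk", "csv"), dir = ".") {
  format <- match.arg(format)
  sol <- results$sol; dom <- results$dom; g <- results$graph
  paths <- character(0)
  if (format == "csv") {
    f <- file.path(dir, "pressure_1d.csv")
    utils::write.csv(data.frame(node = seq_along(sol$p1), p1_mmHg = sol$p1),
                     f, row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(dir, "pressure_3d.csv")
    utils::write.csv(data.frame(cell = seq_along(sol$p3), p3_mmHg = sol$p3),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  } else {
    f <- file.path(dir, "tissue_pressure.vtk")
    con <- file(f, "w")
    writeLines(c("# vtk DataFile Version 3.0", "tissue pressure", "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d %d", dom$grid[1], dom$grid[2],
                         dom$grid[3]),
                 sprintf("ORIGIN %g %g %g", dom$h[1] / 2, dom$h[2] / 2,
                         dom$h[3] / 2),
                 sprintf("SPACING %g %g %g", dom$h[1], dom$h[2], dom$h[3]),
                 sprintf("POINT_DATA %d", prod(dom$grid)),
                 "SCALARS p3_mmHg float 1", "LOOKUP_TABLE default"), con)
    writeLines(paste(format(sol$p3, digits = 7), collapse = " "), con)
    close(con)
    paths <- c(paths, f)
    f <- file.path(dir, "vessel_pressure.vtk")
    con <- file(f, "w")
    ns <- nrow(g$segments)
    writeLines(c("# vtk DataFile Version 3.0", "capillary network", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(g$nodes))), con)
    writeLines(apply(g$nodes, 1, function(p) paste(p, collapse = " ")), con)
    writeLines(sprintf("LINES %d %d", ns, 3 * ns), con)
    writeLines(sprintf("2 %d %d", g$segments$n1 - 1, g$segments$n2 - 1),
               con)
    writeLines(c(sprintf("POINT_DATA %d", nrow(g$nodes)),
                 "SCALARS p1_mmHg float 1", "LOOKUP_TABLE default"), con)
    writeLines(paste(format(sol$p1, digits = 7), collapse = " "), con)
    close(con)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Command-line interface
#'
#' Subcommands: \code{macro} (run the 1D-0D network to periodicity and
#' report Q0), \code{micro} (solve the 3D-1D pressure problem on a network
#' file or the synthetic network), \code{sens} (sensitivity study),
#' \code{run} (full workflow). Invoke via
#' \code{Rscript -e 'ngvu::ngvu_cli()' macro --tol 1e-3}.
#'
#' @param args character vector (default: command line).
#' @return invisibly, the subcommand's result.
#' @export
ngvu_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: ngvu <macro|micro|sens|run> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    if (startsWith(kv[i], "--")) {
      opt[[substring(kv[i], 3)]] <- if (i < length(kv)) kv[i + 1] else ""
      i <- i + 2
    } else i <- i + 1
  }
  getn <- function(name, default) {
    if (!is.null(opt[[name]])) as.numeric(opt[[name]]) else default
  }
  res <- switch(
    cmd,
    macro = {
      net <- build_arterial_network(
        tab = if (!is.null(opt$vessels)) read_vessel_table(opt$vessels)
              else read_vessel_table(),
        T_period = getn("T", 1.0), Qmax = getn("Qmax", 485))
      r <- run_to_periodicity(net, beats_max = getn("beats-max", 25),
                              tol = getn("tol", 1e-3))
      cat(sprintf("converged after %d beats; Q0 = %.4g cm^3/s\n",
                  r$beats, r$Q0))
      r
    },
    micro = {
      g <- if (!is.null(opt$network)) read_capillary_network(opt$network)
           else generate_synthetic_network(seed = getn("seed", 1))
      grid <- if (!is.null(opt$grid)) {
        as.integer(strsplit(opt$grid, ",")[[1]])
      } else c(8L, 8L, 8L)
      dom <- tissue_domain(grid = grid,
                           gauge_mmHg = getn("gauge-mmHg", 30))
      qin <- if (!is.null(opt$inflow)) {
        as.numeric(strsplit(opt$inflow, ",")[[1]])
      } else rep(5e4, length(g$inlets))
      sol <- solve_pressure_3d1d(g, dom, inlet_flows = qin)
      cat(sprintf("solved: mean p1 = %.3f mmHg, residual = %.2e\n",
                  mean(sol$p1), sol$residual))
      sol
    },
    sens = {
      mode <- if (!is.null(opt$mode)) opt$mode else "local"
      out <- switch(mode,
                    oat = oat_sweep(),
                    lhs = lhs_prcc_study(n = getn("n", 200),
                                         seed = getn("seed", 1)),
                    local = local_elasticity())
      print(out)
      if (!is.null(opt$out) && mode == "oat") {
        utils::write.csv(out, opt$out, row.names = FALSE)
      }
      out
    },
    run = {
      cfg <- ngvu_config(seed = getn("seed", 1),
                         n_beats = getn("beats", 3))
      run_full_simulation(cfg)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}
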