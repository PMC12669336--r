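## Shared fixtures. Expensive runs are computed lazily and memoised so that
## several test files can share one macro run / one long cell-chain trace.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## a single elastic vessel as a one-row table (no junctions)
single_vessel_tab <- function(L = 20, R0 = 0.3, h0 = 0.05, E = 4e5) {
  data.frame(id = 1L, name = "test", parent_ids = "", child_ids = "",
             L_cm = L, R0_cm = R0, h0_cm = h0, E_Pa = E,
             outlet_flag = 0L, provenance = "synthetic",
             parents = I(list(integer(0))), children = I(list(integer(0))))
}

single_vessel_net <- function(L = 20, R0 = 0.3, dz_cm = 0.1, fric0 = TRUE) {
  tab <- single_vessel_tab(L = L, R0 = R0)
  net <- build_arterial_network(tab, dz_cm = dz_cm, viscosity = "constant")
  if (fric0) net$fric[] <- 0
  net$junctions <- list()
  net$wk <- net$wk[0, ]
  net
}

## straight multi-node capillary along the x axis
straight_capillary <- function(n_nodes = 11, L_um = 100, r_um = 4) {
  xs <- seq(0, L_um, length.out = n_nodes)
  nodes <- cbind(xs, rep(50, n_nodes), rep(50, n_nodes))
  seg <- data.frame(n1 = seq_len(n_nodes - 1), n2 = 2:n_nodes,
                    radius_um = r_um)
  capillary_graph(nodes, seg, inlets = 1L, outlets = n_nodes)
}

## one periodic macro solution of the full 37-vessel network (Eq-13 record)
macro_fixture <- function() {
  fixture("macro_run", {
    net <- build_arterial_network()
    run_to_periodicity(net, beats_max = 25, tol = 1e-3)
  })
}

## one 60 s stochastic default-parameter cell-chain trace (seed 11)
cell60_fixture <- function() {
  fixture("cell60", {
    set.seed(11)
    simulate_ngvu_cell(t_end_s = 60, sample_ms = 10)
  })
}
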