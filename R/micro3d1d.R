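## 3D-1D coupled microcirculation: a capillary centre-line graph embedded in
## a tissue box. Stationary pressure solve with wall exchange, velocity
## extraction, convection-diffusion transport, network ASCII I/O and a
## synthetic network generator emulating the brain99-style data layout.
##
## Units: lengths um, pressures mmHg, time s; permeabilities K1, K3 in
## um^2/(mmHg s), wall permeability Lp in um/(mmHg s), flows um^3/s.

#' Construct a capillary graph
#'
#' @param nodes numeric matrix (n x 3) of coordinates in micrometres.
#' @param segments data.frame with integer endpoints \code{n1}, \code{n2}
#'   (1-based) and \code{radius_um}.
#' @param inlets,outlets node indices carrying prescribed in/outflow.
#' @param validate check invariants (radii positive, connectivity).
#' @return object of class \code{capillary_graph}; segment lengths are
#'   computed from the coordinates.
#' @export
capillary_graph <- function(nodes, segments, inlets = integer(0),
                            outlets = integer(0), validate = TRUE) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3)
  segments$n1 <- as.integer(segments$n1)
  segments$n2 <- as.integer(segments$n2)
  segments$length_um <- sqrt(rowSums(
    (nodes[segments$n1, , drop = FALSE] -
       nodes[segments$n2, , drop = FALSE])^2))
  g <- structure(list(nodes = nodes, segments = segments,
                      inlets = as.integer(inlets),
                      outlets = as.integer(outlets)),
                 class = "capillary_graph")
  if (validate) validate_capillary_graph(g)
  g
}

validate_capillary_graph <- function(g) {
  if (any(g$segments$radius_um <= 0)) stop("non-positive segment radius")
  if (any(g$segments$length_um <= 0)) stop("zero-length segment")
  n <- nrow(g$nodes)
  ## connectivity via union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in seq_len(nrow(g$segments))) {
    a <- find(g$segments$n1[s]); b <- find(g$segments$n2[s])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  if (length(unique(comp)) > 1) stop("capillary graph is not connected")
  invisible(TRUE)
}

#' @export
print.capillary_graph <- function(x, ...) {
  cat("capillary graph:", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments,", length(x$inlets), "inlet(s),", length(x$outlets),
      "outlet(s)\n")
  invisible(x)
}

#' Read / write the capillary network ASCII format
#'
#' Dialect: first line \code{<n_nodes> <n_segments>}; then node lines
#' \code{id x y z} (um), segment lines \code{id n1 n2 radius_um}, and marker
#' lines \code{INLET id} / \code{OUTLET id}. Node and segment ids are
#' 1-based and must be consecutive.
#'
#' @param path file path (or connection for reading).
#' @return \code{read_capillary_network}: a \code{capillary_graph}.
#' @export
read_capillary_network <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- suppressWarnings(as.numeric(strsplit(lines[1], "\\s+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr)) stop("line 1: malformed header")
  nn <- hdr[1]; ns <- hdr[2]
  if (length(lines) < 1 + nn + ns) stop("file truncated")
  nodes <- matrix(NA_real_, nn, 3)
  for (i in seq_len(nn)) {
    f <- suppressWarnings(as.numeric(strsplit(lines[1 + i], "\\s+")[[1]]))
    if (length(f) != 4 || anyNA(f)) {
      stop("line ", 1 + i, ": malformed node line")
    }
    nodes[f[1], ] <- f[2:4]
  }
  seg <- data.frame(n1 = integer(ns), n2 = integer(ns),
                    radius_um = numeric(ns))
  for (i in seq_len(ns)) {
    ln <- 1 + nn + i
    f <- suppressWarnings(as.numeric(strsplit(lines[ln], "\\s+")[[1]]))
    if (length(f) != 4 || anyNA(f)) stop("line ", ln, ": malformed segment")
    if (f[4] <= 0) stop("line ", ln, ": non-positive radius")
    seg$n1[f[1]] <- f[2]; seg$n2[f[1]] <- f[3]; seg$radius_um[f[1]] <- f[4]
  }
  inlets <- integer(0); outlets <- integer(0)
  for (ln in lines[-seq_len(1 + nn + ns)]) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "INLET") inlets <- c(inlets, as.integer(f[2]))
    else if (f[1] == "OUTLET") outlets <- c(outlets, as.integer(f[2]))
    else stop("unknown marker line: ", ln)
  }
  capillary_graph(nodes, seg, inlets, outlets)
}

#' @rdname read_capillary_network
#' @param g a \code{capillary_graph}.
#' @export
write_capillary_network <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(g$nodes), nrow(g$segments)), con)
  for (i in seq_len(nrow(g$nodes))) {
    writeLines(sprintf("%d %.10g %.10g %.10g", i,
                       g$nodes[i, 1], g$nodes[i, 2], g$nodes[i, 3]), con)
  }
  for (s in seq_len(nrow(g$segments))) {
    writeLines(sprintf("%d %d %d %.10g", s, g$segments$n1[s],
                       g$segments$n2[s], g$segments$radius_um[s]), con)
  }
  for (i in g$inlets) writeLines(paste("INLET", i), con)
  for (i in g$outlets) writeLines(paste("OUTLET", i), con)
  invisible(path)
}

#' Synthetic capillary network generator
#'
#' Stand-in for the brain99-style reconstructed network (which is not
#' redistributed here): two binary trees rooted at opposite faces of the
#' tissue box grow towards the centre, child radii following the symmetric
#' Murray rule r_child = 2^(-1/gamma) r_parent; opposing leaves are joined
#' by anastomoses and two leaves are routed to the boundary as outlets. The
#' two tree roots are the boundary vessels with the largest radii and are
#' labelled inlets (radii default to the 4.5/4.0 um pair of the reference
#' geometry).
#'
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param levels bifurcation levels per tree, >= 1.
#' @param box box extents in um (default c(150, 160, 140)).
#' @param r_inlet_um radii of the two tree roots (um).
#' @param gamma Murray exponent.
#' @return \code{capillary_graph}.
#' @export
generate_synthetic_network <- function(seed = 1L, levels = 3L,
                                       box = c(150, 160, 140),
                                       r_inlet_um = c(4.5, 4.0),
                                       gamma = 3) {
  if (levels < 1) stop("levels must be >= 1")
  if (box[1] < 40) stop("box too small for the requested levels")
  set.seed(seed)
  nodes <- NULL; seg <- NULL
  add_node <- function(p) {
    p <- pmin(pmax(p, 0), box)
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }
  add_seg <- function(a, b, r, kind = "tree") {
    seg <<- rbind(seg, data.frame(n1 = a, n2 = b, radius_um = r,
                                  kind = kind))
  }
  step_x <- box[1] / (2 * (levels + 2))
  grow_tree <- function(root_xyz, dirx, r_root) {
    root <- add_node(root_xyz)
    first <- add_node(root_xyz + c(dirx * step_x, 0, 0))
    add_seg(root, first, r_root)
    tips <- list(list(node = first, r = r_root))
    for (l in seq_len(levels)) {
      new_tips <- list()
      for (tp in tips) {
        r_child <- tp$r * 2^(-1 / gamma)
        for (s in c(-1, 1)) {
          p0 <- nodes[tp$node, ]
          lat <- stats::runif(2, 0.2, 0.8) * c(s, sample(c(-1, 1), 1)) *
            box[2:3] / (2^(l + 1))
          child <- add_node(p0 + c(dirx * step_x, lat))
          add_seg(tp$node, child, r_child)
          new_tips[[length(new_tips) + 1]] <- list(node = child, r = r_child)
        }
      }
      tips <- new_tips
    }
    list(root = root, tips = tips)
  }
  t1 <- grow_tree(c(0, box[2] * 0.45, box[3] * 0.5), +1, r_inlet_um[1])
  t2 <- grow_tree(c(box[1], box[2] * 0.55, box[3] * 0.5), -1, r_inlet_um[2])
  ## anastomoses: pair tips of tree 1 with nearest unused tips of tree 2
  used <- rep(FALSE, length(t2$tips))
  for (tp in t1$tips) {
    d <- vapply(seq_along(t2$tips), function(i) {
      if (used[i]) return(Inf)
      sqrt(sum((nodes[tp$node, ] - nodes[t2$tips[[i]]$node, ])^2))
    }, numeric(1))
    i <- which.min(d); used[i] <- TRUE
    add_seg(tp$node, t2$tips[[i]]$node,
            min(tp$r, t2$tips[[i]]$r), kind = "anastomosis")
  }
  ## route two capillary tips to the y-boundaries as outlets
  leaf_r <- t1$tips[[1]]$r
  o1 <- add_node(c(box[1] * 0.4, 0, nodes[t1$tips[[1]]$node, 3]))
  add_seg(t1$tips[[1]]$node, o1, leaf_r * 0.9, kind = "outlet")
  o2 <- add_node(c(box[1] * 0.6, box[2], nodes[t2$tips[[1]]$node, 3]))
  add_seg(t2$tips[[1]]$node, o2, t2$tips[[1]]$r * 0.9, kind = "outlet")
  rownames(nodes) <- NULL
  capillary_graph(nodes, seg, inlets = c(t1$root, t2$root),
                  outlets = c(o1, o2))
}

#' Tissue domain description
#'
#' @param box extents in um (default the reference 150 x 160 x 140 block).
#' @param grid cells per axis, length 3, each >= 4.
#' @param K3 tissue permeability (um^2/(mmHg s)).
#' @param gauge_mmHg target network mean pressure (default 30).
#' @return list of class \code{tissue_domain}.
#' @export
tissue_domain <- function(box = c(150, 160, 140), grid = c(12, 12, 12),
                          K3 = 1.0, gauge_mmHg = 30) {
  stopifnot(all(grid >= 4), K3 > 0)
  structure(list(box = box, grid = as.integer(grid), h = box / grid,
                 K3 = K3, gauge_mmHg = gauge_mmHg),
            class = "tissue_domain")
}

## cell index of a point (1-based linear index), clamped into the box
cell_of <- function(p, dom) {
  ijk <- pmin(pmax(floor(p / dom$h), 0), dom$grid - 1)
  1 + ijk[1] + dom$grid[1] * (ijk[2] + dom$grid[2] * ijk[3])
}

## Per-segment quadrature samples for the wall-exchange operator:
## sub-points along the centre line, each carrying weight L/ns and the
## nearest tissue cell (cylinder-surface averaging by nearest-cell rule).
exchange_samples <- function(g, dom) {
  out <- vector("list", nrow(g$segments))
  for (s in seq_len(nrow(g$segments))) {
    a <- g$nodes[g$segments$n1[s], ]; b <- g$nodes[g$segments$n2[s], ]
    L <- g$segments$length_um[s]
    ns <- max(1L, ceiling(L / min(dom$h)))
    xi <- (seq_len(ns) - 0.5) / ns
    cells <- vapply(xi, function(x) cell_of(a + x * (b - a), dom),
                    numeric(1))
    out[[s]] <- list(xi = xi, w = rep(L / ns, ns), cells = as.integer(cells))
  }
  out
}

#' Poiseuille axial permeability
#'
#' K1 = R^2 / (8 mu) with the diameter-dependent viscosity law shared with
#' the macrovascular model; returns um^2/(mmHg s).
#'
#' @param radius_um segment radius (um).
#' @param viscosity "pries" or "constant".
#' @export
poiseuille_K1 <- function(radius_um, viscosity = c("pries", "constant")) {
  viscosity <- match.arg(viscosity)
  mu_Pa_s <- viscosity_law(viscosity)(2 * radius_um)
  mu_mmHg_s <- mu_Pa_s / ngvu_constants$mmHg_to_Pa
  radius_um^2 / (8 * mu_mmHg_s)
}

#' Stationary 3D-1D coupled pressure solve
#'
#' Solves the coupled system: along the centre lines,
#' -d/ds (pi R^2 K1 dp1/ds) + 2 pi R Lp (p1 - p3bar) = 0, and in the tissue
#' -div(K3 grad p3) + Lp (p3 - p1) delta_Gamma = 0, with prescribed inlet
#' and outlet flows (Neumann; they must balance) and homogeneous Neumann on
#' the outer boundary. The pure-Neumann nullspace is fixed by pinning one
#' 1D node, after which all pressures are shifted uniformly so the
#' length-weighted network mean equals the gauge target.
#'
#' @param g \code{capillary_graph}.
#' @param dom \code{tissue_domain}.
#' @param inlet_flows um^3/s per inlet node (positive into the network).
#' @param outlet_flows um^3/s per outlet node (positive out of the
#'   network); if missing, inflow is distributed over outlets by
#'   cross-section area.
#' @param K1 axial permeability per segment; default Poiseuille.
#' @param Lp wall permeability (um/(mmHg s)).
#' @param viscosity viscosity law for the default K1.
#' @param gauge_at where the nullspace pin sits: "node1d" (default; the
#'   node adjacent to the largest-radius segment) or "cell3d" (first
#'   tissue cell -- required when Lp = 0 leaves the tissue block floating,
#'   and the natural choice when outlet flows are deliberately throttled
#'   so that the excess must leave through the vessel walls).
#' @param allow_imbalance skip the Neumann compatibility check (the pinned
#'   gauge then absorbs the prescribed imbalance).
#' @return list of class \code{pressure_solution}: \code{p1} (per node,
#'   mmHg), \code{p3} (per cell), segment flows \code{Q_seg}, wall exchange
#'   per segment, residual norms.
#' @export
solve_pressure_3d1d <- function(g, dom, inlet_flows,
                                outlet_flows = NULL,
                                K1 = NULL, Lp = 1e-3,
                                viscosity = "constant",
                                gauge_at = c("node1d", "cell3d"),
                                allow_imbalance = FALSE) {
  gauge_at <- match.arg(gauge_at)
  nseg <- nrow(g$segments)
  nn <- nrow(g$nodes)
  nc <- prod(dom$grid)
  R <- g$segments$radius_um
  L <- g$segments$length_um
  if (is.null(K1)) K1 <- poiseuille_K1(R, viscosity)
  K1 <- rep_len(K1, nseg)
  if (is.null(outlet_flows)) {
    r_out <- vapply(g$outlets, function(nd) {
      max(g$segments$radius_um[g$segments$n1 == nd | g$segments$n2 == nd])
    }, numeric(1))
    outlet_flows <- distribute_outflow(sum(inlet_flows), pi * r_out^2)
  }
  if (!allow_imbalance &&
      abs(sum(inlet_flows) - sum(outlet_flows)) >
      1e-8 * max(sum(inlet_flows), 1)) {
    stop("Neumann solvability violated: inlet and outlet flows must balance")
  }

  g_seg <- pi * R^2 * K1 / L              # axial conductance um^3/(mmHg s)
  ## 1D graph Laplacian
  ii <- c(g$segments$n1, g$segments$n2, g$segments$n1, g$segments$n2)
  jj <- c(g$segments$n1, g$segments$n2, g$segments$n2, g$segments$n1)
  xx <- c(g_seg, g_seg, -g_seg, -g_seg)
  ## exchange operator
  sam <- exchange_samples(g, dom)
  exi <- integer(0); exj <- integer(0); exw <- numeric(0)
  for (s in seq_len(nseg)) {
    ss <- sam[[s]]
    coef <- 2 * pi * R[s] * Lp * ss$w     # um^2/(mmHg s) per sample
    n1 <- g$segments$n1[s]; n2 <- g$segments$n2[s]
    w1 <- (1 - ss$xi) * coef; w2 <- ss$xi * coef
    exi <- c(exi, rep(n1, length(coef)), rep(n2, length(coef)))
    exj <- c(exj, ss$cells, ss$cells)
    exw <- c(exw, w1, w2)
  }
  ## assemble full symmetric system over (p1, p3)
  B_i <- exi; B_j <- nn + exj; B_x <- exw
  ## diagonal lumping of exchange on both sides
  d1 <- tapply(exw, exi, sum)
  d3 <- tapply(exw, exj, sum)
  ii2 <- c(ii, as.integer(names(d1)), nn + as.integer(names(d3)),
           B_i, B_j)
  jj2 <- c(jj, as.integer(names(d1)), nn + as.integer(names(d3)),
           B_j, B_i)
  xx2 <- c(xx, as.numeric(d1), as.numeric(d3), -B_x, -B_x)
  ## 3D FV Laplacian
  nx <- dom$grid[1]; ny <- dom$grid[2]; nz <- dom$grid[3]; h <- dom$h
  idx <- function(i, j, k) 1 + i + nx * (j + ny * k)   # 0-based ijk
  fa <- c(h[2] * h[3] / h[1], h[1] * h[3] / h[2], h[1] * h[2] / h[3]) *
    dom$K3
  for (axis in 1:3) {
    n_ax <- dom$grid[axis]
    grd <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
    sel <- switch(axis, grd$i < nx - 1, grd$j < ny - 1, grd$k < nz - 1)
    gA <- grd[sel, ]
    a <- idx(gA$i, gA$j, gA$k)
    b <- switch(axis,
                idx(gA$i + 1, gA$j, gA$k),
                idx(gA$i, gA$j + 1, gA$k),
                idx(gA$i, gA$j, gA$k + 1))
    ii2 <- c(ii2, nn + a, nn + b, nn + a, nn + b)
    jj2 <- c(jj2, nn + a, nn + b, nn + b, nn + a)
    xx2 <- c(xx2, rep(fa[axis], length(a)), rep(fa[axis], length(a)),
             rep(-fa[axis], length(a)), rep(-fa[axis], length(a)))
  }
  M <- Matrix::sparseMatrix(i = ii2, j = jj2, x = xx2,
                            dims = c(nn + nc, nn + nc))
  rhs <- numeric(nn + nc)
  rhs[g$inlets] <- rhs[g$inlets] + inlet_flows
  rhs[g$outlets] <- rhs[g$outlets] - outlet_flows
  ## gauge pin against the pure-Neumann nullspace (when Lp = 0 the tissue
  ## block is decoupled and floats: pin both parts)
  rhs_p <- rhs
  pins <- if (Lp == 0) {
    c(g$segments$n1[which.max(R)], nn + 1L)
  } else if (gauge_at == "node1d") {
    g$segments$n1[which.max(R)]
  } else nn + 1L
  for (pin in pins) {
    M[pin, ] <- 0; M[pin, pin] <- 1
    rhs_p[pin] <- dom$gauge_mmHg
  }
  sol <- as.numeric(Matrix::solve(M, rhs_p))
  p1 <- sol[seq_len(nn)]; p3 <- sol[nn + seq_len(nc)]
  ## uniform shift to hit the length-weighted network mean
  wts <- numeric(nn)
  for (s in seq_len(nseg)) {
    wts[g$segments$n1[s]] <- wts[g$segments$n1[s]] + L[s] / 2
    wts[g$segments$n2[s]] <- wts[g$segments$n2[s]] + L[s] / 2
  }
  shift <- dom$gauge_mmHg - sum(p1 * wts) / sum(wts)
  p1 <- p1 + shift; p3 <- p3 + shift
  Q_seg <- g_seg * (p1[g$segments$n1] - p1[g$segments$n2])
  exch <- vapply(seq_len(nseg), function(s) {
    ss <- sam[[s]]
    p1s <- (1 - ss$xi) * p1[g$segments$n1[s]] + ss$xi * p1[g$segments$n2[s]]
    sum(2 * pi * R[s] * Lp * ss$w * (p1s - p3[ss$cells]))
  }, numeric(1))
  ## conservation residual (exclude the pinned row, restore its equation)
  res <- {
    full <- Matrix::sparseMatrix(i = ii2, j = jj2, x = xx2,
                                 dims = c(nn + nc, nn + nc)) %*%
      (sol + shift) - rhs
    full[pins] <- 0        # pinned rows absorb the gauge (and, when outlet
                           # flows are throttled, the prescribed imbalance)
    max(abs(full)) / max(abs(rhs), 1e-12)
  }
  structure(list(p1 = p1, p3 = p3, Q_seg = Q_seg, exchange = exch,
                 residual = res, K1 = K1, Lp = Lp, dom = dom,
                 graph = g),
            class = "pressure_solution")
}

#' Velocities from a pressure solution
#'
#' v_c = -K1 dp1/ds per segment (positive from n1 to n2) and
#' v_Omega = -K3 grad p3 per cell (central differences, one-sided at the
#' boundary).
#'
#' @param sol \code{pressure_solution}.
#' @return list with \code{v_seg} (um/s per segment) and \code{v_cell}
#'   (nc x 3 matrix, um/s).
#' @export
compute_velocities <- function(sol) {
  g <- sol$graph; dom <- sol$dom
  dp <- sol$p1[g$segments$n2] - sol$p1[g$segments$n1]
  v_seg <- -sol$K1 * dp / g$segments$length_um
  nx <- dom$grid[1]; ny <- dom$grid[2]; nz <- dom$grid[3]
  p <- array(sol$p3, dim = dom$grid)
  grad <- function(arr, axis) {
    n <- dim(arr)[axis]
    ap <- function(ix) {
      id <- list(seq_len(nx), seq_len(ny), seq_len(nz)); id[[axis]] <- ix
      arr[id[[1]], id[[2]], id[[3]], drop = FALSE]
    }
    up <- ap(pmin(seq_len(n) + 1, n)); dn <- ap(pmax(seq_len(n) - 1, 1))
    den <- (pmin(seq_len(n) + 1, n) - pmax(seq_len(n) - 1, 1)) *
      dom$h[axis]
    sw <- sweep(up - dn, axis, den, "/")
    sw
  }
  v_cell <- cbind(-dom$K3 * as.numeric(grad(p, 1)),
                  -dom$K3 * as.numeric(grad(p, 2)),
                  -dom$K3 * as.numeric(grad(p, 3)))
  list(v_seg = v_seg, v_cell = v_cell)
}

#' Advection-diffusion transport on the coupled 3D-1D geometry
#'
#' Operator-split integrator: explicit upwind advection (graph and tissue)
#' and explicit wall exchange, then implicit diffusion. Homogeneous Neumann
#' on the outer boundary; inlet nodes carry the inflow concentration.
#'
#' @param g \code{capillary_graph}; @param dom \code{tissue_domain}.
#' @param sol \code{pressure_solution} for the velocity field (or NULL for
#'   a quiescent medium).
#' @param c1 initial nodal concentrations; @param c3 initial cell
#'   concentrations.
#' @param dt step (s); @param n_steps number of steps.
#' @param D1,D3 diffusivities (um^2/s); @param eta_w wall mass-transfer
#'   coefficient (um/s); @param c_in inflow concentration.
#' @return list with final \code{c1}, \code{c3}, and total tracer mass
#'   before/after (\code{mass0}, \code{mass1}).
#' @export
solve_transport <- function(g, dom, sol = NULL, c1, c3, dt, n_steps,
                            D1 = 0, D3 = 0, eta_w = 0, c_in = 0) {
  nseg <- nrow(g$segments); nn <- nrow(g$nodes); nc <- prod(dom$grid)
  R <- g$segments$radius_um; L <- g$segments$length_um
  Aseg <- pi * R^2
  ## nodal volumes: half of each adjacent segment
  V1 <- numeric(nn)
  for (s in seq_len(nseg)) {
    V1[g$segments$n1[s]] <- V1[g$segments$n1[s]] + Aseg[s] * L[s] / 2
    V1[g$segments$n2[s]] <- V1[g$segments$n2[s]] + Aseg[s] * L[s] / 2
  }
  V3 <- prod(dom$h)
  Qs <- if (is.null(sol)) numeric(nseg) else sol$Q_seg
  vmax <- if (nseg) max(abs(Qs) / Aseg) else 0
  if (vmax * dt > min(L)) stop("CFL violation on the graph: reduce dt")
  sam <- exchange_samples(g, dom)
  ## tissue face velocities for upwinding (from cell-centred v)
  vel <- if (is.null(sol)) NULL else compute_velocities(sol)
  mass0 <- sum(c1 * V1) + sum(c3) * V3
  ## implicit diffusion operators
  make_diff <- function() {
    if (D3 <= 0) return(NULL)
    nx <- dom$grid[1]; ny <- dom$grid[2]; nz <- dom$grid[3]
    idx <- function(i, j, k) 1 + i + nx * (j + ny * k)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    fa <- c(dom$h[2] * dom$h[3] / dom$h[1],
            dom$h[1] * dom$h[3] / dom$h[2],
            dom$h[1] * dom$h[2] / dom$h[3]) * D3 / V3
    for (axis in 1:3) {
      grd <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
      sel <- switch(axis, grd$i < nx - 1, grd$j < ny - 1, grd$k < nz - 1)
      gA <- grd[sel, ]
      a <- idx(gA$i, gA$j, gA$k)
      b <- switch(axis, idx(gA$i + 1, gA$j, gA$k),
                  idx(gA$i, gA$j + 1, gA$k), idx(gA$i, gA$j, gA$k + 1))
      ii <- c(ii, a, b, a, b); jj <- c(jj, a, b, b, a)
      xx <- c(xx, rep(fa[axis], length(a)), rep(fa[axis], length(a)),
              rep(-fa[axis], length(a)), rep(-fa[axis], length(a)))
    }
    Lap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nc, nc))
    Matrix::Diagonal(nc) + dt * Lap
  }
  Mdiff <- make_diff()
  for (step in seq_len(n_steps)) {
    dm1 <- numeric(nn)   # mass rates into 1D nodes (um^3 * conc / s)
    ## upwind advection along segments
    for (s in seq_len(nseg)) {
      q <- Qs[s]
      if (q == 0) next
      up <- if (q > 0) g$segments$n1[s] else g$segments$n2[s]
      dn <- if (q > 0) g$segments$n2[s] else g$segments$n1[s]
      flux <- abs(q) * c1[up]
      dm1[up] <- dm1[up] - flux
      dm1[dn] <- dm1[dn] + flux
    }
    ## boundary flows: the net segment outflow of an inlet node is fed from
    ## outside at concentration c_in; an outlet node's net segment inflow
    ## leaves the domain at the local concentration.
    if (!is.null(sol)) {
      net_out <- function(nd) {
        sum(Qs[g$segments$n1 == nd]) - sum(Qs[g$segments$n2 == nd])
      }
      for (nd in g$inlets)  dm1[nd] <- dm1[nd] + net_out(nd) * c_in
      for (nd in g$outlets) dm1[nd] <- dm1[nd] + net_out(nd) * c1[nd]
    }
    ## 1D diffusion (explicit)
    if (D1 > 0) {
      for (s in seq_len(nseg)) {
        f <- D1 * Aseg[s] / L[s] *
          (c1[g$segments$n1[s]] - c1[g$segments$n2[s]])
        dm1[g$segments$n1[s]] <- dm1[g$segments$n1[s]] - f
        dm1[g$segments$n2[s]] <- dm1[g$segments$n2[s]] + f
      }
    }
    dm3 <- numeric(nc)
    ## wall exchange (antisymmetric, mass conserving)
    if (eta_w > 0) {
      for (s in seq_len(nseg)) {
        ss <- sam[[s]]
        c1s <- (1 - ss$xi) * c1[g$segments$n1[s]] +
          ss$xi * c1[g$segments$n2[s]]
        ex <- eta_w * 2 * pi * R[s] * ss$w * (c1s - c3[ss$cells])
        dm3[ss$cells] <- dm3[ss$cells] + ex
        half <- sum(ex) / 2
        dm1[g$segments$n1[s]] <- dm1[g$segments$n1[s]] - half
        dm1[g$segments$n2[s]] <- dm1[g$segments$n2[s]] - half
      }
    }
    ## tissue upwind advection
    if (!is.null(vel)) {
      nx <- dom$grid[1]; ny <- dom$grid[2]; nz <- dom$grid[3]
      v <- vel$v_cell
      carr <- array(c3, dim = dom$grid)
      for (axis in 1:3) {
        va <- array(v[, axis], dim = dom$grid)
        n <- dom$grid[axis]
        if (n < 2) next
        idall <- list(seq_len(nx), seq_len(ny), seq_len(nz))
        lo <- idall; lo[[axis]] <- seq_len(n - 1)
        hi <- idall; hi[[axis]] <- seq_len(n - 1) + 1
        vface <- 0.5 * (va[lo[[1]], lo[[2]], lo[[3]], drop = FALSE] +
                        va[hi[[1]], hi[[2]], hi[[3]], drop = FALSE])
        cup <- ifelse(vface > 0,
                      carr[lo[[1]], lo[[2]], lo[[3]], drop = FALSE],
                      carr[hi[[1]], hi[[2]], hi[[3]], drop = FALSE])
        farea <- prod(dom$h[-axis])
        flx <- vface * cup * farea
        dmarr <- array(0, dim = dom$grid)
        dmarr[lo[[1]], lo[[2]], lo[[3]]] <-
          dmarr[lo[[1]], lo[[2]], lo[[3]]] - flx
        dmarr[hi[[1]], hi[[2]], hi[[3]]] <-
          dmarr[hi[[1]], hi[[2]], hi[[3]]] + flx
        dm3 <- dm3 + as.numeric(dmarr)
      }
    }
    c1 <- c1 + dt * dm1 / pmax(V1, 1e-300)
    c3 <- c3 + dt * dm3 / V3
    if (!is.null(Mdiff)) c3 <- as.numeric(Matrix::solve(Mdiff, c3))
  }
  list(c1 = c1, c3 = c3, mass0 = mass0,
       mass1 = sum(c1 * V1) + sum(c3) * V3)
}

#' Scale capillary radii (vasomotion feedback)
#'
#' Multiplies segment radii by per-segment (or scalar) factors; axial
#' conductance follows the configured law (Poiseuille K1 proportional to
#' R^2, so segment conductance scales with R^4).
#'
#' @param g \code{capillary_graph}.
#' @param factors positive scalar or per-segment vector.
#' @return modified graph.
#' @export
apply_radius_modulation <- function(g, factors) {
  stopifnot(all(factors > 0))
  g$segments$radius_um <- g$segments$radius_um * factors
  g
}
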