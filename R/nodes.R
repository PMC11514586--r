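# Negative-energy grid points that are local minima within their full
# 26-neighbourhood (border padded with +Inf). Returned sorted by flat grid
# index (x fastest), which is the documented tie-break order.
field_candidates <- function(field) {
  arr <- field$energies
  d <- dim(arr)
  pad <- array(Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  is_min <- array(TRUE, d)
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    if (ox == 0 && oy == 0 && oz == 0) next
    nb <- pad[(2 + ox):(d[1] + 1 + ox), (2 + oy):(d[2] + 1 + oy),
              (2 + oz):(d[3] + 1 + oz)]
    is_min <- is_min & (arr <= nb)
  }
  idx <- which(is_min & arr < 0)
  if (length(idx) == 0)
    return(tibble(flat = integer(), x = numeric(), y = numeric(),
                  z = numeric(), energy = numeric()))
  ijk <- arrayInd(idx, d)
  g <- field$grid
  tibble(flat = idx,
         x = g$origin[1] + (ijk[, 1] - 1) * g$spacing,
         y = g$origin[2] + (ijk[, 2] - 1) * g$spacing,
         z = g$origin[3] + (ijk[, 3] - 1) * g$spacing,
         energy = arr[idx]) |>
    arrange(.data$flat)
}

# Merge refined candidates that fell into the same basin: greedy clustering
# by ascending energy with a 0.25 A radius; keeps the deepest representative.
dedup_nodes <- function(tbl, radius = 0.25) {
  if (nrow(tbl) <= 1) return(tbl)
  ord <- order(tbl$energy, tbl$flat)
  keep <- integer()
  for (i in ord) {
    if (length(keep) > 0) {
      dmin <- min(sqrt((tbl$x[keep] - tbl$x[i])^2 + (tbl$y[keep] - tbl$y[i])^2 +
                       (tbl$z[keep] - tbl$z[i])^2))
      if (dmin < radius) next
    }
    keep <- c(keep, i)
  }
  tbl[sort(keep), ]
}

#' Greedy node selection
#'
#' Picks up to `n_nodes` candidates: the first is the global energy minimum;
#' each subsequent node maximises
#' `w * |E|/|E_min| + (1 - w) * d_nearest_selected / d_max`, where `d_max`
#' is the largest pairwise distance among the candidates (a
#' rotation-invariant normaliser). Ties break to the lowest candidate index
#' (grid flat index when candidates come from a field).
#'
#' @param candidates Tibble with columns `x`, `y`, `z`, `energy` (< 0), in
#'   tie-break order.
#' @param n_nodes Maximum number of nodes.
#' @param w Energy-vs-coverage weight in `[0, 1]`.
#' @return The selected rows (selection order), same columns.
#' @export
select_nodes <- function(candidates, n_nodes = 100, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  m <- nrow(candidates)
  if (m == 0) return(candidates)
  if (m <= n_nodes) n_take <- m else n_take <- n_nodes
  xyz <- as.matrix(candidates[, c("x", "y", "z")])
  e_rel <- abs(candidates$energy) / max(abs(candidates$energy))
  d_max <- if (m > 1) max(stats::dist(xyz)) else 1
  if (d_max <= 0) d_max <- 1
  first <- which.min(candidates$energy)  # which.min takes the lowest index on ties
  sel <- first
  if (n_take > 1) {
    dnear <- sqrt(colSums((t(xyz) - xyz[first, ])^2))
    for (k in 2:n_take) {
      score <- w * e_rel + (1 - w) * (dnear / d_max)
      score[sel] <- -Inf
      nxt <- which.max(score)
      sel <- c(sel, nxt)
      dnear <- pmin(dnear, sqrt(colSums((t(xyz) - xyz[nxt, ])^2)))
    }
  }
  candidates[sel, ]
}

#' Extract field nodes for one probe
#'
#' Finds favourable (negative-energy) local minima of a probe field and
#' selects a representative subset by the greedy distance/intensity rule.
#' For the smooth probes (DRY/O/N1) each grid minimum is by default refined
#' by continuous minimisation of the analytic energy so that node positions
#' do not inherit the grid's orientation - this is what makes the
#' downstream correlogram descriptors alignment-independent.
#'
#' @param field A `field` from [compute_field()].
#' @param mol The molecule the field was computed from (required for
#'   refinement; omit to keep raw grid nodes).
#' @param n_nodes Maximum nodes to keep (default 100).
#' @param w Greedy score weight (default 0.5), see [select_nodes()].
#' @param refine Refine node positions off-grid (default TRUE when `mol`
#'   given; never for TIP).
#' @param params Probe parameters.
#' @return Tibble with columns `probe`, `x`, `y`, `z`, `energy`.
#' @export
extract_nodes <- function(field, mol = NULL, n_nodes = 100, w = 0.5,
                          refine = !is.null(mol),
                          params = load_probe_params()) {
  cand <- field_candidates(field)
  if (nrow(cand) == 0) {
    warn(sprintf("%s field has no negative-energy points; empty node set",
                 field$probe_id))
    return(tibble(probe = character(), x = numeric(), y = numeric(),
                  z = numeric(), energy = numeric()))
  }
  if (refine && field$probe_id != "TIP") {
    if (is.null(mol)) abort("refinement needs the molecule; pass mol =")
    ap <- field_atom_params(mol, field$probe_id, params)
    ref <- cpp_refine_nodes(as.matrix(cand[, c("x", "y", "z")]),
                            ap$xyz, ap$qa, ap$eps, ap$rmin, ap$hb_depth,
                            ap$hb_dir, ap$qp, ap$hb_r0, ap$hb_sigma, ap$clamp)
    cand$x <- ref$coords[, 1]; cand$y <- ref$coords[, 2]
    cand$z <- ref$coords[, 3]; cand$energy <- ref$energy
    cand <- dedup_nodes(cand[cand$energy < 0, ])
  }
  sel <- select_nodes(cand, n_nodes = n_nodes, w = w)
  tibble(probe = field$probe_id, x = sel$x, y = sel$y, z = sel$z,
         energy = sel$energy)
}

# Frame-free multistart seeds for continuous node discovery. Seeds are
# anchored to the molecular geometry only (inter-atom axes, local plane
# normals, donor/acceptor axes), so the seed cloud rotates rigidly with the
# molecule and the discovered stationary points - hence the descriptors -
# are exactly alignment-independent. Grid-based candidates, by contrast,
# inherit the grid orientation.
node_seeds <- function(mol, radii = c(2.6, 3.4, 4.2)) {
  xyz <- atom_coords(mol)
  n <- nrow(xyz)
  seeds <- list()
  push <- function(p) seeds[[length(seeds) + 1]] <<- p
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) NULL else v / nv
  }
  # pairwise axes: outward continuations of every close atom-atom axis
  d2 <- as.matrix(stats::dist(xyz))
  for (a in seq_len(n)) {
    near <- which(d2[a, ] > 0 & d2[a, ] < 7)
    for (b in near) {
      u <- unit(xyz[a, ] - xyz[b, ])
      if (is.null(u)) next
      for (r in radii) push(xyz[a, ] + r * u)
    }
  }
  # local plane normals (above/below rings and sp2 centres)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  for (a in seq_len(n)) {
    if (length(nb[[a]]) >= 2) {
      v1 <- xyz[nb[[a]][1], ] - xyz[a, ]
      v2 <- xyz[nb[[a]][2], ] - xyz[a, ]
      nrm <- unit(c(v1[2] * v2[3] - v1[3] * v2[2],
                    v1[3] * v2[1] - v1[1] * v2[3],
                    v1[1] * v2[2] - v1[2] * v2[1]))
      if (!is.null(nrm)) for (r in c(3.0, 3.8)) {
        push(xyz[a, ] + r * nrm)
        push(xyz[a, ] - r * nrm)
      }
    }
  }
  # donor / acceptor axes at H-bond geometry
  if (!all(is.na(mol$atoms$hba))) {
    for (role in c("donor", "acceptor")) {
      dirs <- hb_directions(mol, role)
      for (a in seq_len(n)) {
        u <- unit(dirs[a, ])
        if (!is.null(u)) for (r in c(2.4, 2.9, 3.4)) push(xyz[a, ] + r * u)
      }
    }
  }
  S <- do.call(rbind, seeds)
  # deterministic thinning (order is frame-free: seed construction order)
  keep <- rep(TRUE, nrow(S))
  for (i in seq_len(nrow(S))) {
    if (!keep[i]) next
    if (i < nrow(S)) {
      later <- (i + 1):nrow(S)
      dd <- sqrt(colSums((t(S[later, , drop = FALSE]) - S[i, ])^2))
      keep[later[dd < 0.4]] <- FALSE
    }
  }
  S[keep, , drop = FALSE]
}

# Continuous node discovery for one smooth probe: refine every geometric
# seed into its local basin, keep favourable stationary points, merge
# duplicates. Stationary points with near-zero Hessian curvature (flat
# troughs, e.g. the rim of a symmetric ring) are discarded: their positions
# are numerically ill-defined, and the minimum Hessian eigenvalue is a
# rotation-invariant stability criterion, so the surviving node set is
# identical in any molecular frame.
probe_nodes_analytic <- function(mol, probe_id, params = load_probe_params(),
                                 seeds = node_seeds(mol),
                                 min_curvature = 0.03) {
  ap <- field_atom_params(mol, probe_id, params)
  ref <- cpp_refine_nodes(seeds, ap$xyz, ap$qa, ap$eps, ap$rmin, ap$hb_depth,
                          ap$hb_dir, ap$qp, ap$hb_r0, ap$hb_sigma, ap$clamp)
  lam <- apply(ref$hessian, 1, function(hc) {
    H <- matrix(c(hc[1], hc[4], hc[5],
                  hc[4], hc[2], hc[6],
                  hc[5], hc[6], hc[3]), 3, 3)
    min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  })
  tb <- tibble(flat = seq_len(nrow(seeds)), x = ref$coords[, 1],
               y = ref$coords[, 2], z = ref$coords[, 3], energy = ref$energy,
               is_minimum = ref$is_minimum, lambda_min = lam) |>
    filter(.data$energy < 0, .data$is_minimum,
           .data$lambda_min > min_curvature)
  dedup_nodes(tb)
}

#' Analytic TIP (shape) nodes
#'
#' Steric hot-spot pseudo-nodes placed on the van der Waals surface: one
#' point per atom, offset outward along the atom-to-centroid axis, kept only
#' when surface-exposed (not buried inside another atom). Unlike the TIP
#' shell field on a grid, these positions are exactly rotation-equivariant,
#' so the TIP correlogram blocks are alignment-independent.
#'
#' @param mol A [molecule()].
#' @param offset Shell offset above the vdW radius (Angstrom, default 0.25
#'   = half the default grid spacing).
#' @param n_nodes Maximum nodes (spatially spread greedy subset if more).
#' @param w Greedy score weight used when capping.
#' @return Tibble with columns `probe`, `x`, `y`, `z`, `energy` (-1).
#' @export
tip_nodes <- function(mol, offset = 0.25, n_nodes = 100, w = 0.5) {
  xyz <- atom_coords(mol)
  rv <- unname(vdw_radii[mol$atoms$element])
  ctr <- colMeans(xyz)
  pts <- matrix(NA_real_, 0, 3)
  for (a in seq_len(nrow(xyz))) {
    u <- xyz[a, ] - ctr
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) next
    p <- xyz[a, ] + (rv[a] + offset) * u / nu
    d <- sqrt(colSums((t(xyz) - p)^2)) - rv
    d[a] <- Inf
    if (all(d >= 0)) pts <- rbind(pts, p)
  }
  if (nrow(pts) == 0)
    return(tibble(probe = character(), x = numeric(), y = numeric(),
                  z = numeric(), energy = numeric()))
  cand <- tibble(flat = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
                 z = pts[, 3], energy = -1)
  sel <- select_nodes(cand, n_nodes = n_nodes, w = w)
  tibble(probe = "TIP", x = sel$x, y = sel$y, z = sel$z, energy = sel$energy)
}

#' Compute all probe node sets for one molecule
#'
#' Returns one node table for the four probes. DRY/O/N1 nodes are the
#' favourable stationary points of the analytic probe energy, discovered by
#' multistart local minimisation from molecule-anchored seeds and capped by
#' the greedy distance/intensity selection; TIP nodes come from the
#' analytic surface construction (see [tip_nodes()]). Both constructions
#' are exactly rotation-equivariant, which is what makes the GRIND encoding
#' alignment-independent end to end. (Grid-seeded extraction of the same
#' stationary points is available per field via [extract_nodes()].)
#'
#' @param mol Typed, charged [molecule()].
#' @param spacing Grid spacing; sets the TIP shell offset (`spacing/2`).
#' @param margin Unused in the analytic route; kept for config symmetry.
#' @param n_nodes Per-probe node cap (default 100).
#' @param w Greedy selection weight (default 0.5).
#' @param params Probe parameters.
#' @return Tibble of nodes for all four probes with attribute `"id"`.
#' @export
molecule_nodes <- function(mol, spacing = 0.5, margin = 5.0, n_nodes = 100,
                           w = 0.5, params = load_probe_params()) {
  seeds <- node_seeds(mol)
  nodes <- bind_rows(lapply(c("DRY", "O", "N1"), function(p) {
    cand <- probe_nodes_analytic(mol, p, params, seeds)
    if (nrow(cand) == 0)
      return(tibble(probe = character(), x = numeric(), y = numeric(),
                    z = numeric(), energy = numeric()))
    sel <- select_nodes(cand, n_nodes = n_nodes, w = w)
    tibble(probe = p, x = sel$x, y = sel$y, z = sel$z, energy = sel$energy)
  }))
  nodes <- bind_rows(nodes, tip_nodes(mol, offset = spacing / 2,
                                      n_nodes = n_nodes, w = w))
  attr(nodes, "id") <- mol$id
  nodes
}

#' Export nodes as a PDB pseudo-atom file for visualisation
#'
#' @param nodes Node tibble from [molecule_nodes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nodes_pdb <- function(nodes, path) {
  el <- c(DRY = "C", O = "O", N1 = "N", TIP = "S")
  lines <- sprintf(
    "HETATM%5d %-4s NOD A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(nodes)), el[nodes$probe], seq_len(nrow(nodes)),
    nodes$x, nodes$y, nodes$z, 1, abs(nodes$energy), el[nodes$probe])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
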