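#' Load probe and force-field parameters
#'
#' Parameters live in a flat `key=value` text file; the packaged default is
#' `system.file("extdata", "probe_params.txt", package = "grindqsar")`. See
#' that file for the energy model constants (Lennard-Jones table, probe
#' charges, H-bond well geometry, clamp).
#'
#' @param path Optional path to an alternative parameter file.
#' @return A named list of numeric/character values.
#' @export
load_probe_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "probe_params.txt", package = "grindqsar")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- map_chr(kv, 1)
  vals <- map_chr(kv, 2)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) trimws(v) else num
  })
  setNames(out, trimws(keys))
}

probe_ids <- c("DRY", "O", "N1", "TIP")

pget <- function(params, key, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) {
    if (is.null(default)) abort(sprintf("missing parameter '%s'", key))
    default
  } else v
}

# Per-atom energy-term inputs for one probe, consumed by the C++ kernel.
# Validates that charges/typing are present where the probe needs them.
field_atom_params <- function(mol, probe_id, params) {
  probe_id <- match.arg(probe_id, probe_ids)
  check_elements(mol)
  el <- mol$atoms$element
  n <- length(el)
  if (probe_id == "TIP")
    return(list(xyz = atom_coords(mol), rvdw = unname(vdw_radii[el])))
  if (all(is.na(mol$atoms$hba)))
    abort("pharmacophore types missing: run assign_pharmacophore_types() first")
  qp <- pget(params, sprintf("probe.%s.charge", probe_id))
  if (qp != 0 && anyNA(mol$atoms$charge))
    abort("partial charges missing: run assign_partial_charges() first")
  eps_el <- map_dbl(el, function(e) pget(params, sprintf("element.%s.eps", e)))
  rmin_el <- map_dbl(el, function(e) pget(params, sprintf("element.%s.rmin", e)))
  eps <- sqrt(eps_el * pget(params, sprintf("probe.%s.eps", probe_id)))
  rmin <- rmin_el + pget(params, sprintf("probe.%s.rmin", probe_id))
  if (probe_id == "DRY") {
    hs <- pget(params, "probe.DRY.hydrophobic_scale", 3)
    ps <- pget(params, "probe.DRY.polar_scale", 0.5)
    eps <- eps * ifelse(isTRUE_vec(mol$atoms$hydrophobic), hs, ps)
  }
  role <- pget(params, sprintf("probe.%s.hb_role", probe_id), "none")
  hb_depth <- rep(0, n)
  hb_dir <- matrix(0, n, 3)
  if (role == "acceptor") {        # probe accepts: wells on donor atoms
    hb_depth[isTRUE_vec(mol$atoms$hbd)] <- pget(params, sprintf("probe.%s.hb_depth", probe_id))
    hb_dir <- hb_directions(mol, "donor")
  } else if (role == "donor") {    # probe donates: wells on acceptor atoms
    hb_depth[isTRUE_vec(mol$atoms$hba)] <- pget(params, sprintf("probe.%s.hb_depth", probe_id))
    hb_dir <- hb_directions(mol, "acceptor")
  }
  list(xyz = atom_coords(mol),
       qa = ifelse(is.na(mol$atoms$charge), 0, mol$atoms$charge),
       eps = eps, rmin = rmin, hb_depth = hb_depth, hb_dir = hb_dir,
       qp = qp,
       hb_r0 = pget(params, sprintf("probe.%s.hb_r0", probe_id), 2.9),
       hb_sigma = pget(params, sprintf("probe.%s.hb_sigma", probe_id), 0.4),
       clamp = pget(params, "clamp", 5))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Probe interaction energy at arbitrary points
#'
#' Evaluates the analytic probe-molecule interaction energy (the same
#' function sampled by [compute_field()]) at arbitrary Cartesian points.
#'
#' @param mol Typed, charged [molecule()].
#' @param probe_id One of `"DRY"`, `"O"`, `"N1"` (the TIP shell is only
#'   defined relative to a grid spacing; see [compute_field()]).
#' @param points Numeric n x 3 matrix of coordinates (Angstrom).
#' @param params Parameter list from [load_probe_params()].
#' @return Numeric vector of energies (kcal/mol).
#' @export
probe_energy <- function(mol, probe_id, points, params = load_probe_params()) {
  if (probe_id == "TIP")
    abort("the TIP shell field is grid-based; use compute_field()")
  ap <- field_atom_params(mol, probe_id, params)
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_probe_energy(points, ap$xyz, ap$qa, ap$eps, ap$rmin, ap$hb_depth,
                   ap$hb_dir, ap$qp, ap$hb_r0, ap$hb_sigma, ap$clamp)
}
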