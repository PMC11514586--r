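#' Assign pharmacophore atom types
#'
#' Flags every atom as hydrogen-bond acceptor (`hba`), hydrogen-bond donor
#' (`hbd`) and/or hydrophobic, from the bond graph alone. These flags drive
#' the probe fields: the N1 (amide-nitrogen, donor) probe is attracted to
#' acceptors, the O (carbonyl-oxygen, acceptor) probe to donors, and the DRY
#' probe to hydrophobic carbons.
#'
#' Rules (deterministic in the graph, permutation-invariant):
#' * N or O with an available lone pair (not positively charged, fewer than
#'   four connections) is an acceptor; a hydroxyl O is both acceptor and
#'   donor.
#' * N or O bonded to at least one explicit hydrogen is a donor. Hydrogens
#'   must be explicit in the input; the reader never adds them.
#' * Carbon not bonded to N, O or S is hydrophobic.
#' * Sulfur is neither donor, acceptor nor hydrophobe unless
#'   `sulfur = "polar"` (acceptor when it has a lone pair).
#'
#' @param mol A [molecule()] with bonds present.
#' @param sulfur `"inert"` (default) or `"polar"`.
#' @return The molecule with `hba`, `hbd`, `hydrophobic` filled in.
#' @export
assign_pharmacophore_types <- function(mol, sulfur = c("inert", "polar")) {
  sulfur <- match.arg(sulfur)
  check_elements(mol)
  if (nrow(mol$atoms) > 1 && nrow(mol$bonds) == 0)
    abort(sprintf("molecule '%s': bonds are required for pharmacophore typing", mol$id))
  el <- mol$atoms$element
  n <- length(el)
  nb <- vector("list", n)          # neighbour indices
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  degree <- lengths(nb)
  fc <- mol$atoms$formal_charge
  has_h <- map_lgl(nb, function(ix) any(el[ix] == "H"))
  neigh_el <- function(ix) el[nb[[ix]]]

  hba <- rep(FALSE, n); hbd <- rep(FALSE, n); hyd <- rep(FALSE, n)
  for (a in seq_len(n)) {
    if (el[a] %in% c("N", "O")) {
      if (fc[a] <= 0 && degree[a] < 4) hba[a] <- TRUE
      if (has_h[a]) hbd[a] <- TRUE
      # donor-only nitrogen with a full valence shell (e.g. quaternary/charged)
      if (el[a] == "N" && fc[a] > 0) hba[a] <- FALSE
    } else if (el[a] == "C") {
      hyd[a] <- !any(neigh_el(a) %in% c("N", "O", "S"))
    } else if (el[a] == "S" && sulfur == "polar") {
      if (fc[a] <= 0 && degree[a] <= 2) hba[a] <- TRUE
      if (has_h[a]) hbd[a] <- TRUE
    }
  }
  mol$atoms$hba <- hba
  mol$atoms$hbd <- hbd
  mol$atoms$hydrophobic <- hyd
  mol
}

# Donor/acceptor axis per atom, used for the directional H-bond weight.
# Donors: mean unit vector towards bonded hydrogens (where the proton
# points). Acceptors: opposite of the mean unit vector towards heavy
# neighbours (where the lone pair points). Zero rows mean "no preferred
# direction" and give weight 1 in the energy. `role` picks which axis is
# built (an hydroxyl O is both donor and acceptor).
hb_directions <- function(mol, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  el <- mol$atoms$element
  xyz <- atom_coords(mol)
  n <- nrow(xyz)
  dir <- matrix(0, n, 3)
  nb <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) c(0, 0, 0) else v / nv
  }
  for (a in seq_len(n)) {
    if (role == "donor" && isTRUE(mol$atoms$hbd[a])) {
      hs <- nb[[a]][el[nb[[a]]] == "H"]
      if (length(hs) > 0) {
        v <- colSums(matrix(xyz[hs, , drop = FALSE], ncol = 3)) / length(hs) - xyz[a, ]
        dir[a, ] <- unit(v)
      }
    } else if (role == "acceptor" && isTRUE(mol$atoms$hba[a])) {
      heavy <- nb[[a]][el[nb[[a]]] != "H"]
      if (length(heavy) > 0) {
        v <- xyz[a, ] - colSums(matrix(xyz[heavy, , drop = FALSE], ncol = 3)) / length(heavy)
        dir[a, ] <- unit(v)
      }
    }
  }
  dir
}
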