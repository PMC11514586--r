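#' Construct a molecule
#'
#' A molecule is the unit of every structure-based computation in grindqsar:
#' an ordered atom table (element, 3D coordinates in Angstrom, optional
#' partial charge and pharmacophore flags), a bond table, and optional
#' activity annotations (pIC50 and a structural-cluster label).
#'
#' @param id Compound identifier (single string).
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`, `formal_charge`, `hydrophobic`, `hba`, `hbd`.
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2, 3, or 4 for aromatic). May have zero rows.
#' @param activity Optional pIC50 (numeric scalar, -log10 molar IC50).
#' @param cluster Optional structural cluster label (e.g. `"I"`..`"IV"`).
#'
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = NULL, activity = NA_real_,
                     cluster = NA_character_) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) < 1L) abort("a molecule needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort(sprintf("molecule '%s': non-finite coordinates", id))
  for (col in c("charge")) if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  for (col in c("hydrophobic", "hba", "hbd"))
    if (!col %in% names(atoms)) atoms[[col]] <- NA
  if (is.null(bonds)) bonds <- tibble(i = integer(), j = integer(), order = integer())
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    ok <- bonds$i >= 1 & bonds$i <= nrow(atoms) & bonds$j >= 1 & bonds$j <= nrow(atoms)
    if (!all(ok)) abort(sprintf("molecule '%s': bond indices out of range", id))
  }
  if (!is.na(activity) && (!is.finite(activity)))
    abort(sprintf("molecule '%s': activity must be finite", id))
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         activity = as.numeric(activity), cluster = as.character(cluster)),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s>  %d atoms, %d bonds", x$id, nrow(x$atoms), nrow(x$bonds)))
  if (!is.na(x$activity)) cat(sprintf(", pIC50 %.2f", x$activity))
  if (!is.na(x$cluster)) cat(sprintf(", cluster %s", x$cluster))
  cat("\n")
  typed <- !all(is.na(x$atoms$hba))
  charged <- !all(is.na(x$atoms$charge))
  cat(sprintf("  pharmacophore types: %s; partial charges: %s\n",
              if (typed) "assigned" else "not assigned",
              if (charged) "assigned" else "not assigned"))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param mol A [molecule()].
#' @return Numeric n x 3 matrix.
#' @export
atom_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Apply a rigid-body transform to a molecule
#'
#' Rotates atom coordinates by `rotation` and then translates them. Used to
#' probe the alignment independence of the descriptor pipeline: GRIND
#' variables are built from internal node distances only, so a rigid motion
#' of the input must leave them unchanged.
#'
#' @param mol A [molecule()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 numeric translation (Angstrom).
#' @return The transformed molecule (typing/charges preserved).
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  xyz <- atom_coords(mol) %*% t(rotation)
  mol$atoms$x <- xyz[, 1] + translation[1]
  mol$atoms$y <- xyz[, 2] + translation[2]
  mol$atoms$z <- xyz[, 3] + translation[3]
  mol
}

#' Random rotation matrix
#'
#' Uniform random rotation built from a QR decomposition of a Gaussian
#' matrix (sign-corrected to determinant +1).
#'
#' @param seed Optional integer seed (set before drawing; not restored).
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

elements_known <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# Bondi-style van der Waals radii (Angstrom), used by the TIP shape probe
# and the grid clamp region.
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

check_elements <- function(mol) {
  bad <- setdiff(unique(mol$atoms$element), elements_known)
  if (length(bad) > 0)
    abort(sprintf("molecule '%s': unknown element(s): %s",
                  mol$id, paste(bad, collapse = ", ")))
  invisible(TRUE)
}
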