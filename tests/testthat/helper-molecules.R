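# Small real molecules built in code (idealised coordinates, Angstrom).

mol_methane <- function() {
  molecule("methane", tibble::tibble(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, 0.629, -0.629, 0.629, -0.629),
    y = c(0, 0.629, -0.629, -0.629, 0.629),
    z = c(0, 0.629, 0.629, -0.629, -0.629)),
    tibble::tibble(i = 1L, j = 2:5, order = 1L))
}

mol_benzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  atoms <- tibble::tibble(
    element = rep(c("C", "H"), each = 6),
    x = c(1.39 * cos(ang), 2.47 * cos(ang)),
    y = c(1.39 * sin(ang), 2.47 * sin(ang)),
    z = 0)
  bonds <- tibble::tibble(
    i = c(1:6, 1:6),
    j = c(2:6, 1L, 7:12),
    order = c(rep(4L, 6), rep(1L, 6)))
  molecule("benzene", atoms, bonds)
}

mol_pyridine <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  atoms <- tibble::tibble(
    element = c("N", rep("C", 5), rep("H", 5)),
    x = c(1.35 * cos(ang), 2.45 * cos(ang[-1])),
    y = c(1.35 * sin(ang), 2.45 * sin(ang[-1])),
    z = 0)
  bonds <- tibble::tibble(
    i = c(1:6, 2:6),
    j = c(2:6, 1L, 7:11),
    order = c(rep(4L, 6), rep(1L, 5)))
  molecule("pyridine", atoms, bonds)
}

mol_acetamide <- function() {
  molecule("acetamide", tibble::tibble(
    element = c("C", "C", "O", "N", "H", "H", "H", "H", "H"),
    x = c(0, 1.52, 2.15, 2.16, 3.16, 1.67, -0.4, -0.4, -0.4),
    y = c(0, 0, 1.1, -1.19, -1.24, -2.05, 0.51, 0.51, -1.02),
    z = c(0, 0, 0, 0, 0, 0, 0.89, -0.89, 0)),
    tibble::tibble(i = c(1L, 2L, 2L, 4L, 4L, 1L, 1L, 1L),
                   j = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                   order = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)))
}

mol_formaldehyde <- function() {
  molecule("formaldehyde", tibble::tibble(
    element = c("C", "O", "H", "H"),
    x = c(0, 1.21, -0.54, -0.54),
    y = c(0, 0, 0.94, -0.94),
    z = 0),
    tibble::tibble(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                   order = c(2L, 1L, 1L)))
}

mol_acetate <- function() {
  molecule("acetate", tibble::tibble(
    element = c("C", "C", "O", "O", "H", "H", "H"),
    x = c(0, 1.53, 2.15, 2.13, -0.4, -0.4, -0.4),
    y = c(0, 0, 1.09, -1.1, 0.51, 0.51, -1.02),
    z = c(0, 0, 0, 0, 0.89, -0.89, 0),
    formal_charge = c(0L, 0L, 0L, -1L, 0L, 0L, 0L)),
    tibble::tibble(i = c(1L, 2L, 2L, 1L, 1L, 1L),
                   j = c(2L, 3L, 4L, 5L, 6L, 7L),
                   order = c(1L, 2L, 1L, 1L, 1L, 1L)))
}

prepared <- function(mol) assign_partial_charges(assign_pharmacophore_types(mol))

# A random full-rank regression instance for PLS oracle tests.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("V%d", 1:p)))
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta + rnorm(n, sd = 0.5))
  list(X = X, y = y)
}

# Least-squares oracle: intercept + slopes by normal equations.
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(crossprod(Xi), crossprod(Xi, y)))
}
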