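point_mol <- function(q = 0, element = "C") {
  m <- molecule("pt", tibble::tibble(element = element, x = 0, y = 0, z = 0))
  m$atoms$charge <- q
  m$atoms$hba <- FALSE; m$atoms$hbd <- FALSE; m$atoms$hydrophobic <- FALSE
  m
}

test_that("grid construction follows the bounding-box arithmetic", {
  g <- build_grid(point_mol(), spacing = 0.5, margin = 5)
  expect_equal(g$shape, rep(21L, 3))          # 2*5/0.5 + 1
  g2 <- build_grid(point_mol(), spacing = 1, margin = 5)
  expect_equal(g2$shape, rep(11L, 3))
  two <- molecule("two", tibble::tibble(element = c("C", "C"),
                                        x = c(0, 4), y = 0, z = 0))
  g3 <- build_grid(two, spacing = 0.5, margin = 5)
  expect_equal(g3$shape[1], 29L)              # extent 14 A on x
  expect_error(build_grid(point_mol(), spacing = 0), "spacing")
})

test_that("electrostatic term matches the printed dielectric formula", {
  # q_atom = +1, probe charge -1, eps(r) = 4r, r = 3: E = 332.0636/(4*3^2)
  m <- point_mol(q = 1)
  p <- load_probe_params()
  p[["probe.N1.charge"]] <- -1
  p[["probe.N1.eps"]] <- 0        # LJ off
  p[["probe.N1.hb_role"]] <- "none"
  e <- probe_energy(m, "N1", matrix(c(3, 0, 0), 1), p)
  expect_equal(e, -332.0636 / (4 * 9), tolerance = 1e-6)
})

test_that("fields decay to zero far from the molecule", {
  m <- prepared(mol_acetamide())
  pts <- matrix(c(25, 0, 0, 0, 30, 0, -20, -20, 10), 3, 3, byrow = TRUE)
  for (probe in c("DRY", "O", "N1"))
    expect_true(all(abs(probe_energy(m, probe, pts)) < 0.01))
})

test_that("benzene DRY minima lie above and below the ring plane", {
  m <- prepared(mol_benzene())
  fld <- compute_field(m, "DRY", build_grid(m, spacing = 0.5, margin = 5))
  idx <- arrayInd(which.min(fld$energies), dim(fld$energies))
  zmin <- fld$grid$origin[3] + (idx[3] - 1) * fld$grid$spacing
  expect_gt(abs(zmin), 2)   # off-plane (ring is at z = 0)
  # and in-plane points at the same radius are less favourable
  in_plane <- probe_energy(m, "DRY", matrix(c(0, 0, 0), 1))
  above <- probe_energy(m, "DRY", matrix(c(0, 0, abs(zmin)), 1))
  expect_lt(above, in_plane)
})

test_that("fields are equivariant under joint translation of molecule and grid", {
  m <- prepared(mol_acetamide())
  g <- build_grid(m, spacing = 1.0, margin = 4)
  f0 <- compute_field(m, "O", g)
  shift <- c(3.5, -2.25, 1.0)
  mt <- transform_molecule(m, diag(3), shift)
  gt <- g; gt$origin <- g$origin + shift
  f1 <- compute_field(mt, "O", gt)
  expect_equal(f1$energies, f0$energies, tolerance = 1e-9)
})

test_that("pairwise-additive fields superpose", {
  p <- load_probe_params()
  p[["probe.O.hb_role"]] <- "none"   # H-bond off: strictly pairwise
  a <- point_mol(q = 0.3, element = "C")
  b <- point_mol(q = -0.2, element = "N")
  b$atoms$x <- 2.5
  ab <- molecule("ab", rbind(a$atoms, b$atoms))
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  e_ab <- probe_energy(ab, "O", pts, p)
  e_sum <- probe_energy(a, "O", pts, p) + probe_energy(b, "O", pts, p)
  expect_equal(e_ab, e_sum, tolerance = 1e-9)
})

test_that("energies are clamped inside atoms and TIP is a -1 surface shell", {
  m <- prepared(mol_methane())
  expect_equal(probe_energy(m, "DRY", matrix(0, 1, 3))[1], 5)
  g <- build_grid(m, spacing = 0.5, margin = 4)
  tip <- compute_field(m, "TIP", g)
  expect_true(all(tip$energies %in% c(-1, 0)))
  expect_true(any(tip$energies == -1))
  # shell points sit within one spacing of the vdW surface
  pts <- grindqsar:::grid_points(g)
  shell <- pts[as.vector(tip$energies) == -1, , drop = FALSE]
  dmin <- apply(shell, 1, function(p)
    min(sqrt(colSums((t(atom_coords(m)) - p)^2)) -
          grindqsar:::vdw_radii[m$atoms$element]))
  expect_true(all(dmin >= 0 & dmin < g$spacing))
})

test_that("cube files round-trip", {
  g <- structure(list(origin = c(-1, -2, 0.5), spacing = 0.5,
                      shape = c(2L, 2L, 2L)), class = "grid_spec")
  f0 <- structure(list(grid = g, probe_id = "DRY",
                       energies = array(0, dim = c(2, 2, 2))), class = "field")
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(f0, path)
  back <- read_cube(path)
  expect_equal(back$energies, f0$energies)
  expect_equal(back$grid$origin, g$origin, tolerance = 1e-6)

  m <- prepared(mol_formaldehyde())
  f <- compute_field(m, "N1", build_grid(m, spacing = 1, margin = 3))
  write_cube(f, path)
  b2 <- read_cube(path)
  expect_equal(b2$probe_id, "N1")
  expect_equal(length(b2$energies), prod(f$grid$shape))
  expect_equal(b2$energies, f$energies, tolerance = 1e-4)
  expect_equal(b2$grid$origin, f$grid$origin, tolerance = 1e-6)
})

test_that("charged probes refuse molecules without assigned charges", {
  m <- assign_pharmacophore_types(mol_acetamide())
  expect_error(compute_field(m, "N1"), "assign_partial_charges")
})
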