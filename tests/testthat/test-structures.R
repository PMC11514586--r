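test_that("SDF round-trip preserves records, coordinates and properties", {
  mols <- list(mol_methane(), mol_acetamide())
  mols[[1]]$activity <- 5.37
  mols[[1]]$cluster <- "I"
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "methane")
  expect_equal(nrow(back[[1]]$atoms), 5)
  expect_equal(nrow(back[[1]]$bonds), 4)
  expect_equal(back[[1]]$activity, 5.37)
  expect_equal(back[[1]]$cluster, "I")
  for (k in 1:2) {
    expect_equal(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_equal(atom_coords(back[[k]]), atom_coords(mols[[k]]),
                 tolerance = 1e-4)
  }
  # second write of the re-read molecules is byte-identical
  path2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed SDF input fails with the record index", {
  m <- mol_methane()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, path)
  lines <- readLines(path)
  # drop one bond line -> truncated bond block in record 1
  truncated <- lines[-7]
  path_bad <- withr::local_tempfile(fileext = ".sdf")
  writeLines(truncated, path_bad)
  expect_error(read_sdf(path_bad), "record 1")
  # corrupt the counts line
  lines2 <- lines
  lines2[4] <- " xx  4  0  0  0  0  0  0  0  0999 V2000"
  writeLines(lines2, path_bad)
  expect_error(read_sdf(path_bad), "counts")
})

test_that("pharmacophore typing follows the donor/acceptor/hydrophobe rules", {
  py <- assign_pharmacophore_types(mol_pyridine())
  expect_true(py$atoms$hba[py$atoms$element == "N"])
  expect_false(py$atoms$hbd[py$atoms$element == "N"])

  bz <- assign_pharmacophore_types(mol_benzene())
  expect_true(all(bz$atoms$hydrophobic[bz$atoms$element == "C"]))
  expect_false(any(bz$atoms$hba))

  ac <- assign_pharmacophore_types(mol_acetamide())
  expect_true(ac$atoms$hbd[4])   # amide N-H
  expect_true(ac$atoms$hba[3])   # carbonyl O
  expect_false(ac$atoms$hydrophobic[2])  # carbonyl C bonded to N and O
  expect_true(ac$atoms$hydrophobic[1])   # methyl C

  expect_error(
    assign_pharmacophore_types(
      molecule("x", tibble::tibble(element = c("C", "Xx"), x = 0:1, y = 0, z = 0),
               tibble::tibble(i = 1L, j = 2L, order = 1L))),
    "Xx")
})

test_that("typing is invariant to atom permutation", {
  m <- mol_acetamide()
  set.seed(5)
  perm <- sample(nrow(m$atoms))
  inv <- order(perm)
  mp <- molecule("perm", m$atoms[perm, ],
                 tibble::tibble(i = inv[m$bonds$i], j = inv[m$bonds$j],
                                order = m$bonds$order))
  t1 <- assign_pharmacophore_types(m)$atoms
  t2 <- assign_pharmacophore_types(mp)$atoms
  for (col in c("hba", "hbd", "hydrophobic"))
    expect_identical(t2[[col]], t1[[col]][perm])
})

test_that("partial charges conserve the net formal charge", {
  q <- assign_partial_charges(mol_methane())$atoms$charge
  expect_equal(sum(q), 0, tolerance = 1e-6)
  qa <- assign_partial_charges(mol_acetate())$atoms$charge
  expect_equal(sum(qa), -1, tolerance = 1e-6)
})

test_that("formaldehyde charges have the reference Gasteiger signs", {
  # sign layout verified against an independent PEOE implementation on the
  # same graph: carbonyl C positive, O negative, H slightly positive
  m <- assign_partial_charges(mol_formaldehyde())
  q <- m$atoms$charge
  expect_gt(q[1], 0)
  expect_lt(q[2], 0)
  expect_true(all(q[3:4] > 0))
  # magnitudes in the reference ballpark (C ~ +0.11, O ~ -0.31)
  expect_equal(q[1], 0.106, tolerance = 0.05)
  expect_equal(q[2], -0.307, tolerance = 0.05)
})

test_that("activity table round-trips through CSV", {
  tbl <- tibble::tibble(id = c("a", "b"), pIC50 = c(5.1, 7.3),
                        cluster = c("I", "II"), set = c("train", "test"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_activity(tbl, path)
  expect_equal(as.data.frame(read_activity(path)), as.data.frame(tbl))
})
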