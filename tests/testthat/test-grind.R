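# Brute-force re-implementation of the greedy node-selection rule.
greedy_oracle <- function(cand, n_nodes, w) {
  xyz <- as.matrix(cand[, c("x", "y", "z")])
  d_max <- max(dist(xyz))
  e_rel <- abs(cand$energy) / max(abs(cand$energy))
  sel <- which(cand$energy == min(cand$energy))[1]
  while (length(sel) < min(n_nodes, nrow(cand))) {
    best <- NA; best_score <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (i %in% sel) next
      dn <- min(sqrt(rowSums((xyz[sel, , drop = FALSE] -
                                matrix(xyz[i, ], length(sel), 3, byrow = TRUE))^2)))
      score <- w * e_rel[i] + (1 - w) * dn / d_max
      if (score > best_score + 1e-12) { best <- i; best_score <- score }
    }
    sel <- c(sel, best)
  }
  sel
}

test_that("greedy node selection matches the brute-force rule", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(5:12, 1)
    cand <- tibble::tibble(flat = 1:m, x = runif(m, 0, 10), y = runif(m, 0, 10),
                           z = runif(m, 0, 10), energy = -runif(m, 0.1, 5))
    for (w in c(0, 0.5, 1)) {
      n_take <- sample(2:m, 1)
      got <- select_nodes(cand, n_nodes = n_take, w = w)
      expect_equal(got$flat, cand$flat[greedy_oracle(cand, n_take, w)])
    }
  }
})

test_that("node extraction finds isolated wells", {
  # single acceptor atom -> one deep N1 well along the lone-pair axis
  m <- prepared(mol_pyridine())
  fld <- compute_field(m, "N1", build_grid(m, spacing = 0.5, margin = 5))
  nodes <- extract_nodes(fld, mol = m, n_nodes = 1)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$energy, min(nodes$energy))
  # the node refines close to the 2.9 A H-bond distance from the ring N
  n_xyz <- as.matrix(m$atoms[m$atoms$element == "N", c("x", "y", "z")])
  d <- sqrt(sum((c(nodes$x, nodes$y, nodes$z) - n_xyz)^2))
  expect_lt(abs(d - 2.9), 0.5)

  # two equal wells far apart are both selected for any w
  g <- structure(list(origin = c(-10, -2, -2), spacing = 1,
                      shape = c(21L, 5L, 5L)), class = "grid_spec")
  arr <- array(0, dim = g$shape)
  arr[3, 3, 3] <- -2; arr[19, 3, 3] <- -2
  fld2 <- structure(list(grid = g, probe_id = "DRY", energies = arr),
                    class = "field")
  nodes2 <- extract_nodes(fld2, n_nodes = 2, refine = FALSE)
  expect_equal(nrow(nodes2), 2)
  expect_equal(sort(nodes2$x), c(-8, 8))

  # all-positive field -> empty set with a warning
  arr0 <- array(1, dim = g$shape)
  fld3 <- structure(list(grid = g, probe_id = "DRY", energies = arr0),
                    class = "field")
  expect_warning(out <- extract_nodes(fld3, refine = FALSE), "no negative")
  expect_equal(nrow(out), 0)
})

test_that("correlogram encoding: single pair, empty probe, bin bookkeeping", {
  nodes <- generate_toy_nodes(c("DRY", "DRY"), c(0, 5), c(0, 0), c(0, 0),
                              c(-2, -3))
  v <- encode_correlogram(nodes, bin_width = 0.4, max_distance = 25)
  expect_equal(unname(v[meta_to_index("DRY-DRY", 13)]), 6)  # [4.8, 5.2)
  dd <- v[variable_meta()$block == "DRY-DRY"]
  expect_equal(sum(dd != 0), 1)
  # probes with no nodes leave all their blocks at zero
  meta <- variable_meta()
  for (bl in c("O-O", "N1-TIP", "DRY-O"))
    expect_true(all(v[meta$block == bl] == 0))
})

test_that("every cross-block bin equals the brute-force max over node pairs", {
  set.seed(7)
  for (rep in 1:25) {
    nd <- sample(3:6, 1); nn <- sample(2:5, 1)
    nodes <- generate_toy_nodes(
      probe = rep(c("DRY", "N1"), c(nd, nn)),
      x = runif(nd + nn, 0, 20), y = runif(nd + nn, 0, 20),
      z = runif(nd + nn, 0, 20), energy = -runif(nd + nn, 0.1, 5))
    v <- encode_correlogram(nodes, bin_width = 0.4, max_distance = 25)
    A <- nodes[nodes$probe == "DRY", ]; B <- nodes[nodes$probe == "N1", ]
    oracle <- numeric(grindqsar:::n_grind_bins(0.4, 25))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
      b <- floor(d / 0.4) + 1
      if (b <= length(oracle))
        oracle[b] <- max(oracle[b], A$energy[i] * B$energy[j])
    }
    got <- unname(v[variable_meta()$block == "DRY-N1"])
    expect_equal(got, oracle)
  }
})

test_that("auto-block excludes self-pairs and uses each unordered pair once", {
  nodes <- generate_toy_nodes(rep("O", 3), c(0, 3, 3), c(0, 0, 4), c(0, 0, 0),
                              c(-1, -2, -4))
  v <- encode_correlogram(nodes)
  # pairs: d(1,2)=3 (prod 2), d(2,3)=4 (prod 8), d(1,3)=5 (prod 4)
  expect_equal(unname(v[meta_to_index("O-O", 8)]), 2)   # [2.8,3.2)
  expect_equal(unname(v[meta_to_index("O-O", 11)]), 8)  # [4.0,4.4)
  expect_equal(unname(v[meta_to_index("O-O", 13)]), 4)  # [4.8,5.2)
  expect_equal(sum(v != 0), 3)
})

test_that("variable indexing is the declared bijection", {
  meta <- variable_meta(0.4, 25)
  expect_equal(nrow(meta), 620)                     # 62 bins x 10 blocks
  first <- variable_lookup(1)
  expect_equal(first$block, "DRY-DRY")
  expect_equal(c(first$bin_lo, first$bin_hi), c(0, 0.4))
  ks <- c(1, 62, 63, 337, 620)
  for (k in ks) {
    mt <- variable_lookup(k)
    expect_equal(meta_to_index(mt$block, mt$bin), k)
  }
  expect_error(variable_lookup(0), "range")
  expect_error(variable_lookup(621), "range")
  # the variable the interpretation names: DRY-N1 13.2-13.6
  idx <- meta_to_index("DRY-N1", floor(13.2 / 0.4 + 1e-9) + 1)
  mt <- variable_lookup(idx)
  expect_equal(c(mt$bin_lo, mt$bin_hi), c(13.2, 13.6))
})

test_that("encoding is invariant under rigid motion of the nodes", {
  set.seed(11)
  n <- 12
  nodes <- generate_toy_nodes(
    probe = sample(c("DRY", "O", "N1", "TIP"), n, replace = TRUE),
    x = runif(n, 0, 15), y = runif(n, 0, 15), z = runif(n, 0, 15),
    energy = -runif(n, 0.5, 5))
  v0 <- encode_correlogram(nodes)
  R <- random_rotation()
  xyz <- as.matrix(nodes[, c("x", "y", "z")]) %*% t(R)
  moved <- nodes
  moved$x <- xyz[, 1] + 4.2; moved$y <- xyz[, 2] - 1.3; moved$z <- xyz[, 3] + 9
  v1 <- encode_correlogram(moved)
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("increasing max_distance appends columns without changing values", {
  set.seed(3)
  nodes <- generate_toy_nodes(rep(c("DRY", "O"), each = 4),
                              runif(8, 0, 18), runif(8, 0, 18), runif(8, 0, 18),
                              -runif(8, 0.5, 3))
  v_small <- encode_correlogram(nodes, max_distance = 12)
  v_big <- encode_correlogram(nodes, max_distance = 25)
  meta_small <- variable_meta(0.4, 12)
  meta_big <- variable_meta(0.4, 25)
  shared <- match(meta_small$name, meta_big$name)
  expect_equal(unname(v_big[shared]), unname(v_small))
})

test_that("every descriptor value is a product of two stored node energies", {
  m <- prepared(mol_acetamide())
  nodes <- molecule_nodes(m, n_nodes = 20)
  v <- encode_correlogram(nodes)
  prods <- outer(nodes$energy, nodes$energy)
  for (val in v[v != 0])
    expect_true(any(abs(prods - val) < 1e-9))
})
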