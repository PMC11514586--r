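#' Correlogram block order
#'
#' The ten ordered probe pairs over {DRY, O, N1, TIP}: the four
#' auto-correlogram blocks first, then the six cross blocks.
#' @return Character vector of block labels (e.g. `"DRY-N1"`).
#' @export
grind_blocks <- function() {
  c("DRY-DRY", "O-O", "N1-N1", "TIP-TIP",
    "DRY-O", "DRY-N1", "DRY-TIP", "O-N1", "O-TIP", "N1-TIP")
}

n_grind_bins <- function(bin_width = 0.4, max_distance = 25) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  as.integer(floor(max_distance / bin_width + 1e-9))
}

#' GRIND variable metadata
#'
#' One row per descriptor variable: consecutive `index`, probe-pair `block`,
#' distance bin `[bin_lo, bin_hi)` and the column `name` used in descriptor
#' tables (`"DRY-N1_13.2_13.6"`). Blocks appear in [grind_blocks()] order;
#' bins ascend within a block, so `index = block_offset + bin_number`.
#'
#' @param bin_width Bin width in Angstrom (default 0.4; 0.8 matches a wider
#'   smoothing-window convention).
#' @param max_distance Maximum node-pair distance considered (default 25).
#' @return Tibble with columns `index`, `block`, `bin`, `bin_lo`, `bin_hi`,
#'   `name`.
#' @export
variable_meta <- function(bin_width = 0.4, max_distance = 25) {
  nb <- n_grind_bins(bin_width, max_distance)
  blocks <- grind_blocks()
  tibble(
    index = seq_len(nb * length(blocks)),
    block = rep(blocks, each = nb),
    bin = rep(seq_len(nb), times = length(blocks)),
    bin_lo = rep((seq_len(nb) - 1) * bin_width, times = length(blocks)),
    bin_hi = rep(seq_len(nb) * bin_width, times = length(blocks))
  ) |>
    mutate(name = sprintf("%s_%g_%g", .data$block, .data$bin_lo, .data$bin_hi))
}

#' Look up a GRIND variable by index
#' @param index Variable index (1-based).
#' @inheritParams variable_meta
#' @return One-row tibble of metadata.
#' @export
variable_lookup <- function(index, bin_width = 0.4, max_distance = 25) {
  meta <- variable_meta(bin_width, max_distance)
  if (any(index < 1 | index > nrow(meta)))
    abort(sprintf("variable index out of range 1..%d", nrow(meta)))
  meta[index, ]
}

#' Index of a GRIND variable from block and bin
#' @param block Block label (e.g. `"DRY-N1"`).
#' @param bin Bin number within the block (1-based).
#' @inheritParams variable_meta
#' @return Integer index.
#' @export
meta_to_index <- function(block, bin, bin_width = 0.4, max_distance = 25) {
  nb <- n_grind_bins(bin_width, max_distance)
  bi <- match(block, grind_blocks())
  if (anyNA(bi)) abort(sprintf("unknown block: %s", block[is.na(bi)][1]))
  if (any(bin < 1 | bin > nb)) abort(sprintf("bin out of range 1..%d", nb))
  as.integer((bi - 1L) * nb + bin)
}

#' Encode one molecule's nodes as a GRIND correlogram row
#'
#' MACC2-style maximum auto/cross-correlation transform: for every probe
#' pair and distance bin `[k bw, (k+1) bw)`, the descriptor is the largest
#' product of node energies over node pairs whose distance falls in that
#' bin (0 when no pair does). Node energies are negative, so products are
#' non-negative; larger values mean two intense interaction hot spots at
#' that separation.
#'
#' @param nodes Node tibble (columns `probe`, `x`, `y`, `z`, `energy`), as
#'   from [molecule_nodes()].
#' @param bin_width,max_distance Binning parameters, see [variable_meta()].
#' @return Named numeric vector of length `10 * n_bins`, names as in
#'   [variable_meta()].
#' @export
encode_correlogram <- function(nodes, bin_width = 0.4, max_distance = 25) {
  nb <- n_grind_bins(bin_width, max_distance)
  meta <- variable_meta(bin_width, max_distance)
  out <- setNames(numeric(nrow(meta)), meta$name)
  by_probe <- split(nodes, nodes$probe)
  for (bl in grind_blocks()) {
    pr <- strsplit(bl, "-", fixed = TRUE)[[1]]
    A <- by_probe[[pr[1]]]; B <- by_probe[[pr[2]]]
    if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0) next
    d2 <- outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 + outer(A$z, B$z, "-")^2
    prod_e <- outer(A$energy, B$energy)
    if (pr[1] == pr[2]) {
      keep <- upper.tri(d2)            # i != j, each unordered pair once
      d <- sqrt(d2[keep]); pe <- prod_e[keep]
    } else {
      d <- sqrt(as.vector(d2)); pe <- as.vector(prod_e)
    }
    bin <- floor(d / bin_width) + 1
    ok <- bin >= 1 & bin <= nb
    if (!any(ok)) next
    mx <- tapply(pe[ok], bin[ok], max)
    idx <- meta_to_index(bl, as.integer(names(mx)), bin_width, max_distance)
    out[idx] <- pmax(out[idx], mx)
  }
  out
}

#' GRIND descriptor matrix for a set of molecules
#'
#' Runs the full descriptor stage (grid, four probe fields, node extraction,
#' correlogram encoding) for each molecule and assembles the
#' compounds-by-variables table.
#'
#' @param mols List of typed, charged [molecule()]s.
#' @param spacing,margin Grid parameters.
#' @param n_nodes,w Node extraction parameters.
#' @param bin_width,max_distance Correlogram binning parameters.
#' @param params Probe parameters.
#' @param verbose Print one line per molecule.
#' @return A tibble with an `id` column followed by one column per GRIND
#'   variable; attribute `"meta"` carries the [variable_meta()] table.
#' @export
grind_descriptors <- function(mols, spacing = 0.5, margin = 5.0,
                              n_nodes = 100, w = 0.5, bin_width = 0.4,
                              max_distance = 25,
                              params = load_probe_params(), verbose = FALSE) {
  meta <- variable_meta(bin_width, max_distance)
  rows <- lapply(mols, function(m) {
    if (verbose) inform(sprintf("descriptors: %s", m$id))
    nodes <- molecule_nodes(m, spacing = spacing, margin = margin,
                            n_nodes = n_nodes, w = w, params = params)
    encode_correlogram(nodes, bin_width = bin_width, max_distance = max_distance)
  })
  X <- do.call(rbind, rows)
  out <- bind_cols(tibble(id = map_chr(mols, "id")), as_tibble(X))
  attr(out, "meta") <- meta
  out
}

# Numeric matrix (rows = compounds) from a descriptor tibble.
descriptor_matrix <- function(desc) {
  X <- as.matrix(desc[, setdiff(names(desc), "id"), drop = FALSE])
  rownames(X) <- desc$id
  X
}

#' Write / read a descriptor table as CSV
#' @param desc Descriptor tibble from [grind_descriptors()].
#' @param path CSV path.
#' @return `path` (write) or the descriptor tibble (read).
#' @export
write_descriptors <- function(desc, path) {
  readr::write_csv(desc, path)
  invisible(path)
}

#' @rdname write_descriptors
#' @param bin_width,max_distance Binning parameters used to rebuild the
#'   metadata attribute on read.
#' @export
read_descriptors <- function(path, bin_width = 0.4, max_distance = 25) {
  out <- readr::read_csv(path, show_col_types = FALSE) |>
    mutate(id = as.character(.data$id))
  attr(out, "meta") <- variable_meta(bin_width, max_distance)
  out
}
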