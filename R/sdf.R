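#' Read molecules from a V2000 SDF file
#'
#' Parses a (possibly multi-record) MDL SD file in V2000 connection-table
#' format. Coordinates are taken verbatim; no hydrogens are added and no
#' protonation-state adjustment is performed - the input 3D structure is
#' treated as authoritative.
#'
#' @param path Path to the SDF file.
#' @param activity_prop Name of the SDF data item holding the pIC50 value
#'   (default `"pIC50"`). Missing items leave the activity `NA`.
#' @param cluster_prop Name of the SDF data item holding the structural
#'   cluster label (default `"cluster"`).
#' @return A list of [molecule()] objects, in file order.
#' @export
read_sdf <- function(path, activity_prop = "pIC50", cluster_prop = "cluster") {
  if (!file.exists(path)) abort(sprintf("SDF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # split records on $$$$ delimiters
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  mols <- vector("list", length(starts))
  kept <- 0L
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:min(ends[k], length(lines))]
    rec <- rec[trimws(rec) != "$$$$"]
    if (all(trimws(rec) == "")) next
    kept <- kept + 1L
    mols[[kept]] <- parse_sdf_record(rec, k)
  }
  mols[seq_len(kept)] |>
    lapply(function(m) {
      props <- attr(m, "sdf_properties")
      if (!is.null(props[[activity_prop]]))
        m$activity <- suppressWarnings(as.numeric(props[[activity_prop]][1]))
      if (!is.null(props[[cluster_prop]]))
        m$cluster <- as.character(props[[cluster_prop]][1])
      m
    })
}

parse_sdf_record <- function(rec, record_index) {
  if (length(rec) < 4)
    abort(sprintf("SDF record %d: truncated header block", record_index))
  title <- trimws(rec[1])
  counts <- rec[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1)
    abort(sprintf("SDF record %d: malformed counts line '%s'",
                  record_index, counts))
  if (length(rec) < 4 + natoms + nbonds)
    abort(sprintf("SDF record %d: truncated atom/bond block (expected %d atoms, %d bonds)",
                  record_index, natoms, nbonds))
  atom_lines <- rec[5:(4 + natoms)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  element <- trimws(substr(atom_lines, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z) || any(element == ""))
    abort(sprintf("SDF record %d: malformed atom block", record_index))
  bonds <- tibble(i = integer(), j = integer(), order = integer())
  if (nbonds > 0) {
    bond_lines <- rec[(5 + natoms):(4 + natoms + nbonds)]
    bi <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    if (anyNA(bi) || anyNA(bj) || anyNA(bo) ||
        any(bi < 1 | bi > natoms | bj < 1 | bj > natoms))
      abort(sprintf("SDF record %d: malformed bond block", record_index))
    bonds <- tibble(i = bi, j = bj, order = bo)
  }
  # M CHG property lines override implicit zero formal charges
  formal <- rep(0L, natoms)
  rest <- rec[-seq_len(4 + natoms + nbonds)]
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    fields <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nn <- fields[1]
    for (q in seq_len(nn)) formal[fields[2 * q]] <- fields[2 * q + 1]
  }
  props <- parse_sdf_properties(rest)
  id <- if (nzchar(title)) title else sprintf("mol_%d", record_index)
  m <- molecule(
    id = id,
    atoms = tibble(element = element, x = x, y = y, z = z,
                   formal_charge = formal),
    bonds = bonds
  )
  attr(m, "sdf_properties") <- props
  m
}

parse_sdf_properties <- function(lines) {
  props <- list()
  idx <- grep("^>\\s*<", lines)
  for (i in idx) {
    name <- sub("^>\\s*<([^>]+)>.*$", "\\1", lines[i])
    vals <- character()
    j <- i + 1
    while (j <= length(lines) && nzchar(trimws(lines[j]))) {
      vals <- c(vals, trimws(lines[j]))
      j <- j + 1
    }
    props[[name]] <- vals
  }
  props
}

#' Write molecules to a V2000 SDF file
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output path.
#' @param properties Named character vector mapping SDF data-item names to
#'   molecule fields (`"activity"`, `"cluster"`); items with `NA` values are
#'   skipped. Default writes `pIC50` and `cluster`.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path,
                      properties = c(pIC50 = "activity", cluster = "cluster")) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  out <- character()
  for (m in mols) {
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    rec <- c(
      m$id, "  grindqsar", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              m$atoms$x, m$atoms$y, m$atoms$z, m$atoms$element)
    )
    if (nb > 0)
      rec <- c(rec, sprintf("%3d%3d%3d  0", m$bonds$i, m$bonds$j, m$bonds$order))
    chg <- which(m$atoms$formal_charge != 0L)
    if (length(chg) > 0)
      rec <- c(rec, paste0("M  CHG", sprintf("%3d", length(chg)),
                           paste0(sprintf("%4d%4d", chg, m$atoms$formal_charge[chg]),
                                  collapse = "")))
    rec <- c(rec, "M  END")
    for (pname in names(properties)) {
      val <- m[[properties[[pname]]]]
      if (length(val) == 1 && !is.na(val))
        rec <- c(rec, sprintf(">  <%s>", pname), format(val, digits = 10), "")
    }
    out <- c(out, rec, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an activity table
#'
#' The activity table is a CSV with columns `id`, `pIC50`, `cluster`, `set`
#' (`set` in train/test/unassigned). Missing `cluster`/`set` columns are
#' filled with defaults.
#'
#' @param path CSV path.
#' @return A tibble with columns `id`, `pIC50`, `cluster`, `set`.
#' @export
read_activity <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "pIC50") %in% names(tbl)))
    abort("activity table must have columns 'id' and 'pIC50'")
  if (!"cluster" %in% names(tbl)) tbl$cluster <- NA_character_
  if (!"set" %in% names(tbl)) tbl$set <- "unassigned"
  as_tibble(tbl[, c("id", "pIC50", "cluster", "set")]) |>
    mutate(id = as.character(.data$id), cluster = as.character(.data$cluster))
}

#' Write an activity table
#' @param tbl Tibble with columns `id`, `pIC50`, `cluster`, `set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_activity <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}
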