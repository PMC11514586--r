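BOHR <- 0.52917721067  # Angstrom per Bohr

#' Write a field as a Gaussian cube file
#'
#' Standard cube layout: two comment lines (the second carries the probe
#' id), origin and axis records in Bohr, one placeholder atom record, then
#' energies with the z index varying fastest.
#'
#' @param field A `field` from [compute_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path) {
  g <- field$grid
  hdr <- c(
    "grindqsar molecular interaction field",
    sprintf("probe %s energies kcal/mol", field$probe_id),
    sprintf("%5d%12.6f%12.6f%12.6f", 1L,
            g$origin[1] / BOHR, g$origin[2] / BOHR, g$origin[3] / BOHR),
    sprintf("%5d%12.6f%12.6f%12.6f", g$shape[1], g$spacing / BOHR, 0, 0),
    sprintf("%5d%12.6f%12.6f%12.6f", g$shape[2], 0, g$spacing / BOHR, 0),
    sprintf("%5d%12.6f%12.6f%12.6f", g$shape[3], 0, 0, g$spacing / BOHR),
    sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1L, 0, 0, 0, 0)  # placeholder atom
  )
  # z fastest within x,y
  vals <- as.vector(aperm(field$energies, c(3, 2, 1)))
  rows <- split(vals, ceiling(seq_along(vals) / 6))
  body <- map_chr(rows, function(v) paste(sprintf("%13.5E", v), collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path Cube file path.
#' @return A `field` object (coordinates converted back to Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  probe_id <- sub("^probe (\\S+).*$", "\\1", lines[2])
  parse_rec <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  rec3 <- parse_rec(lines[3])
  natoms <- as.integer(rec3[1])
  origin <- rec3[2:4] * BOHR
  ax <- lapply(4:6, function(i) parse_rec(lines[i]))
  shape <- as.integer(c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
  spacing <- ax[[1]][2] * BOHR
  data_lines <- lines[(7 + natoms):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  if (length(vals) != prod(shape))
    abort(sprintf("cube voxel count %d does not match header shape %d",
                  length(vals), prod(shape)))
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  structure(list(
    grid = structure(list(origin = origin, spacing = spacing, shape = shape),
                     class = "grid_spec"),
    probe_id = probe_id,
    energies = arr
  ), class = "field")
}
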