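## Plain-text interchange formats: PLUMED-style COLVAR/HILLS tables,
## pair-list TSV, bias grids, ensemble tables and PQR atom records.

#' Write a CV series as a PLUMED-style COLVAR table
#'
#' Header line `#! FIELDS time xi [xi_prime]`, whitespace-separated values.
#'
#' @param series a [cv_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(series, path) {
  cols <- intersect(c("time", "xi", "xi_prime"), names(series))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  write.table(format(series[, cols], digits = 10, trim = TRUE,
                     scientific = FALSE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# parse a "#! FIELDS ..." header; returns column names
read_plumed_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!grepl("^#!\\s*FIELDS", header))
    stop("not a PLUMED-style table (missing '#! FIELDS' header): ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", header), "\\s+")[[1L]]
  tab <- read.table(path, comment.char = "#", col.names = fields)
  tab
}

#' Read a COLVAR table written by [write_colvar()]
#'
#' @param path input path.
#' @return A [cv_series()].
#' @export
read_colvar <- function(path) {
  tab <- read_plumed_table(path)
  cv_series(tab$time, tab$xi, if ("xi_prime" %in% names(tab)) tab$xi_prime)
}

#' Write deposited hills as a HILLS-style table
#'
#' Header `#! FIELDS time center sigma height biasf`.
#'
#' @param bias a [bias_potential()] with at least one hill.
#' @param path output path.
#' @param biasf biasing factor recorded in the last column.
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path, biasf = NA_real_) {
  h <- bias$hills
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  tab <- data.frame(time = h$time, center = h$center, sigma = h$sigma,
                    height = h$height, biasf = biasf)
  write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a HILLS-style table into a bias potential
#'
#' @param path input path.
#' @return A [bias_potential()].
#' @export
read_hills <- function(path) {
  tab <- read_plumed_table(path)
  bias_potential(hills = data.frame(time = tab$time, center = tab$center,
                                    sigma = tab$sigma, height = tab$height))
}

#' Read / write hydrogen-bond pair lists as TSV
#'
#' Columns: `group`, `donor_resnum`, `donor_atom`, `acceptor_resnum`,
#' `acceptor_atom`.
#'
#' @param path file path.
#' @return [read_pairs()] returns an [hbond_pairs()] table.
#' @export
read_pairs <- function(path) {
  hbond_pairs(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_pairs
#' @param pairs an [hbond_pairs()] table to write.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a bias grid as two-column text
#'
#' Format: comment lines `# T <K>` and `# deltaT <K>` followed by
#' whitespace-separated `s V` rows.
#'
#' @param grid data frame with columns `s` and `V` (kJ/mol).
#' @param path file path.
#' @param T,deltaT temperatures recorded in the header (K).
#' @export
write_bias_grid <- function(grid, path, T = NA_real_, deltaT = NA_real_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# T", T), paste("# deltaT", deltaT), "# s V"), con)
  write.table(format(grid[, c("s", "V")], digits = 12, trim = TRUE,
                     scientific = FALSE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_grid
#' @return [read_bias_grid()] returns the grid data frame with attributes
#'   `T` and `deltaT` when present in the header.
#' @export
read_bias_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- read.table(text = lines[!startsWith(lines, "#")],
                    col.names = c("s", "V"))
  for (key in c("T", "deltaT")) {
    hit <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (length(hit))
      attr(tab, key) <- suppressWarnings(as.numeric(sub(".*\\s", "", hit[1L])))
  }
  tab
}

#' Read / write metastatistics ensemble tables
#'
#' Tab-separated tables with columns `time`, `walker`, `xi`, optionally
#' `xi_prime`, `energy` (kJ/mol), optional `multiplicity` and optional
#' per-term energy columns (`u_str`, `u_bend`, `u_tors`, `u_vdw`, `u_el`,
#' `g_solv_np`, `g_solv_pol`).
#'
#' @param path file path.
#' @return [read_ensemble()] returns a [metastatistics()] object.
#' @export
read_ensemble <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  metastatistics(tab)
}

#' @rdname read_ensemble
#' @param ms a [metastatistics()] table to write.
#' @export
write_ensemble <- function(ms, path) {
  write.table(as.data.frame(ms), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PQR file into a solute model
#'
#' PQR is whitespace-separated PDB: ATOM/HETATM records with occupancy and
#' B-factor replaced by per-atom charge (e) and radius (A).
#'
#' @param path input path.
#' @param sigma_default per-atom SASA coefficient attached to every atom
#'   (kJ/mol/A^2); override per atom afterwards if needed.
#' @return A [solute_model()].
#' @export
read_pqr <- function(path, sigma_default = 0.0226) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  parts <- strsplit(trimws(rec), "\\s+")
  get <- function(i) vapply(parts, `[[`, "", i)
  solute_model(data.frame(
    atom_id = as.integer(get(2L)),
    atom_name = get(3L),
    residue_name = get(4L),
    residue_number = as.integer(get(5L)),
    chain = "A",
    x = as.numeric(get(6L)), y = as.numeric(get(7L)),
    z = as.numeric(get(8L)),
    charge = as.numeric(get(9L)), radius = as.numeric(get(10L)),
    sigma = sigma_default,
    stringsAsFactors = FALSE))
}

#' Write a solute model as PQR
#'
#' @param model a [solute_model()].
#' @param path output path.
#' @export
write_pqr <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
    a$atom_id, a$atom_name, a$residue_name, a$residue_number,
    a$x, a$y, a$z, a$charge, a$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
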