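## Hydrogen-bond collective variable: structures, switching function,
## switched H-bond counts and CV histograms.

#' Construct a molecular structure from an atom table
#'
#' A `structure3d` is the package's light-weight container for one frame of
#' atomic coordinates: a data frame with one row per atom and columns
#' `atom_id`, `atom_name`, `residue_name`, `residue_number`, `chain`,
#' `x`, `y`, `z` (Angstrom) and optionally `charge` (e) and `radius` (A).
#'
#' @param atoms data frame with the columns above.
#' @param frame_time optional time stamp of the frame (ps).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, frame_time = NULL) {
  required <- c("atom_id", "atom_name", "residue_name", "residue_number",
                "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique within a structure")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  obj <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              frame_time = frame_time)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue_number)), "residues\n")
  invisible(x)
}

#' Read a PDB file into a structure
#'
#' Parses ATOM/HETATM records through [bio3d::read.pdb()].  For multi-model
#' files only the requested model is returned (model 1 by default); use
#' [load_frames()] to obtain every model as a separate frame.
#'
#' @param path path to a PDB file.
#' @param model model number to extract (1-based).
#' @return A [structure3d()] object.
#' @export
load_structure <- function(path, model = 1L) {
  frames <- load_frames(path)
  if (model < 1L || model > length(frames))
    stop("model ", model, " not present (file has ", length(frames), ")")
  frames[[model]]
}

#' Read every MODEL of a PDB file as a list of frames
#'
#' @param path path to a PDB file.
#' @return List of [structure3d()] objects, one per model.
#' @export
load_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop("no ATOM/HETATM records in ", path)
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    structure3d(data.frame(
      atom_id = a$eleno,
      atom_name = a$elety,
      residue_name = a$resid,
      residue_number = a$resno,
      chain = ifelse(is.na(a$chain), "A", a$chain),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE))
  })
}

#' Write a structure to a PDB file
#'
#' @param frame a [structure3d()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  a <- frame$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = a$atom_id, elety = a$atom_name,
                   chain = a$chain)
  invisible(path)
}

#' Switching-function parameters for the hydrogen-bond counter
#'
#' Rational switch `(1 - x^n)/(1 - x^m)` with `x = (r - d0)/r0`, continuously
#' extended to `n/m` at `x = 1`.  Defaults count a donor-N to acceptor-O
#' heavy-atom contact as formed below about 2.5 A and let it decay smoothly.
#'
#' @param r0 switching radius (A).
#' @param d0 offset distance (A).
#' @param n,m even positive integer exponents, `m > n`.
#' @return Object of class `switching_params`.
#' @export
switching_params <- function(r0 = 2.5, d0 = 0, n = 8L, m = 12L) {
  if (r0 <= 0) stop("r0 must be positive")
  if (n <= 0 || m <= n) stop("need m > n > 0")
  if (n %% 2L || m %% 2L) stop("n and m must be even")
  out <- list(r0 = r0, d0 = d0, n = as.integer(n), m = as.integer(m))
  class(out) <- "switching_params"
  out
}

#' Evaluate the rational switching function
#'
#' @param r distances (A), vectorized; must be non-negative.
#' @param p a [switching_params()] object.
#' @return Values in `[0, 1]`, monotonically non-increasing in `r` beyond
#'   `d0`.
#' @export
switching_value <- function(r, p = switching_params()) {
  if (any(r < 0)) stop("distances must be non-negative")
  x <- (r - p$d0) / p$r0
  x <- pmax(x, 0)                       # below d0 the contact is fully formed
  out <- numeric(length(x))
  # remove the 0/0 at x = 1 with the analytic limit n/m
  near1 <- abs(x - 1) < 1e-8
  out[near1] <- p$n / p$m
  xs <- x[!near1]
  out[!near1] <- (1 - xs^p$n) / (1 - xs^p$m)
  # guard against overflow at very large x: limit is x^(n-m) -> 0
  big <- !near1 & x > 1e6
  out[big] <- 0
  out
}

#' Hydrogen-bond pair list
#'
#' Validates a donor/acceptor pair table.  Selectors are
#' `(residue_number, atom_name)`; matching is by residue number and atom name
#' only (never residue name), so the same list applies to point variants
#' whose backbone N/O atoms are retained.
#'
#' @param pairs data frame with columns `group` (one of `"beta"`, `"alpha1"`,
#'   `"alpha2"`), `donor_resnum`, `donor_atom`, `acceptor_resnum`,
#'   `acceptor_atom`.
#' @return The validated data frame with class `hbond_pairs`.
#' @export
hbond_pairs <- function(pairs) {
  required <- c("group", "donor_resnum", "donor_atom",
                "acceptor_resnum", "acceptor_atom")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols))
    stop("pair table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(pairs$group %in% c("beta", "alpha1", "alpha2")))
    stop("group labels must be beta, alpha1 or alpha2")
  same <- pairs$donor_resnum == pairs$acceptor_resnum &
    pairs$donor_atom == pairs$acceptor_atom
  if (any(same)) stop("donor and acceptor selectors must differ")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  class(pairs) <- c("hbond_pairs", "data.frame")
  pairs
}

#' Native hydrogen-bond pairs of BPTI
#'
#' The 16 backbone donor-N / acceptor-O pairs defining the hydrogen-bond
#' collective variable of the 58-residue bovine pancreatic trypsin
#' inhibitor: 8 in the beta-sheet, 3 in helix alpha1 and 5 in helix alpha2,
#' so the CV spans 0 to 16.
#'
#' @return An [hbond_pairs()] table with 16 rows.
#' @export
bpti_hbond_pairs <- function() {
  tab <- rbind(
    data.frame(group = "beta",
               donor_resnum = c(35L, 18L, 33L, 20L, 31L, 22L, 29L, 24L),
               acceptor_resnum = c(18L, 35L, 20L, 33L, 22L, 31L, 24L, 29L)),
    data.frame(group = "alpha1",
               donor_resnum = c(5L, 6L, 7L),
               acceptor_resnum = c(2L, 3L, 4L)),
    data.frame(group = "alpha2",
               donor_resnum = c(52L, 53L, 54L, 54L, 55L),
               acceptor_resnum = c(48L, 49L, 50L, 51L, 51L)))
  tab$donor_atom <- "N"
  tab$acceptor_atom <- "O"
  hbond_pairs(tab[, c("group", "donor_resnum", "donor_atom",
                      "acceptor_resnum", "acceptor_atom")])
}

# resolve (residue_number, atom_name) selectors to atom row indices
resolve_selectors <- function(frame, resnums, atom_names) {
  a <- frame$atoms
  key <- paste(a$residue_number, a$atom_name)
  want <- paste(resnums, atom_names)
  idx <- match(want, key)
  dup <- duplicated(key) & key %in% want
  if (any(dup))
    stop("ambiguous selector(s): ", paste(unique(key[dup]), collapse = "; "))
  if (anyNA(idx))
    stop("unresolvable selector(s): ",
         paste(unique(want[is.na(idx)]), collapse = "; "))
  idx
}

# donor-acceptor distances for a pair table in a frame
pair_distances <- function(frame, pairs) {
  di <- resolve_selectors(frame, pairs$donor_resnum, pairs$donor_atom)
  ai <- resolve_selectors(frame, pairs$acceptor_resnum, pairs$acceptor_atom)
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  sqrt(rowSums((xyz[di, , drop = FALSE] - xyz[ai, , drop = FALSE])^2))
}

#' Switched hydrogen-bond count of a frame
#'
#' Sums the switching function over the donor-acceptor distances of the
#' requested groups, giving a continuous count in `[0, n_pairs]`.
#'
#' @param frame a [structure3d()].
#' @param pairs an [hbond_pairs()] table.
#' @param p a [switching_params()] object.
#' @param groups which groups to include (default all).
#' @return Dimensionless switched count.
#' @export
count_hbonds <- function(frame, pairs, p = switching_params(),
                         groups = c("beta", "alpha1", "alpha2")) {
  sel <- pairs$group %in% groups
  if (!any(sel)) return(0)
  sub <- pairs[sel, , drop = FALSE]
  sum(switching_value(pair_distances(frame, sub), p))
}

#' Base and extended hydrogen-bond collective variables
#'
#' `xi` counts only the beta-sheet pairs (the variable biased during
#' metadynamics in the reduced-CV setting); `xi_prime = xi + alpha` adds the
#' helical pairs and is the variable constrained in the entropy-reweighting
#' step.  When every group is part of the biased CV (the small-protein
#' setting) the two coincide by construction of the pair list.
#'
#' @inheritParams count_hbonds
#' @return Named numeric vector `c(xi = ..., xi_prime = ...)`, with
#'   `xi_prime >= xi`.
#' @export
extended_cv <- function(frame, pairs, p = switching_params()) {
  xi <- count_hbonds(frame, pairs, p, groups = "beta")
  alpha <- count_hbonds(frame, pairs, p, groups = c("alpha1", "alpha2"))
  c(xi = xi, xi_prime = xi + alpha)
}

#' Time series of a collective variable
#'
#' @param times frame times (ps).
#' @param xi per-frame CV values.
#' @param xi_prime optional extended CV values (must satisfy
#'   `xi_prime >= xi`).
#' @return Data frame of class `cv_series`.
#' @export
cv_series <- function(times, xi, xi_prime = NULL) {
  if (length(times) != length(xi)) stop("times and xi lengths differ")
  if (length(xi) == 0L) stop("empty CV series")
  if (!is.null(xi_prime)) {
    if (length(xi_prime) != length(xi)) stop("xi_prime length differs")
    if (any(xi_prime < xi - 1e-9)) stop("xi_prime must be >= xi")
  }
  out <- data.frame(time = times, xi = xi)
  if (!is.null(xi_prime)) out$xi_prime <- xi_prime
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Normalized histogram of a CV series
#'
#' @param series a [cv_series()] (or any data frame with an `xi` column), or
#'   a plain numeric vector of CV values.
#' @param bin_edges strictly increasing bin edges covering the data.
#' @param column which CV column to histogram when `series` is a data frame.
#' @return Data frame with bin `mid` points and probabilities `P` summing to
#'   one.
#' @export
cv_distribution <- function(series, bin_edges, column = "xi") {
  x <- if (is.data.frame(series)) series[[column]] else as.numeric(series)
  if (length(x) == 0L) stop("empty CV series")
  h <- hist(x, breaks = bin_edges, plot = FALSE)
  P <- h$counts / sum(h$counts)
  data.frame(mid = h$mids, P = P)
}
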