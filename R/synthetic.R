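## Synthetic fixtures: analytic landscapes, Boltzmann-style metastatistics
## ensembles with a known free-energy oracle, and toy peptides.  Every
## generator is a pure function of its seed.

#' Symmetric double-well toy landscape
#'
#' `F(s) = barrier * ((s - center)^2 / half_sep^2 - 1)^2 + tilt * (s - center)`,
#' shifted so that `min F = 0`.  With `tilt = 0` the minima sit exactly at
#' `center +/- half_sep` and the barrier at `center` equals `barrier`.
#'
#' @param barrier barrier height (kJ/mol).
#' @param center barrier location (CV units).
#' @param half_sep half the well separation (CV units).
#' @param tilt optional linear asymmetry (kJ/mol per CV unit).
#' @param domain reflecting-wall interval; defaults to
#'   `center +/- 2 * half_sep`.
#' @inheritParams toy_system
#' @return A [toy_system()] with attributes `minima` and `barrier`.
#' @export
make_double_well <- function(barrier = 15, center = 8, half_sep = 3,
                             tilt = 0, domain = NULL, friction = 2,
                             timestep = 0.02, temperature = 300,
                             s_init = NULL, seed = 1L) {
  if (barrier <= 0) stop("barrier must be positive")
  if (is.null(domain)) domain <- c(center - 2 * half_sep,
                                   center + 2 * half_sep)
  raw <- function(s) barrier * ((s - center)^2 / half_sep^2 - 1)^2 +
    tilt * (s - center)
  shift <- min(raw(seq(domain[1L], domain[2L], length.out = 4001L)))
  f <- function(s) raw(s) - shift
  df <- function(s) 4 * barrier * ((s - center)^2 / half_sep^2 - 1) *
    (s - center) / half_sep^2 + tilt
  if (is.null(s_init)) s_init <- center - half_sep
  sys <- toy_system(f, df, domain, friction, timestep, temperature,
                    s_init, seed)
  attr(sys, "minima") <- c(center - half_sep, center + half_sep)
  attr(sys, "barrier") <- barrier
  sys
}

#' Specification of a synthetic metastatistics ensemble
#'
#' The CV proposal is a bimodal truncated-Gaussian mixture emulating the
#' shape of a frozen-bias metastatistics (a sharp folded peak and a broad
#' unfolded one).  Frame energies follow
#' `U(xi) = energy_base(xi) + delta_stab * (s_folded - xi) / (s_folded - s_unfolded)`
#' plus Gaussian noise `sigma_E`.  Because the stability term is linear in
#' `xi`, its tilted average at any constraint `<xi> = s` is exactly
#' `delta_stab * (s_folded - s)/(s_folded - s_unfolded)`, so the injected
#' ddG between a `delta_stab` ensemble and a `delta_stab = 0` reference,
#' evaluated between `s_folded` and `s_unfolded`, is exactly `delta_stab`
#' in the infinite-sample limit (a built-in oracle).
#'
#' @param n_frames number of frames (>= 100).
#' @param n_walkers walker labels assigned round-robin.
#' @param sigma_E frame-level Gaussian energy noise (kJ/mol).
#' @param temperature simulation temperature (K).
#' @param proposal list with `means`, `sds`, `weights` of the mixture.
#' @param cv_range truncation interval of the CV.
#' @param energy_base baseline energy as a function of `xi` (kJ/mol).
#' @param delta_stab injected stability gap (kJ/mol; 0 for a reference).
#' @param s_folded,s_unfolded state conventions of the gap term.
#' @param seed RNG seed.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 1e5, n_walkers = 90L, sigma_E = 2,
                          temperature = 300,
                          proposal = list(means = c(4, 14),
                                          sds = c(1.5, 0.8),
                                          weights = c(0.5, 0.5)),
                          cv_range = c(0, 16),
                          energy_base = NULL,
                          delta_stab = 0, s_folded = 14, s_unfolded = 4,
                          seed = 1L) {
  if (n_frames < 100L) stop("n_frames must be at least 100")
  if (sigma_E < 0) stop("sigma_E must be non-negative")
  if (is.null(energy_base))
    energy_base <- function(xi) 3 * (s_folded - xi)
  out <- list(n_frames = as.integer(n_frames),
              n_walkers = as.integer(n_walkers), sigma_E = sigma_E,
              temperature = temperature, proposal = proposal,
              cv_range = cv_range, energy_base = energy_base,
              delta_stab = delta_stab, s_folded = s_folded,
              s_unfolded = s_unfolded, seed = as.integer(seed))
  class(out) <- "ensemble_spec"
  out
}

# mean energy of a frame at CV value xi (noise-free)
spec_energy_mean <- function(spec, xi) {
  spec$energy_base(xi) + spec$delta_stab * (spec$s_folded - xi) /
    (spec$s_folded - spec$s_unfolded)
}

# truncated-mixture density on a dense grid (the analytic proposal)
spec_density_grid <- function(spec, n_grid = 4001L) {
  s <- seq(spec$cv_range[1L], spec$cv_range[2L], length.out = n_grid)
  d <- rep(0, n_grid)
  pr <- spec$proposal
  for (k in seq_along(pr$means))
    d <- d + pr$weights[k] * dnorm(s, pr$means[k], pr$sds[k])
  d <- d / sum(d)
  list(s = s, p = d)
}

#' Exact large-sample MEC free energy of a synthetic ensemble
#'
#' Computes, by dense-grid quadrature on the analytic proposal density
#' (independently of any sampled frames), the value the constrained-entropy
#' free energy converges to as the number of frames grows:
#' the tilted mean energy minus `T kB` times the maximal cross-entropy at
#' the constraint `<xi> = s`.
#'
#' @param spec an [ensemble_spec()].
#' @param s target mean CV values (vectorized).
#' @param T_eff effective temperature (K); defaults to the spec's.
#' @return `G*(s)` in kJ/mol.
#' @export
g_star <- function(spec, s, T_eff = spec$temperature) {
  gr <- spec_density_grid(spec)
  u <- spec_energy_mean(spec, gr$s)
  logp <- log(gr$p)
  one <- function(si) {
    tilted <- function(lam) {
      lw <- logp - lam * (gr$s - si)         # exponent centered at si
      m <- max(lw)
      w <- exp(lw - m)
      list(w = w, m = m)
    }
    con <- function(lam) {
      tw <- tilted(lam)$w
      sum(tw * gr$s) / sum(tw) - si
    }
    lam <- uniroot(con, c(-80, 80), extendInt = "downX",
                   tol = 1e-12)$root
    tw <- tilted(lam)
    sc <- tw$m + log(sum(tw$w))              # = log Z + lam * si
    mean_u <- sum(tw$w * u) / sum(tw$w)
    mean_u - T_eff * kB_kJmolK * sc
  }
  vapply(s, one, numeric(1))
}

#' Sample a synthetic metastatistics ensemble
#'
#' Draws `n_frames` CV values from the spec's truncated mixture (rejection
#' on the truncation interval), attaches noisy energies and round-robin
#' walker labels.  Bitwise reproducible from the spec's seed.
#'
#' @param spec an [ensemble_spec()].
#' @return A [metastatistics()] with the spec stored in attribute `spec`.
#' @export
sample_metastatistics <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_frames
  pr <- spec$proposal
  xi <- numeric(0)
  while (length(xi) < n) {
    need <- n - length(xi)
    comp <- sample.int(length(pr$means), need, replace = TRUE,
                       prob = pr$weights)
    draw <- rnorm(need, pr$means[comp], pr$sds[comp])
    keep <- draw >= spec$cv_range[1L] & draw <= spec$cv_range[2L]
    xi <- c(xi, draw[keep])
  }
  energy <- spec_energy_mean(spec, xi)
  if (spec$sigma_E > 0) energy <- energy + rnorm(n, 0, spec$sigma_E)
  ms <- metastatistics(data.frame(
    time = seq_len(n), walker = rep_len(seq_len(spec$n_walkers), n),
    xi = xi, energy = energy))
  attr(ms, "spec") <- spec
  ms
}

#' Toy backbone peptide with a matching pair list and solute model
#'
#' Places backbone N and O atoms of `n_residues` residues along a strand.
#' In the `helix` geometry the acceptor O of residue `i` is put 1.2 A from
#' the donor N of residue `i + 2` -- well inside the default switching
#' radius -- so every listed pair counts as fully formed; in the
#' `extended` geometry each O stays near its own residue and all
#' donor-acceptor distances exceed 8 A.  Charges, radii and SASA
#' coefficients are populated with documented defaults (N: -0.30 e,
#' 1.55 A; O: -0.50 e, 1.52 A; sigma 0.0226 kJ/mol/A^2).
#'
#' @param n_residues number of residues (>= 3).
#' @param geometry `"helix"` or `"extended"`.
#' @param seed seed for the (tiny) coordinate jitter.
#' @return List with `structure` ([structure3d()]), `pairs`
#'   ([hbond_pairs()]) and `model` ([solute_model()]).
#' @export
make_toy_peptide <- function(n_residues, geometry = c("helix", "extended"),
                             seed = 1L) {
  if (n_residues < 3L) stop("need at least 3 residues")
  geometry <- match.arg(geometry)
  set.seed(seed)
  sp <- 5.0                                  # residue spacing (A)
  nN <- n_residues
  nx <- sp * seq_len(nN)
  jit <- function(n) runif(n, -0.01, 0.01)
  Npos <- cbind(nx + jit(nN), jit(nN), jit(nN))
  if (geometry == "helix") {
    # O_i sits 1.2 A from N_{i+2} -- deep inside the switching radius so
    # the pair counts as fully formed; the last two O's (no partner) stay
    # beside their own residue so no two atoms ever coincide
    Opos <- Npos + cbind(rep(1.5, nN), rep(1.2, nN), rep(0, nN))
    idx <- seq_len(nN - 2L)
    Opos[idx, ] <- Npos[idx + 2L, ] + cbind(rep(0, length(idx)),
                                            rep(1.2, length(idx)),
                                            rep(0, length(idx)))
  } else {
    Opos <- Npos + cbind(rep(1.5, nN), rep(1.2, nN), rep(0, nN))
  }
  atoms <- data.frame(
    atom_id = seq_len(2L * nN),
    atom_name = rep(c("N", "O"), nN),
    residue_name = "GLY",
    residue_number = rep(seq_len(nN), each = 2L),
    chain = "A",
    x = as.vector(rbind(Npos[, 1L], Opos[, 1L])),
    y = as.vector(rbind(Npos[, 2L], Opos[, 2L])),
    z = as.vector(rbind(Npos[, 3L], Opos[, 3L])),
    stringsAsFactors = FALSE)
  frame <- structure3d(atoms)
  n_pairs <- nN - 2L
  grp <- rep("beta", n_pairs)
  if (n_pairs > 2L) {
    extra <- seq(ceiling(n_pairs / 2) + 1L, n_pairs)
    grp[extra] <- rep(c("alpha1", "alpha2"), length.out = length(extra))
  }
  pairs <- hbond_pairs(data.frame(
    group = grp,
    donor_resnum = seq_len(n_pairs) + 2L, donor_atom = "N",
    acceptor_resnum = seq_len(n_pairs), acceptor_atom = "O",
    stringsAsFactors = FALSE))
  model_atoms <- atoms
  model_atoms$charge <- ifelse(atoms$atom_name == "N", -0.30, -0.50)
  model_atoms$radius <- ifelse(atoms$atom_name == "N", 1.55, 1.52)
  model_atoms$sigma <- 0.0226
  list(structure = frame, pairs = pairs,
       model = solute_model(model_atoms))
}

#' Synthetic frame realizing a pair list as fully bonded or fully broken
#'
#' Builds a structure containing exactly the atoms a pair list refers to.
#' In `"bonded"` mode, atoms connected through shared pairs are packed into
#' tight clusters so that every donor-acceptor distance is far below the
#' switching radius (each pair contributes about 1 to the count); in
#' `"broken"` mode every atom is placed hundreds of Angstrom from every
#' other (each pair contributes about 0).
#'
#' @param pairs an [hbond_pairs()] table.
#' @param mode `"bonded"` or `"broken"`.
#' @param seed seed for the in-cluster jitter.
#' @return A [structure3d()].
#' @export
make_hbond_frame <- function(pairs, mode = c("bonded", "broken"),
                             seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  sel <- unique(rbind(
    data.frame(resnum = pairs$donor_resnum, atom = pairs$donor_atom,
               stringsAsFactors = FALSE),
    data.frame(resnum = pairs$acceptor_resnum, atom = pairs$acceptor_atom,
               stringsAsFactors = FALSE)))
  n <- nrow(sel)
  if (mode == "bonded") {
    # union-find over pairs to group atoms sharing any pair into clusters
    key <- paste(sel$resnum, sel$atom)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      i <- match(paste(pairs$donor_resnum[k], pairs$donor_atom[k]), key)
      j <- match(paste(pairs$acceptor_resnum[k], pairs$acceptor_atom[k]),
                 key)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    comp <- vapply(seq_len(n), find, integer(1))
    comp <- match(comp, unique(comp))
    pos <- cbind(100 * comp + runif(n, -0.15, 0.15),
                 runif(n, -0.15, 0.15), runif(n, -0.15, 0.15))
  } else {
    pos <- cbind(300 * seq_len(n), rep(0, n), rep(0, n))
  }
  structure3d(data.frame(
    atom_id = seq_len(n), atom_name = sel$atom, residue_name = "GLY",
    residue_number = sel$resnum, chain = "A",
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    stringsAsFactors = FALSE))
}
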