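## Mean-field MM/PBSA effective solute energy: Shrake-Rupley SASA,
## SASA-linear nonpolar solvation, finite-difference linearized
## Poisson-Boltzmann polar solvation, and the energy bookkeeping.

#' Solute model for the mean-field energy
#'
#' Atom table with mandatory point charges (e), radii (A) and per-atom
#' SASA coefficients `sigma` (kJ/mol/A^2, positive for hydrophobic and
#' negative for hydrophilic groups).
#'
#' @param atoms data frame with at least `x`, `y`, `z`, `charge`, `radius`,
#'   `sigma` (plus any identification columns).
#' @return Object of class `solute_model`.
#' @export
solute_model <- function(atoms) {
  required <- c("x", "y", "z", "charge", "radius", "sigma")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("solute model lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("solute model must contain atoms")
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  out <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              n_atoms = nrow(atoms))
  class(out) <- "solute_model"
  out
}

#' @export
print.solute_model <- function(x, ...) {
  cat("solute_model:", x$n_atoms, "atoms, net charge",
      round(sum(x$atoms$charge), 4), "e\n")
  invisible(x)
}

#' Deterministic quasi-uniform unit sphere point set
#'
#' Fibonacci (golden-spiral) lattice; the same `n` always yields the same
#' points, making the SASA estimate deterministic.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points on the sphere of radius `radius + probe`
#' are marked buried when they fall inside any neighboring atom's expanded
#' sphere; the accessible fraction times the sphere area is the per-atom
#' SASA.
#'
#' @param model a [solute_model()].
#' @param probe probe radius (A), 1.4 for water.
#' @param n_points test points per atom (>= 92).
#' @param points optional explicit `n x 3` unit-vector matrix (e.g. a
#'   rotated copy of the standard set, for invariance checks).
#' @return Per-atom SASA values (A^2).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L, points = NULL) {
  if (n_points < 92L) stop("need at least 92 test points per atom")
  a <- model$atoms
  if (is.null(points)) points <- fibonacci_sphere(n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rr <- a$radius + probe
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(points * rr[i], 2L, xyz[i, ], `+`)
    accessible <- rep(TRUE, nrow(pts))
    # neighbors whose expanded sphere can reach atom i's surface
    dij <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dij < rr[i] + rr & seq_len(n) != i)
    for (j in nb) {
      dx <- pts[, 1L] - xyz[j, 1L]
      dy <- pts[, 2L] - xyz[j, 2L]
      dz <- pts[, 3L] - xyz[j, 3L]
      accessible <- accessible & (dx * dx + dy * dy + dz * dz > rr[j]^2)
      if (!any(accessible)) break
    }
    out[i] <- mean(accessible) * 4 * pi * rr[i]^2
  }
  out
}

#' Nonpolar solvation free energy from SASA
#'
#' `G_np = sum_i sigma_i * SASA_i`.
#'
#' @param model a [solute_model()].
#' @param sasa_values per-atom SASA (A^2), aligned with the atoms.
#' @return Nonpolar solvation energy (kJ/mol).
#' @export
g_solv_np <- function(model, sasa_values) {
  if (length(sasa_values) != model$n_atoms)
    stop("sasa_values must align with the solute atoms")
  sum(model$atoms$sigma * sasa_values)
}

#' Finite-difference Poisson-Boltzmann grid settings
#'
#' @param box_min,box_max grid corners (A, length-3); the solute must sit
#'   at least `margin` inside.
#' @param spacing node spacing (A).
#' @param eps_in,eps_out relative permittivities of solute and solvent.
#' @param kappa Debye screening constant (1/A); 0 for pure Poisson.
#' @param margin required clearance between solute spheres and the box (A).
#' @return Object of class `pb_grid`.
#' @export
pb_grid <- function(box_min, box_max, spacing = 0.4, eps_in = 1,
                    eps_out = 80, kappa = 0, margin = 5) {
  if (spacing <= 0) stop("spacing must be positive")
  if (eps_in <= 0 || eps_out <= 0) stop("permittivities must be positive")
  if (any(box_max - box_min <= 0)) stop("degenerate box")
  out <- list(box_min = box_min, box_max = box_max, spacing = spacing,
              eps_in = eps_in, eps_out = eps_out, kappa = kappa,
              margin = margin)
  class(out) <- "pb_grid"
  out
}

#' Grid box sized to a solute
#'
#' @param model a [solute_model()].
#' @inheritParams pb_grid
#' @return A [pb_grid()] whose box encloses every atom sphere with the
#'   requested margin.
#' @export
pb_grid_for <- function(model, spacing = 0.4, eps_in = 1, eps_out = 80,
                        kappa = 0, margin = 5) {
  a <- model$atoms
  lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius)) -
    margin
  hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius)) +
    margin
  pb_grid(lo, hi, spacing, eps_in, eps_out, kappa, margin)
}

# build node coordinate vectors; n chosen so spacing is honored exactly
pb_axes <- function(grid) {
  lapply(1:3, function(k) {
    n <- ceiling((grid$box_max[k] - grid$box_min[k]) / grid$spacing) + 1L
    grid$box_min[k] + (seq_len(n) - 1L) * grid$spacing
  })
}

# trilinear spread of point charges onto grid nodes -> 3D array
spread_charges <- function(model, ax, h) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  rho <- array(0, c(nx, ny, nz))
  a <- model$atoms
  for (i in seq_len(nrow(a))) {
    fx <- (a$x[i] - ax[[1]][1L]) / h
    fy <- (a$y[i] - ax[[2]][1L]) / h
    fz <- (a$z[i] - ax[[3]][1L]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
        (if (dz) tz else 1 - tz)
      rho[i0 + dx + 1L, j0 + dy + 1L, k0 + dz + 1L] <-
        rho[i0 + dx + 1L, j0 + dy + 1L, k0 + dz + 1L] + a$charge[i] * wgt
    }
  }
  rho
}

# trilinear interpolation of a grid field at the atom positions
interp_at_atoms <- function(phi, model, ax, h) {
  a <- model$atoms
  vapply(seq_len(nrow(a)), function(i) {
    fx <- (a$x[i] - ax[[1]][1L]) / h
    fy <- (a$y[i] - ax[[2]][1L]) / h
    fz <- (a$z[i] - ax[[3]][1L]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
        (if (dz) tz else 1 - tz)
      val <- val + wgt * phi[i0 + dx + 1L, j0 + dy + 1L, k0 + dz + 1L]
    }
    val
  }, numeric(1))
}

# node dielectric map: eps_in inside the van der Waals union, eps_out
# elsewhere.  The solute characteristic function is smoothed linearly over
# a one-cell shell around each sphere and blended harmonically, which
# suppresses the staircase oscillation of a sharp boundary and makes the
# discretization error decrease smoothly with the spacing.  `inflate`
# grows every radius (probe-inflated boundary option).
dielectric_map <- function(model, ax, eps_in, eps_out, h, inflate = 0) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  chi <- array(0, c(nx, ny, nz))
  a <- model$atoms
  for (i in seq_len(nrow(a))) {
    r <- a$radius[i] + inflate
    reach <- r + h
    ix <- which(abs(ax[[1]] - a$x[i]) <= reach)
    iy <- which(abs(ax[[2]] - a$y[i]) <= reach)
    iz <- which(abs(ax[[3]] - a$z[i]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[[1]][ix] - a$x[i])^2
    dy2 <- (ax[[2]][iy] - a$y[i])^2
    dz2 <- (ax[[3]][iz] - a$z[i])^2
    d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
    ci <- pmin(pmax((r + h / 2 - d) / h, 0), 1)
    chi[ix, iy, iz] <- pmax(chi[ix, iy, iz], ci)
  }
  eps <- 1 / (chi / eps_in + (1 - chi) / eps_out)
  list(eps = eps, inside = chi >= 0.5)
}

# Debye-Hueckel boundary values on the box faces
boundary_phi <- function(model, ax, eps, kappa) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  phi <- array(0, c(nx, ny, nz))
  a <- model$atoms
  fill <- function(ix, iy, iz) {
    gx <- ax[[1]][ix]; gy <- ax[[2]][iy]; gz <- ax[[3]][iz]
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    val <- numeric(nrow(pts))
    for (i in seq_len(nrow(a))) {
      r <- sqrt((pts[, 1L] - a$x[i])^2 + (pts[, 2L] - a$y[i])^2 +
                  (pts[, 3L] - a$z[i])^2)
      r <- pmax(r, 1e-6)
      val <- val + coulomb_kJmolAng * a$charge[i] *
        exp(-kappa * r) / (eps * r)
    }
    phi[ix, iy, iz] <<- array(val, c(length(ix), length(iy), length(iz)))
  }
  fill(1L, seq_len(ny), seq_len(nz)); fill(nx, seq_len(ny), seq_len(nz))
  fill(seq_len(nx), 1L, seq_len(nz)); fill(seq_len(nx), ny, seq_len(nz))
  fill(seq_len(nx), seq_len(ny), 1L); fill(seq_len(nx), seq_len(ny), nz)
  phi
}

# one linearized-PB solve on the lattice; returns full phi array (kJ/mol/e)
# 7-point stencil, harmonic-mean face dielectrics, Jacobi-preconditioned CG
pb_solve_field <- function(model, ax, h, eps_node, ion_mask, kappa,
                           phi_bound, rho, tol = 1e-8, max_iter = 5000L) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  if (nx < 3L || ny < 3L || nz < 3L) stop("grid too small")
  I <- 2:(nx - 1L); J <- 2:(ny - 1L); K <- 2:(nz - 1L)
  hmean <- function(a, b) 2 * a * b / (a + b)
  # face dielectrics seen from each interior node towards +/- each axis
  eW <- hmean(eps_node[I, J, K], eps_node[I - 1L, J, K])
  eE <- hmean(eps_node[I, J, K], eps_node[I + 1L, J, K])
  eS <- hmean(eps_node[I, J, K], eps_node[I, J - 1L, K])
  eN <- hmean(eps_node[I, J, K], eps_node[I, J + 1L, K])
  eD <- hmean(eps_node[I, J, K], eps_node[I, J, K - 1L])
  eU <- hmean(eps_node[I, J, K], eps_node[I, J, K + 1L])
  screen <- ifelse(ion_mask[I, J, K], eps_node[I, J, K] * kappa^2 * h^2, 0)
  diag_term <- eW + eE + eS + eN + eD + eU + screen
  applyA <- function(u) {
    # u: full array with zero (or fixed) boundary; returns interior result
    diag_term * u[I, J, K] -
      eW * u[I - 1L, J, K] - eE * u[I + 1L, J, K] -
      eS * u[I, J - 1L, K] - eN * u[I, J + 1L, K] -
      eD * u[I, J, K - 1L] - eU * u[I, J, K + 1L]
  }
  # rhs: 4 pi k_e q / h, plus boundary Dirichlet contributions
  b <- 4 * pi * coulomb_kJmolAng * rho[I, J, K] / h
  ub <- phi_bound
  ub[I, J, K] <- 0
  b <- b - applyA(ub)
  # CG with Jacobi preconditioner on the interior unknowns
  u <- array(0, c(nx, ny, nz))          # boundary kept at zero; added later
  r <- b                                # since u = 0
  z <- r / diag_term
  p <- array(0, c(nx, ny, nz)); p[I, J, K] <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b * b))
  if (b_norm == 0) {
    phi <- phi_bound
    phi[I, J, K] <- 0
    return(phi)
  }
  for (it in seq_len(max_iter)) {
    Ap <- applyA(p)
    alpha <- rz / sum(p[I, J, K] * Ap)
    u[I, J, K] <- u[I, J, K] + alpha * p[I, J, K]
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * b_norm) break
    z <- r / diag_term
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p[I, J, K] <- z + beta * p[I, J, K]
    if (it == max_iter)
      stop("PB solver did not converge: relative residual ",
           signif(sqrt(sum(r * r)) / b_norm, 3))
  }
  phi <- phi_bound
  phi[I, J, K] <- u[I, J, K]
  phi
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves the linearized PB equation on a uniform lattice with a 7-point
#' stencil and harmonic-mean face dielectrics.  The dielectric is `eps_in`
#' inside the van der Waals union of the atom spheres and `eps_out`
#' outside, with the interface smoothed over one grid cell (harmonic
#' blend) so the discretization error shrinks smoothly under refinement;
#' charges are spread trilinearly; Dirichlet boundary values come
#' from the Debye-Hueckel superposition of the atomic charges.  The grid
#' self-energy is removed by a second, uniform-dielectric (`eps_in`,
#' `kappa = 0`) reference solve with identical charge spreading:
#' `G_pol = 1/2 sum_i q_i (phi_solv(r_i) - phi_ref(r_i))`.
#'
#' @param model a [solute_model()].
#' @param grid a [pb_grid()] (see [pb_grid_for()]).
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @return Scalar polar solvation energy (kJ/mol); attribute `phi_at_atoms`
#'   carries the per-atom reaction potentials.
#' @export
solve_pb <- function(model, grid, tol = 1e-8) {
  a <- model$atoms
  lo_clear <- c(min(a$x - a$radius), min(a$y - a$radius),
                min(a$z - a$radius)) - grid$box_min
  hi_clear <- grid$box_max - c(max(a$x + a$radius), max(a$y + a$radius),
                               max(a$z + a$radius))
  if (any(c(lo_clear, hi_clear) < grid$margin - 1e-9))
    stop("solute sphere union is within ", grid$margin,
         " A of the grid boundary; enlarge the box")
  if (all(a$charge == 0)) {
    out <- 0
    attr(out, "phi_at_atoms") <- numeric(nrow(a))
    return(out)
  }
  ax <- pb_axes(grid)
  h <- grid$spacing
  rho <- spread_charges(model, ax, h)
  dm <- dielectric_map(model, ax, grid$eps_in, grid$eps_out, h)
  phi_b_solv <- boundary_phi(model, ax, grid$eps_out, grid$kappa)
  phi_solv <- pb_solve_field(model, ax, h, dm$eps, !dm$inside, grid$kappa,
                             phi_b_solv, rho, tol)
  eps_ref <- array(grid$eps_in, dim(dm$eps))
  phi_b_ref <- boundary_phi(model, ax, grid$eps_in, 0)
  phi_ref <- pb_solve_field(model, ax, h, eps_ref, !dm$inside, 0,
                            phi_b_ref, rho, tol)
  dphi <- interp_at_atoms(phi_solv, model, ax, h) -
    interp_at_atoms(phi_ref, model, ax, h)
  out <- 0.5 * sum(a$charge * dphi)
  attr(out, "phi_at_atoms") <- dphi
  out
}

#' Intramolecular force-field energy (bookkeeping)
#'
#' The five bonded/nonbonded terms are inputs (from an external engine or
#' the synthetic generator), never computed here; this simply asserts the
#' schema and sums them.
#'
#' @param terms named numeric vector or list with `u_str`, `u_bend`,
#'   `u_tors`, `u_vdw`, `u_el` (kJ/mol).
#' @return Their sum (kJ/mol).
#' @export
intra_energy <- function(terms) {
  required <- c("u_str", "u_bend", "u_tors", "u_vdw", "u_el")
  terms <- as.list(terms)
  missing_terms <- setdiff(required, names(terms))
  if (length(missing_terms))
    stop("missing intramolecular term(s): ",
         paste(missing_terms, collapse = ", "))
  sum(vapply(terms[required], as.numeric, numeric(1)))
}

#' Assemble the mean-field energy breakdown of one configuration
#'
#' `U_bar = U_intra + G_solv_np + G_solv_pol`, with the nonpolar term from
#' [sasa()] + [g_solv_np()] and the polar term from [solve_pb()].
#'
#' @param terms intramolecular terms as for [intra_energy()].
#' @param model a [solute_model()] for this configuration.
#' @param grid a [pb_grid()]; defaults to [pb_grid_for()] the model.
#' @param probe SASA probe radius (A).
#' @param n_points SASA test points per atom.
#' @return Object of class `energy_breakdown`: named list of the seven
#'   terms plus `u_bar`.
#' @export
mean_field_energy <- function(terms, model, grid = NULL, probe = 1.4,
                              n_points = 960L) {
  terms <- as.list(terms)
  if (is.null(grid)) grid <- pb_grid_for(model)
  np <- g_solv_np(model, sasa(model, probe, n_points))
  pol <- as.numeric(solve_pb(model, grid))
  out <- list(u_str = as.numeric(terms$u_str),
              u_bend = as.numeric(terms$u_bend),
              u_tors = as.numeric(terms$u_tors),
              u_vdw = as.numeric(terms$u_vdw),
              u_el = as.numeric(terms$u_el),
              g_solv_np = np, g_solv_pol = pol)
  out$u_bar <- intra_energy(out) + np + pol
  class(out) <- "energy_breakdown"
  out
}

#' Per-term energy change between two states
#'
#' `unfolded - folded` for every term plus the total, the sign convention
#' of stability tables (a larger unfolded term gives a positive delta).
#'
#' @param folded,unfolded `energy_breakdown` objects (or named lists with
#'   the same term schema).
#' @return Data frame with columns `term` and `delta` (kJ/mol).
#' @export
energy_delta <- function(folded, unfolded) {
  terms <- c("u_str", "u_bend", "u_tors", "u_vdw", "u_el",
             "g_solv_np", "g_solv_pol", "u_bar")
  f <- unlist(folded[terms]); u <- unlist(unfolded[terms])
  if (length(f) != length(terms) || length(u) != length(terms))
    stop("term schema mismatch between the two states")
  data.frame(term = terms, delta = as.numeric(u - f))
}
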