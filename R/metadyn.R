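## Well-tempered metadynamics: bias potentials, altruistic multi-walker
## combination, toy overdamped-Langevin sampler and bias -> free-energy
## conversion.

#' Well-tempered metadynamics parameters
#'
#' Either `deltaT` (K) or the biasing factor `(T + deltaT)/T` must be given
#' for a tempered run.  `w` is the bare Gaussian height (kJ/mol), `delta`
#' the Gaussian width in CV units and `tau_G` the deposition interval (ps).
#' With `tempered = FALSE` heights are never scaled (the plain-metadynamics
#' limit, formally `deltaT = Inf`).
#'
#' @param T simulation temperature (K).
#' @param deltaT well-tempered temperature offset (K).
#' @param biasf biasing factor; used to derive `deltaT = (biasf - 1) * T`
#'   when `deltaT` is not supplied.
#' @param w Gaussian height (kJ/mol).
#' @param delta Gaussian width (CV units).
#' @param tau_G deposition interval (ps).
#' @param tempered logical; `FALSE` disables height tempering.
#' @return Object of class `wt_params`.
#' @export
wt_params <- function(T = 300, deltaT = NULL, biasf = NULL, w = 1.0,
                      delta = 1.0, tau_G = 20, tempered = TRUE) {
  if (T <= 0) stop("T must be positive")
  if (is.null(deltaT)) {
    if (is.null(biasf)) {
      if (tempered) stop("supply deltaT or biasf for a tempered run")
      deltaT <- Inf
    } else {
      if (biasf <= 1) stop("biasing factor must exceed 1")
      deltaT <- (biasf - 1) * T
    }
  }
  if (tempered && deltaT <= 0)
    stop("deltaT must be positive when tempering is enabled")
  out <- list(T = T, deltaT = deltaT, w = w, delta = delta, tau_G = tau_G,
              tempered = tempered, kB = kB_kJmolK)
  class(out) <- "wt_params"
  out
}

#' Biasing factor of a parameter set
#'
#' @param p a [wt_params()] object.
#' @return `(T + deltaT)/T`.
#' @export
biasing_factor <- function(p) (p$T + p$deltaT) / p$T

#' Bias potential as a sum of deposited Gaussians
#'
#' Houses the deposited hills, an optional cached uniform-grid evaluation
#' and an additive offset (the physically irrelevant constant).
#'
#' @param hills data frame with columns `time`, `center`, `sigma`, `height`.
#' @param grid optional data frame with columns `s`, `V` (a grid-only bias,
#'   e.g. after walker combination).
#' @param offset additive constant (kJ/mol).
#' @return Object of class `bias_potential`.
#' @export
bias_potential <- function(hills = NULL, grid = NULL, offset = 0) {
  if (is.null(hills))
    hills <- data.frame(time = numeric(), center = numeric(),
                        sigma = numeric(), height = numeric())
  stopifnot(all(c("time", "center", "sigma", "height") %in% names(hills)))
  if (any(hills$sigma <= 0)) stop("hill widths must be positive")
  if (any(hills$height <= 0)) stop("hill heights must be positive")
  out <- list(hills = hills, grid = grid, offset = offset)
  class(out) <- "bias_potential"
  out
}

#' @export
print.bias_potential <- function(x, ...) {
  cat("bias_potential:", nrow(x$hills), "hills",
      if (!is.null(x$grid)) sprintf("+ grid of %d nodes", nrow(x$grid)),
      "\n")
  invisible(x)
}

# linear interpolation on a (s, V) grid, clamped at the ends
grid_interp <- function(grid, s) {
  approx(grid$s, grid$V, xout = s, rule = 2)$y
}

#' Evaluate a bias potential
#'
#' Sum of Gaussians plus offset when hills are present; linear grid
#' interpolation plus offset for a grid-only bias.
#'
#' @param b a [bias_potential()].
#' @param s CV values (vectorized).
#' @return Bias values (kJ/mol).
#' @export
evaluate_bias <- function(b, s) {
  if (nrow(b$hills) > 0L) {
    h <- b$hills
    vals <- vapply(s, function(si)
      sum(h$height * exp(-(si - h$center)^2 / (2 * h$sigma^2))), numeric(1))
  } else if (!is.null(b$grid)) {
    vals <- grid_interp(b$grid, s)
  } else {
    vals <- rep(0, length(s))
  }
  vals + b$offset
}

#' Cache a bias potential onto a uniform grid
#'
#' @param b a [bias_potential()].
#' @param lo,hi grid range (CV units); defaults span the hills +/- 3 widths.
#' @param spacing node spacing (CV units).
#' @return The bias with its `grid` field populated.
#' @export
cache_bias_grid <- function(b, lo = NULL, hi = NULL, spacing = 0.1) {
  if (is.null(lo) || is.null(hi)) {
    if (nrow(b$hills) == 0L) stop("cannot infer grid range without hills")
    pad <- 3 * max(b$hills$sigma)
    if (is.null(lo)) lo <- min(b$hills$center) - pad
    if (is.null(hi)) hi <- max(b$hills$center) + pad
  }
  nodes <- seq(lo, hi, by = spacing)
  b$grid <- data.frame(s = nodes, V = evaluate_bias(b, nodes) - b$offset)
  b
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian centered at the current CV value.  Under tempering
#' the deposited height is `w * exp(-V_G(s_now) / (kB * deltaT))`, i.e. it
#' shrinks as the bias accumulated at that point grows; untempered runs
#' deposit the bare height `w`.
#'
#' @param b a [bias_potential()].
#' @param s_now current CV value.
#' @param p a [wt_params()].
#' @param t deposit time (ps).
#' @return The bias with the new hill appended.
#' @export
deposit_hill <- function(b, s_now, p, t = NA_real_) {
  if (p$tempered && p$deltaT <= 0)
    stop("deltaT must be positive when tempering is enabled")
  height <- if (p$tempered && is.finite(p$deltaT)) {
    v_now <- evaluate_bias(b, s_now) - b$offset
    p$w * exp(-v_now / (p$kB * p$deltaT))
  } else {
    p$w
  }
  b$hills <- rbind(b$hills, data.frame(time = t, center = s_now,
                                       sigma = p$delta, height = height))
  if (!is.null(b$grid))
    b$grid$V <- b$grid$V +
      height * exp(-(b$grid$s - s_now)^2 / (2 * p$delta^2))
  b
}

#' Free energy difference from a converged well-tempered bias
#'
#' The well-tempered bias converges to `-deltaT/(T + deltaT) * F(s)` up to a
#' constant, so
#' `F(s) - F(s0) = -((T + deltaT)/deltaT) * (V_G(s) - V_G(s0))`.
#' The result is independent of any additive offset in the bias.
#'
#' @param b a [bias_potential()].
#' @param p a [wt_params()] with finite positive `deltaT`.
#' @param s CV values (vectorized).
#' @param s0 reference CV value.
#' @return Free-energy differences (kJ/mol).
#' @export
free_energy_from_bias <- function(b, p, s, s0) {
  if (!is.finite(p$deltaT) || p$deltaT <= 0)
    stop("free_energy_from_bias requires finite positive deltaT")
  pref <- (p$T + p$deltaT) / p$deltaT
  -pref * (evaluate_bias(b, s) - evaluate_bias(b, s0))
}

# biases -> common-grid value matrix (resampling to the union range if the
# node sets differ); returns list(nodes, V matrix nodes x walkers)
biases_to_matrix <- function(biases, spacing = 0.1) {
  grids <- lapply(biases, function(b) {
    if (is.null(b$grid)) b <- cache_bias_grid(b, spacing = spacing)
    data.frame(s = b$grid$s, V = b$grid$V + b$offset)
  })
  node_sets <- lapply(grids, `[[`, "s")
  same <- all(vapply(node_sets, function(n)
    length(n) == length(node_sets[[1L]]) &&
      max(abs(n - node_sets[[1L]])) < 1e-9, logical(1)))
  if (same) {
    nodes <- node_sets[[1L]]
  } else {
    lo <- min(vapply(node_sets, min, numeric(1)))
    hi <- max(vapply(node_sets, max, numeric(1)))
    nodes <- seq(lo, hi, by = spacing)
  }
  V <- vapply(grids, function(g) grid_interp(g, nodes),
              numeric(length(nodes)))
  list(nodes = nodes, V = matrix(V, ncol = length(biases)))
}

# the default altruistic convex-combination rule on a value matrix
combine_matrix <- function(V, alpha, w_share) {
  pooled <- rowMeans(V)
  (1 - alpha) * V + alpha * (w_share * V + (1 - w_share) * pooled)
}

#' Altruistic combination of per-walker biases
#'
#' Each walker's bias is replaced by a convex combination of its own bias
#' and the pooled (swarm-mean) bias:
#' `V_i' = (1 - alpha) V_i + alpha * (w_share * V_i + (1 - w_share) * mean_j V_j)`.
#' `alpha = 0` leaves every bias unchanged.  The rule is pluggable through
#' `rule`, which receives the node-by-walker value matrix.
#'
#' @param biases list of [bias_potential()] objects (>= 2 walkers).
#' @param alpha mixing strength in `[0, 1]`.
#' @param w_share self-share in `[0, 1]`.
#' @param spacing grid spacing used if biases must be resampled.
#' @param rule optional replacement combination function
#'   `function(V, alpha, w_share) -> V'`.
#' @return List of grid-based [bias_potential()] objects.
#' @export
altruistic_combine <- function(biases, alpha, w_share, spacing = 0.1,
                               rule = combine_matrix) {
  if (length(biases) == 0L) stop("empty walker list")
  if (alpha < 0 || alpha > 1 || w_share < 0 || w_share > 1)
    stop("alpha and w_share must lie in [0, 1]")
  m <- biases_to_matrix(biases, spacing)
  Vn <- rule(m$V, alpha, w_share)
  lapply(seq_along(biases), function(i)
    bias_potential(grid = data.frame(s = m$nodes, V = Vn[, i])))
}

#' Average per-walker biases into a single bias
#'
#' Pointwise arithmetic mean on a shared grid; the returned bias is the one
#' assigned to every walker for the constant-bias collection stage.
#'
#' @inheritParams altruistic_combine
#' @return A single grid-based [bias_potential()].
#' @export
average_bias_final <- function(biases, spacing = 0.1) {
  if (length(biases) == 0L) stop("empty walker list")
  m <- biases_to_matrix(biases, spacing)
  bias_potential(grid = data.frame(s = m$nodes, V = rowMeans(m$V)))
}

#' Degree-4 polynomial interpolant of a bias grid with linear tails
#'
#' Least-squares quartic fit of the grid values inside `fit_range`; outside
#' the range the interpolant continues linearly with the polynomial's
#' boundary slope (C1 continuity).
#'
#' @param grid data frame with columns `s` and `V`.
#' @param fit_range length-2 numeric, fitting interval.
#' @return A function of `s`, with attribute `coefficients` (ascending
#'   powers).
#' @export
interpolate_bias_poly4 <- function(grid, fit_range) {
  inside <- grid$s >= fit_range[1L] & grid$s <= fit_range[2L]
  if (sum(inside) < 5L) stop("need at least 5 grid nodes inside fit_range")
  s <- grid$s[inside]
  # center the basis for conditioning
  s_mid <- mean(fit_range)
  X <- outer(s - s_mid, 0:4, `^`)
  beta <- qr.coef(qr(X), grid$V[inside])
  poly_val <- function(x) drop(outer(x - s_mid, 0:4, `^`) %*% beta)
  poly_der <- function(x)
    drop(outer(x - s_mid, 0:3, `^`) %*% (beta[2:5] * (1:4)))
  lo <- fit_range[1L]; hi <- fit_range[2L]
  v_lo <- poly_val(lo); d_lo <- poly_der(lo)
  v_hi <- poly_val(hi); d_hi <- poly_der(hi)
  f <- function(s) {
    out <- numeric(length(s))
    below <- s < lo; above <- s > hi; mid <- !below & !above
    out[mid] <- poly_val(s[mid])
    out[below] <- v_lo + d_lo * (s[below] - lo)
    out[above] <- v_hi + d_hi * (s[above] - hi)
    out
  }
  attr(f, "coefficients") <- beta
  attr(f, "fit_range") <- fit_range
  f
}

#' Toy one-dimensional system for the CV-space Langevin sampler
#'
#' @param free_energy function `F(s)` (kJ/mol).
#' @param dfree its derivative `F'(s)`.
#' @param domain length-2 CV interval with reflecting walls.
#' @param friction friction coefficient (1/ps).
#' @param timestep integration step (ps).
#' @param temperature temperature (K).
#' @param s_init initial CV value (defaults to the domain midpoint).
#' @param seed RNG seed for full reproducibility.
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(free_energy, dfree, domain, friction = 2,
                       timestep = 0.02, temperature = 300,
                       s_init = NULL, seed = 1L) {
  if (timestep <= 0) stop("timestep must be positive")
  if (friction <= 0) stop("friction must be positive")
  if (is.null(s_init)) s_init <- mean(domain)
  out <- list(free_energy = free_energy, dfree = dfree, domain = domain,
              friction = friction, timestep = timestep,
              temperature = temperature, s_init = s_init,
              seed = as.integer(seed))
  class(out) <- "toy_system"
  out
}

#' Simulation schedule
#'
#' One row per stage: `label`, `length_ns`, `alpha`, `w_share` (NA when the
#' bias is not updated) and `bias_updated`.
#'
#' @param stages data frame with those columns.
#' @return The validated data frame with class `md_schedule`.
#' @export
md_schedule <- function(stages) {
  required <- c("label", "length_ns", "alpha", "w_share", "bias_updated")
  if (!all(required %in% names(stages)))
    stop("schedule lacks columns: ",
         paste(setdiff(required, names(stages)), collapse = ", "))
  if (any(stages$length_ns <= 0)) stop("stage durations must be positive")
  ok <- is.na(stages$alpha) |
    (stages$alpha >= 0 & stages$alpha <= 1 &
       stages$w_share >= 0 & stages$w_share <= 1)
  if (!all(ok)) stop("alpha and w_share must lie in [0, 1]")
  stages <- as.data.frame(stages, stringsAsFactors = FALSE)
  class(stages) <- c("md_schedule", "data.frame")
  stages
}

#' The production staging used for the protein runs
#'
#' 8 ns of bias-free equilibration (stages 1-4), 22 ns of altruistic
#' well-tempered bias construction with mixing strength ramped 0, 1/4, 1/2,
#' 3/4 over four 2-ns stages and then full mixing with self-share 1/2 for
#' 14 ns (stages 5-15), followed by a constant-bias collection stage.
#'
#' @param collect_ns duration of the final constant-bias stage (10 ns for
#'   the small protein, 30 ns for the larger one).
#' @return An [md_schedule()].
#' @export
table_schedule <- function(collect_ns = 10) {
  md_schedule(data.frame(
    label = c("equil", "build0", "build1", "build2", "build3", "build4",
              "collect"),
    length_ns = c(8, 2, 2, 2, 2, 14, collect_ns),
    alpha = c(NA, 0, 1/4, 1/2, 3/4, 1, NA),
    w_share = c(NA, 1, 1, 1, 1, 1/2, NA),
    bias_updated = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE))
}

#' Total durations of a schedule
#'
#' @param sched an [md_schedule()].
#' @return Named vector with the bias-updated construction time, the time
#'   before collection (equilibration + construction) and the total (ns).
#' @export
schedule_durations <- function(sched) {
  constr <- sum(sched$length_ns[sched$bias_updated])
  upd <- which(sched$bias_updated)
  pre <- if (length(upd)) sum(sched$length_ns[seq_len(max(upd))]) else 0
  c(construction_ns = constr, pre_collection_ns = pre,
    total_ns = sum(sched$length_ns))
}

#' Run the toy multi-walker well-tempered metadynamics sampler
#'
#' Overdamped Euler-Maruyama Langevin dynamics on the CV `s` with force
#' `-d/ds (F(s) + V_G(s))`, reflecting walls at the domain boundaries.
#' During bias-updated stages each walker deposits a (tempered) hill on its
#' own grid every `tau_G` ps; every `exchange_ns` of such a stage the
#' walkers' biases are mixed with [altruistic_combine()] using the stage's
#' `alpha`/`w_share`.  After the last updated stage the biases are averaged
#' into one ([average_bias_final()]) and frames are logged every
#' `output_every_ps` during the remaining constant-bias stages, forming the
#' metastatistics.  Fully reproducible from the system seed.
#'
#' @param sys a [toy_system()].
#' @param p a [wt_params()].
#' @param sched an [md_schedule()].
#' @param n_walkers number of walkers.
#' @param grid_spacing bias grid spacing (CV units).
#' @param exchange_ns interval between altruistic combinations (ns).
#' @param output_every_ps frame-logging interval in the collection stages.
#' @return List of class `toy_run` with elements `series` (data frame
#'   `time`, `walker`, `xi`), `bias` (final shared [bias_potential()], grid
#'   based), `per_walker_hills` (list of hill data frames), `params`,
#'   `schedule`.
#' @export
run_toy_walker <- function(sys, p, sched, n_walkers = 1L,
                           grid_spacing = 0.1, exchange_ns = 2,
                           output_every_ps = 1) {
  set.seed(sys$seed)
  dt <- sys$timestep
  kT <- kB_kJmolK * sys$temperature
  mob <- 1 / sys$friction                   # mobility dt-prefactor
  noise_amp <- sqrt(2 * kT * dt / sys$friction)
  lo <- sys$domain[1L]; hi <- sys$domain[2L]
  nodes <- seq(lo, hi, by = grid_spacing)
  nn <- length(nodes)
  V <- matrix(0, nn, n_walkers)
  hill_log <- replicate(n_walkers,
                        list(time = numeric(), center = numeric(),
                             height = numeric()), simplify = FALSE)
  s <- rep(sys$s_init, n_walkers)
  tau_steps <- max(1L, round(p$tau_G / dt))
  out_steps <- max(1L, round(output_every_ps / dt))
  t_now <- 0
  last_updated <- if (any(sched$bias_updated)) max(which(sched$bias_updated)) else 0L
  rec_time <- list(); rec_walker <- list(); rec_xi <- list(); rec_k <- 0L
  walker_col <- (seq_len(n_walkers) - 1L) * nn

  step_block <- function(n_steps, depositing, recording, t0) {
    # chunked so noise is pregenerated; returns final state via <<-
    done <- 0L
    while (done < n_steps) {
      chunk <- min(n_steps - done, max(1L, 1000000L %/% n_walkers))
      eta <- matrix(rnorm(chunk * n_walkers), chunk, n_walkers)
      for (k in seq_len(chunk)) {
        gstep <- done + k
        # forces: analytic landscape + finite-difference bias slope
        i <- pmin(pmax(floor((s - lo) / grid_spacing) + 1L, 1L), nn - 1L)
        dV <- (V[i + 1L + walker_col] - V[i + walker_col]) / grid_spacing
        force <- -(sys$dfree(s) + dV)
        s_new <- s + mob * force * dt + noise_amp * eta[k, ]
        # reflecting walls
        s_new <- ifelse(s_new < lo, 2 * lo - s_new, s_new)
        s_new <- ifelse(s_new > hi, 2 * hi - s_new, s_new)
        if (any(!is.finite(s_new)) || any(s_new < lo) || any(s_new > hi))
          stop("unstable integration: CV left the domain (reduce timestep)")
        s <<- s_new
        if (depositing && gstep %% tau_steps == 0L) {
          iw <- pmin(pmax(floor((s - lo) / grid_spacing) + 1L, 1L), nn - 1L)
          frac <- (s - nodes[iw]) / grid_spacing
          v_here <- (1 - frac) * V[iw + walker_col] +
            frac * V[iw + 1L + walker_col]
          h <- if (p$tempered && is.finite(p$deltaT))
            p$w * exp(-v_here / (p$kB * p$deltaT)) else rep(p$w, n_walkers)
          for (wk in seq_len(n_walkers)) {
            V[, wk] <<- V[, wk] +
              h[wk] * exp(-(nodes - s[wk])^2 / (2 * p$delta^2))
            hl <- hill_log[[wk]]
            hl$time <- c(hl$time, t0 + gstep * dt)
            hl$center <- c(hl$center, s[wk])
            hl$height <- c(hl$height, h[wk])
            hill_log[[wk]] <<- hl
          }
        }
        if (recording && gstep %% out_steps == 0L) {
          rec_k <<- rec_k + 1L
          rec_time[[rec_k]] <<- rep(t0 + gstep * dt, n_walkers)
          rec_walker[[rec_k]] <<- seq_len(n_walkers)
          rec_xi[[rec_k]] <<- s
        }
      }
      done <- done + chunk
    }
  }

  for (st in seq_len(nrow(sched))) {
    row <- sched[st, ]
    stage_steps <- round(row$length_ns * 1000 / dt)
    recording <- !row$bias_updated && st > last_updated
    if (row$bias_updated) {
      seg_steps <- max(1L, round(exchange_ns * 1000 / dt))
      remaining <- stage_steps
      while (remaining > 0L) {
        n_do <- min(seg_steps, remaining)
        step_block(n_do, depositing = TRUE, recording = FALSE, t0 = t_now)
        t_now <- t_now + n_do * dt
        remaining <- remaining - n_do
        if (n_walkers > 1L)
          V <- combine_matrix(V, row$alpha, row$w_share)
      }
      if (st == last_updated) V[] <- rowMeans(V)   # final walker averaging
    } else {
      step_block(stage_steps, depositing = FALSE, recording = recording,
                 t0 = t_now)
      t_now <- t_now + stage_steps * dt
    }
  }

  series <- data.frame(time = unlist(rec_time), walker = unlist(rec_walker),
                       xi = unlist(rec_xi))
  final_bias <- bias_potential(grid = data.frame(s = nodes, V = V[, 1L]))
  hills_df <- lapply(hill_log, function(hl)
    data.frame(time = hl$time, center = hl$center,
               sigma = rep(p$delta, length(hl$time)),
               height = hl$height))
  out <- list(series = series, bias = final_bias,
              per_walker_hills = hills_df, params = p, schedule = sched,
              system = sys)
  class(out) <- "toy_run"
  out
}

#' Normalized reweighting weights for a frozen-bias trajectory
#'
#' Frames collected under a constant bias carry weight proportional to
#' `exp(+V_G(s)/kB T)`; the maximum bias value is subtracted before
#' exponentiation to avoid overflow.
#'
#' @param series a [cv_series()] or data frame with column `xi`.
#' @param b the frozen [bias_potential()].
#' @param p a [wt_params()] (only `T` is used).
#' @return Normalized per-frame weights.
#' @export
reweight_weights <- function(series, b, p) {
  v <- evaluate_bias(b, series$xi)
  lw <- v / (p$kB * p$T)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Unbiased average of an observable from frozen-bias sampling
#'
#' @inheritParams reweight_weights
#' @param values per-frame observable values (defaults to the CV itself).
#' @return The reweighted (unbiased) average.
#' @export
reweight_wt <- function(series, b, p, values = series$xi) {
  if (length(values) != nrow(series))
    stop("values must align with the frames of the series")
  sum(reweight_weights(series, b, p) * values)
}
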