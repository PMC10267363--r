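## Maximal-constrained-entropy reweighting of a metastatistics ensemble:
## exponential tilt exp(-lambda*xi)/Z solving <xi> = s, cross-entropy,
## constrained averages, free-energy profiles and ddG.

#' Metastatistics ensemble
#'
#' Enumerated frames of a frozen-bias (or otherwise biased) simulation:
#' a data frame with columns `xi` (CV value), `energy` (kJ/mol, the
#' mean-field solute energy or enthalpy), and optionally `xi_prime`
#' (extended CV), `multiplicity` (frame weight, default 1), `walker`
#' (source walker id, used by the jackknife) and `time` (ps).
#'
#' @param frames data frame with at least `xi` and `energy`.
#' @return The validated frame table with class `metastatistics`.
#' @export
metastatistics <- function(frames) {
  if (!all(c("xi", "energy") %in% names(frames)))
    stop("metastatistics needs columns xi and energy")
  frames <- as.data.frame(frames, stringsAsFactors = FALSE)
  if (is.null(frames$multiplicity)) frames$multiplicity <- 1
  if (any(frames$multiplicity < 0)) stop("multiplicities must be >= 0")
  if (sum(frames$multiplicity) <= 0)
    stop("multiplicities must not be all zero")
  if (is.null(frames$walker)) frames$walker <- 1L
  class(frames) <- c("metastatistics", "data.frame")
  frames
}

# the CV column the constraint acts on
mec_cv <- function(ms, cv = c("xi", "xi_prime")) {
  cv <- match.arg(cv)
  if (is.null(ms[[cv]])) stop("ensemble has no column ", cv)
  ms[[cv]]
}

#' Metastatistics frame probabilities
#'
#' `P_tilde[g] = multiplicity[g] / sum(multiplicity)`.
#'
#' @param ms a [metastatistics()] object.
#' @return Per-frame probabilities summing to one.
#' @export
metastat_probability <- function(ms) {
  w <- ms$multiplicity
  w / sum(w)
}

# log weights of the tilted distribution: log P_tilde - lambda*xi, and the
# stabilized log partition function; shared workhorse for everything below
tilt_logz <- function(logp, xi, lam) {
  lw <- logp - lam * xi
  m <- max(lw)
  logZ <- m + log(sum(exp(lw - m)))
  list(lw = lw, logZ = logZ)
}

# <B>_lambda with max-shifted exponentials
tilt_average <- function(logp, xi, lam, values) {
  lw <- logp - lam * xi
  m <- max(lw)
  w <- exp(lw - m)
  sum(w * values) / sum(w)
}

#' Solve for the tilt parameter lambda at a target mean CV
#'
#' Finds the `lambda` for which the exponentially tilted metastatistics
#' satisfies `<xi>_lambda = s_target`.  The map `lambda -> <xi>_lambda` is
#' strictly decreasing (its derivative is `-Var_lambda(xi)`), so a
#' geometrically expanded bracket followed by bisection converges globally.
#'
#' @param ms a [metastatistics()].
#' @param s_target target mean, strictly inside `(min xi, max xi)`.
#' @param cv which CV column the constraint acts on.
#' @param tol residual tolerance as a fraction of the CV range.
#' @param max_iter bisection iteration cap.
#' @return The scalar `lambda`.
#' @export
solve_lambda <- function(ms, s_target, cv = "xi", tol = 1e-10,
                         max_iter = 200L) {
  xi <- mec_cv(ms, cv)
  if (length(unique(xi)) < 2L)
    stop("need at least 2 distinct CV values to solve for lambda")
  rng <- range(xi)
  if (s_target <= rng[1L] || s_target >= rng[2L])
    stop("target s = ", s_target, " is outside the open CV support (",
         rng[1L], ", ", rng[2L], ") and is unreachable")
  logp <- log(metastat_probability(ms))
  gfun <- function(lam) tilt_average(logp, xi, lam, xi) - s_target
  lo <- -1; hi <- 1
  g_lo <- gfun(lo); g_hi <- gfun(hi)
  # g is decreasing: g(-inf) -> max(xi)-s > 0, g(+inf) -> min(xi)-s < 0
  expand <- 0L
  while (g_lo < 0 && expand < 200L) { lo <- 2 * lo; g_lo <- gfun(lo); expand <- expand + 1L }
  while (g_hi > 0 && expand < 400L) { hi <- 2 * hi; g_hi <- gfun(hi); expand <- expand + 1L }
  if (g_lo < 0 || g_hi > 0)
    stop("lambda solver failed to bracket the constraint at s = ", s_target)
  tol_abs <- tol * diff(rng)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- gfun(mid)
    if (abs(g_mid) <= tol_abs) return(mid)
    if (g_mid > 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-15 * max(1, abs(mid))) break
  }
  mid <- (lo + hi) / 2
  if (abs(gfun(mid)) > tol_abs)
    stop("lambda solver did not reach tolerance at s = ", s_target)
  mid
}

#' Modulated (tilted) frame probabilities
#'
#' `P[g] = P_tilde[g] * exp(-lambda * xi[g]) / Z_lambda`, computed with a
#' max shift so large `lambda * xi` cannot overflow.
#'
#' @param ms a [metastatistics()].
#' @param lam tilt parameter.
#' @param cv which CV column to tilt on.
#' @return Per-frame probabilities summing to one.
#' @export
modulation_weights <- function(ms, lam, cv = "xi") {
  xi <- mec_cv(ms, cv)
  lw <- log(metastat_probability(ms)) - lam * xi
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Maximal cross-entropy at the constrained solution
#'
#' `S_c = ln Z_lambda + lambda * s_target`, which equals minus the
#' Kullback-Leibler divergence of the tilted distribution from the
#' metastatistics; both routes are computed and asserted to agree.
#'
#' @param ms a [metastatistics()].
#' @param lam the solution of [solve_lambda()] for `s_target`.
#' @param s_target the constrained mean.
#' @param cv which CV column the constraint acts on.
#' @param check_tol agreement tolerance between the two routes.
#' @return The (non-positive) maximal cross-entropy.
#' @export
cross_entropy_max <- function(ms, lam, s_target, cv = "xi",
                              check_tol = 1e-9) {
  xi <- mec_cv(ms, cv)
  pt <- metastat_probability(ms)
  tz <- tilt_logz(log(pt), xi, lam)
  sc <- tz$logZ + lam * s_target
  p <- modulation_weights(ms, lam, cv)
  keep <- p > 0
  sc_kl <- -sum(p[keep] * log(p[keep] / pt[keep]))
  if (abs(sc - sc_kl) > check_tol * max(1, abs(sc)))
    stop("cross-entropy identity violated (|", sc, " - ", sc_kl,
         "| too large); is lambda the solution for s_target?")
  sc
}

#' Constrained (tilted) average of a per-frame observable
#'
#' `<B>_lambda = sum_g P_tilde[g] exp(-lambda xi[g]) B[g] / Z_lambda`.
#'
#' @param ms a [metastatistics()].
#' @param lam tilt parameter.
#' @param values per-frame observable values aligned with the frames.
#' @param cv which CV column the tilt acts on.
#' @return The constrained average.
#' @export
constrained_average <- function(ms, lam, values, cv = "xi") {
  if (length(values) != nrow(ms))
    stop("values must align with the ensemble frames")
  xi <- mec_cv(ms, cv)
  tilt_average(log(metastat_probability(ms)), xi, lam, values)
}

#' Free energy of one constrained macrostate
#'
#' `G(s) = <U>_lambda - T_eff * kB * S_c(s)`, with `lambda` solving the
#' constraint `<xi>_lambda = s`.  The identification of the informational
#' cross-entropy with a thermodynamic entropy is empirical, so the
#' effective temperature is always explicit.
#'
#' @param ms a [metastatistics()].
#' @param s_target the constrained mean CV value.
#' @param T_eff effective temperature (K).
#' @param cv which CV column the constraint acts on.
#' @return Object of class `mec_solution`: a list with `s_target`, `lambda`,
#'   `logZ`, `cross_entropy`, `mean_energy`, `G` and `T_eff`.
#' @export
free_energy_mec <- function(ms, s_target, T_eff = 300, cv = "xi") {
  lam <- solve_lambda(ms, s_target, cv = cv)
  xi <- mec_cv(ms, cv)
  logp <- log(metastat_probability(ms))
  tz <- tilt_logz(logp, xi, lam)
  sc <- tz$logZ + lam * s_target
  mean_u <- tilt_average(logp, xi, lam, ms$energy)
  out <- list(s_target = s_target, lambda = lam, logZ = tz$logZ,
              cross_entropy = sc, mean_energy = mean_u,
              G = mean_u - T_eff * kB_kJmolK * sc, T_eff = T_eff)
  class(out) <- "mec_solution"
  out
}

#' @export
print.mec_solution <- function(x, ...) {
  cat(sprintf(
    "mec_solution: s = %.4g, lambda = %.4g, Sc = %.4g, <U> = %.4g, G = %.4g kJ/mol\n",
    x$s_target, x$lambda, x$cross_entropy, x$mean_energy, x$G))
  invisible(x)
}

# G(s) - G(s0) for one ensemble (no uncertainty), returning NA at
# unreachable targets; used by the profile and its jackknife replicates
profile_values <- function(ms, s_grid, s0, T_eff, cv) {
  g0 <- free_energy_mec(ms, s0, T_eff, cv)$G
  vapply(s_grid, function(s) {
    if (abs(s - s0) < 1e-12) return(0)
    tryCatch(free_energy_mec(ms, s, T_eff, cv)$G - g0,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' MEC free-energy profile over a grid of target states
#'
#' Computes `G(s) - G(s0)` for every `s` in `s_grid`.  Per-point
#' uncertainty is a leave-one-walker-out jackknife over the `walker`
#' labels (set `uncertainty = "none"` to skip it).  Unreachable grid
#' points (outside the CV support) are returned as `NA` with a warning.
#'
#' @param ms a [metastatistics()].
#' @param s_grid CV values at which to evaluate the profile.
#' @param s0 reference state (where `G` is zeroed).
#' @param T_eff effective temperature (K).
#' @param cv which CV column the constraint acts on.
#' @param uncertainty `"jackknife"` or `"none"`.
#' @return Data frame of class `fe_profile` with columns `s`, `G`, `G_err`,
#'   `lambda`, `Sc`, `meanU`; attributes `s0` and `T_eff`.
#' @export
mec_profile <- function(ms, s_grid, s0, T_eff = 300, cv = "xi",
                        uncertainty = c("jackknife", "none")) {
  uncertainty <- match.arg(uncertainty)
  sols <- lapply(s_grid, function(s)
    tryCatch(free_energy_mec(ms, s, T_eff, cv),
             error = function(e) NULL))
  bad <- vapply(sols, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " unreachable grid point(s) skipped: s = ",
            paste(s_grid[bad], collapse = ", "))
  g0 <- free_energy_mec(ms, s0, T_eff, cv)$G
  take <- function(f) vapply(sols, function(x)
    if (is.null(x)) NA_real_ else f(x), numeric(1))
  out <- data.frame(s = s_grid, G = take(function(x) x$G) - g0,
                    G_err = NA_real_,
                    lambda = take(function(x) x$lambda),
                    Sc = take(function(x) x$cross_entropy),
                    meanU = take(function(x) x$mean_energy))
  if (uncertainty == "jackknife") {
    walkers <- unique(ms$walker)
    if (length(walkers) >= 2L) {
      reps <- vapply(walkers, function(wk) {
        sub <- metastatistics(ms[ms$walker != wk, , drop = FALSE])
        profile_values(sub, s_grid, s0, T_eff, cv)
      }, numeric(length(s_grid)))
      reps <- matrix(reps, nrow = length(s_grid))
      nw <- length(walkers)
      jk_mean <- rowMeans(reps, na.rm = TRUE)
      out$G_err <- sqrt((nw - 1) / nw *
                          rowSums((reps - jk_mean)^2, na.rm = TRUE))
    }
  }
  attr(out, "s0") <- s0
  attr(out, "T_eff") <- T_eff
  attr(out, "cv") <- cv
  class(out) <- c("fe_profile", "data.frame")
  out
}

# profile value at a state (exact grid match or linear interpolation)
profile_at <- function(profile, s) {
  hit <- which(abs(profile$s - s) < 1e-9 & !is.na(profile$G))
  if (length(hit)) return(profile$G[hit[1L]])
  ok <- !is.na(profile$G)
  if (s < min(profile$s[ok]) || s > max(profile$s[ok]))
    stop("state s = ", s, " not covered by the profile")
  approx(profile$s[ok], profile$G[ok], xout = s)$y
}

#' Unfolding free-energy change difference between two profiles
#'
#' `ddG = [G_X(s_unf) - G_X(s_fold)] - [G_0(s_unf) - G_0(s_fold)]`.
#' Positive values mean the variant requires more reversible work to
#' unfold than the reference, i.e. the mutation is stabilizing (the sign
#' tracks the melting-temperature shift).
#'
#' @param profile_variant,profile_reference [mec_profile()] outputs.
#' @param s_unfolded,s_folded CV values of the unfolded and folded states.
#' @return The scalar ddG (kJ/mol).
#' @export
ddg <- function(profile_variant, profile_reference, s_unfolded, s_folded) {
  (profile_at(profile_variant, s_unfolded) -
     profile_at(profile_variant, s_folded)) -
    (profile_at(profile_reference, s_unfolded) -
       profile_at(profile_reference, s_folded))
}
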