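## End-to-end ddG workflow: state selection from CV distributions, MEC
## profiles per variant, the direct metadynamics free-energy route, and
## per-term energy deltas.

#' Select folded and unfolded states from a CV distribution
#'
#' The folded state is the location of the highest peak of the (smoothed)
#' histogram; the unfolded state is the highest remaining local maximum at
#' least `gap` CV units away.  Ties break deterministically toward lower
#' `s`.
#'
#' @param dist data frame with columns `mid` and `P` (from
#'   [cv_distribution()]).
#' @param gap minimum CV separation between the two states.
#' @param smooth moving-average window (bins) applied before peak finding;
#'   use 1 to disable.
#' @return Named vector `c(s_folded = ..., s_unfolded = ...)`.
#' @export
select_states <- function(dist, gap = 5, smooth = 3L) {
  P <- dist$P
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    P <- as.numeric(filter(P, k, sides = 2))
    P[is.na(P)] <- dist$P[is.na(P)]
  }
  n <- length(P)
  if (n < 3L) stop("distribution has too few bins for peak finding")
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else P[i - 1L]
    right <- if (i == n) -Inf else P[i + 1L]
    P[i] > 0 && P[i] >= left && P[i] > right
  }, logical(1))
  peaks <- which(is_max)
  if (length(peaks) < 2L)
    stop("CV distribution is unimodal after smoothing; ",
         "specify the states manually")
  # highest peak, ties toward lower s
  ord <- order(-P[peaks], dist$mid[peaks])
  folded_idx <- peaks[ord[1L]]
  s_folded <- dist$mid[folded_idx]
  far <- peaks[abs(dist$mid[peaks] - s_folded) >= gap]
  if (!length(far))
    stop("no second peak at least ", gap, " CV units from the main peak; ",
         "specify the states manually")
  ord2 <- order(-P[far], dist$mid[far])
  s_unfolded <- dist$mid[far[ord2[1L]]]
  c(s_folded = s_folded, s_unfolded = s_unfolded)
}

#' Direct metadynamics free-energy difference from a bias grid
#'
#' The metadynamics-only route: `G(s) - G(s0)` evaluated from the frozen
#' bias with the well-tempered prefactor, either on the raw grid (linear
#' interpolation) or through the quartic interpolant with linear tails.
#'
#' @param bias_grid data frame with columns `s`, `V`, or a
#'   [bias_potential()] carrying a grid.
#' @param p a [wt_params()].
#' @param s,s0 target and reference CV values.
#' @param interpolate use the degree-4 polynomial interpolant.
#' @param fit_range fitting interval for the interpolant (defaults to the
#'   grid range shrunk by half a CV unit at each end).
#' @return Free-energy differences (kJ/mol), vectorized over `s`.
#' @export
fes_direct <- function(bias_grid, p, s, s0, interpolate = FALSE,
                       fit_range = NULL) {
  if (inherits(bias_grid, "bias_potential")) {
    if (is.null(bias_grid$grid)) bias_grid <- cache_bias_grid(bias_grid)
    bias_grid <- bias_grid$grid
  }
  rng <- range(bias_grid$s)
  if (any(s < rng[1L] - 1e-9) || any(s > rng[2L] + 1e-9) ||
      s0 < rng[1L] - 1e-9 || s0 > rng[2L] + 1e-9)
    stop("requested state outside the bias grid range")
  vfun <- if (interpolate) {
    if (is.null(fit_range)) fit_range <- c(rng[1L] + 0.5, rng[2L] - 0.5)
    interpolate_bias_poly4(bias_grid, fit_range)
  } else {
    function(x) grid_interp(bias_grid, x)
  }
  pref <- (p$T + p$deltaT) / p$deltaT
  -pref * (vfun(s) - vfun(s0))
}

# per-term constrained-average deltas between folded and unfolded states
term_deltas <- function(ms, lam_unf, lam_fold, cv) {
  term_cols <- intersect(c("u_str", "u_bend", "u_tors", "u_vdw", "u_el",
                           "g_solv_np", "g_solv_pol", "energy"),
                         names(ms))
  do.call(rbind, lapply(term_cols, function(tc) {
    data.frame(term = if (tc == "energy") "u_bar" else tc,
               delta = constrained_average(ms, lam_unf, ms[[tc]], cv) -
                 constrained_average(ms, lam_fold, ms[[tc]], cv))
  }))
}

# cheap deterministic checksum of an ensemble, for the run manifest
ensemble_checksum <- function(ms) {
  sprintf("%d:%.8e:%.8e", nrow(ms), sum(ms$xi), sum(ms$energy))
}

#' Run the full ddG workflow
#'
#' For each variant: CV distribution on unit bins, folded/unfolded state
#' selection (or the configured override), MEC free-energy profiles on a
#' shared target grid, ddG against the reference, per-term energy deltas,
#' and (when a bias grid is supplied) the direct metadynamics route for
#' comparison.  Both ddG routes are reported because they can disagree
#' when the biased CV does not capture every slow degree of freedom.
#'
#' @param reference list with `name` and `ensemble` (a [metastatistics()]
#'   or a path readable by [read_ensemble()]); optional `bias` (grid data
#'   frame) for the direct route.
#' @param variants list of such lists.
#' @param cv which CV column the MEC constraint acts on (`"xi"` or
#'   `"xi_prime"`).
#' @param T_eff effective temperature of the entropy term (K).
#' @param states optional named vector `c(s_folded=, s_unfolded=)`
#'   overriding peak selection.
#' @param s_grid optional explicit profile grid; defaults to unit steps
#'   between the two states.
#' @param gap peak-separation parameter of [select_states()].
#' @param uncertainty passed to [mec_profile()].
#' @param wt optional [wt_params()] for the direct route.
#' @param seed seed recorded in the manifest (the workflow itself is
#'   deterministic given the inputs).
#' @return Object of class `ddg_report`: list with `states`, `reference`
#'   (name, profile), `variants` (per variant: name, profile, `ddg`,
#'   `sign_prediction`, `ddg_direct`, `energy_deltas`) and `manifest`.
#' @export
run_pipeline <- function(reference, variants, cv = "xi", T_eff = 300,
                         states = NULL, s_grid = NULL, gap = 5,
                         uncertainty = "none", wt = NULL, seed = 1L) {
  load_ens <- function(x)
    if (is.character(x)) read_ensemble(x) else metastatistics(x)
  ref_ms <- load_ens(reference$ensemble)
  var_ms <- lapply(variants, function(v) load_ens(v$ensemble))
  for (ms in c(list(ref_ms), var_ms))
    if (is.null(ms[[cv]]))
      stop("CV column ", cv, " missing from an ensemble")
  if (is.null(states)) {
    xs <- mec_cv(ref_ms, cv)
    edges <- seq(floor(min(xs)), ceiling(max(xs)), by = 1)
    states <- select_states(cv_distribution(xs, edges), gap = gap)
  }
  s_f <- unname(states["s_folded"]); s_u <- unname(states["s_unfolded"])
  if (is.null(s_grid))
    s_grid <- seq(min(s_f, s_u), max(s_f, s_u), by = 1)
  prof_ref <- mec_profile(ref_ms, s_grid, s0 = s_f, T_eff = T_eff,
                          cv = cv, uncertainty = uncertainty)
  lam_f_ref <- solve_lambda(ref_ms, s_f, cv)
  lam_u_ref <- solve_lambda(ref_ms, s_u, cv)
  out_vars <- lapply(seq_along(variants), function(i) {
    ms <- var_ms[[i]]
    prof <- mec_profile(ms, s_grid, s0 = s_f, T_eff = T_eff, cv = cv,
                        uncertainty = uncertainty)
    dd <- ddg(prof, prof_ref, s_unfolded = s_u, s_folded = s_f)
    dd_direct <- NA_real_
    if (!is.null(variants[[i]]$bias) && !is.null(reference$bias) &&
        !is.null(wt)) {
      dd_direct <- fes_direct(variants[[i]]$bias, wt, s_u, s_f) -
        fes_direct(reference$bias, wt, s_u, s_f)
    }
    lam_f <- solve_lambda(ms, s_f, cv)
    lam_u <- solve_lambda(ms, s_u, cv)
    list(name = variants[[i]]$name, profile = prof, ddg = dd,
         sign_prediction = if (dd > 0) "stabilizing" else "destabilizing",
         ddg_direct = dd_direct,
         energy_deltas = term_deltas(ms, lam_u, lam_f, cv))
  })
  manifest <- list(
    cv = cv, T_eff = T_eff, s_folded = s_f, s_unfolded = s_u,
    s_grid = s_grid, lambda_tolerance = 1e-10, seed = as.integer(seed),
    reference_checksum = ensemble_checksum(ref_ms),
    variant_checksums = vapply(var_ms, ensemble_checksum, character(1)),
    reference_energy_deltas = term_deltas(ref_ms, lam_u_ref, lam_f_ref, cv))
  out <- list(states = c(s_folded = s_f, s_unfolded = s_u),
              reference = list(name = reference$name, profile = prof_ref),
              variants = out_vars, manifest = manifest)
  class(out) <- "ddg_report"
  out
}

#' @export
print.ddg_report <- function(x, ...) {
  cat("ddG report (reference:", x$reference$name, ")\n")
  cat(sprintf("  states: folded s = %g, unfolded s = %g\n",
              x$states["s_folded"], x$states["s_unfolded"]))
  for (v in x$variants)
    cat(sprintf("  %-8s ddG = %8.3f kJ/mol  (%s)%s\n", v$name, v$ddg,
                v$sign_prediction,
                if (is.finite(v$ddg_direct))
                  sprintf("  [direct: %8.3f]", v$ddg_direct) else ""))
  invisible(x)
}

#' Write a ddG report to disk
#'
#' Emits `report.json` (full report), `ddg.tsv` (one row per variant) and
#' `energy_deltas.tsv` (per-term deltas) into a directory.  Output is
#' byte-identical across runs with identical inputs and seed.
#'
#' @param report a `ddg_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(
    states = as.list(report$states),
    reference = list(name = report$reference$name,
                     profile = report$reference$profile),
    variants = lapply(report$variants, function(v)
      list(name = v$name, ddg = v$ddg,
           sign_prediction = v$sign_prediction,
           ddg_direct = v$ddg_direct, profile = v$profile,
           energy_deltas = v$energy_deltas)),
    manifest = report$manifest)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  ddg_tab <- do.call(rbind, lapply(report$variants, function(v)
    data.frame(variant = v$name, ddg = v$ddg,
               ddg_direct = v$ddg_direct,
               sign_prediction = v$sign_prediction)))
  write.table(ddg_tab, file.path(dir, "ddg.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ed <- do.call(rbind, lapply(report$variants, function(v) {
    d <- v$energy_deltas; d$variant <- v$name; d
  }))
  write.table(ed[, c("variant", "term", "delta")],
              file.path(dir, "energy_deltas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
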