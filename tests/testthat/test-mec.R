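# Maximal-constrained-entropy reweighting: lambda solves, tilted weights,
# cross-entropy identities, constrained averages and profiles.

test_that("metastatistics probabilities are normalized multiplicities", {
  ms <- metastatistics(data.frame(xi = 1:4, energy = 0,
                                  multiplicity = c(1, 1, 1, 1)))
  expect_equal(metastat_probability(ms), rep(0.25, 4))
  ms2 <- metastatistics(data.frame(xi = 1:2, energy = 0,
                                   multiplicity = c(1, 3)))
  expect_equal(metastat_probability(ms2), c(0.25, 0.75))
  set.seed(4)
  w <- runif(50)
  ms3 <- metastatistics(data.frame(xi = seq_len(50), energy = 0,
                                   multiplicity = w))
  expect_equal(metastat_probability(ms3), w / sum(w), tolerance = 1e-14)
  expect_equal(sum(metastat_probability(ms3)), 1, tolerance = 1e-12)
  expect_error(metastatistics(data.frame(xi = 1, energy = 0,
                                         multiplicity = 0)), "zero")
})

test_that("lambda vanishes at the unconstrained mean and at symmetry", {
  ms <- tiny_ms()
  s_mean <- sum(metastat_probability(ms) * ms$xi)
  expect_equal(solve_lambda(ms, s_mean), 0, tolerance = 1e-8)
  uni <- metastatistics(data.frame(xi = c(0, 1, 2), energy = 0))
  expect_equal(solve_lambda(uni, 1), 0, tolerance = 1e-8)
})

test_that("lambda solve matches the dual convex minimization", {
  ms <- tiny_ms()
  for (s in c(0.3, 0.5, 0.9, 1.4)) {
    lam <- solve_lambda(ms, s)
    expect_lt(abs(constrained_average(ms, lam, ms$xi) - s), 1e-9)
    # independent route: minimize ln Z(lambda) + lambda * s over lambda
    pt <- metastat_probability(ms)
    dual <- function(l) log(sum(pt * exp(-l * ms$xi))) + l * s
    lam_dual <- optimize(dual, c(-50, 50), tol = 1e-12)$minimum
    expect_equal(lam, lam_dual, tolerance = 1e-6)
  }
  expect_error(solve_lambda(ms, 2.5), "unreachable")
  expect_error(solve_lambda(ms, 0), "unreachable")
  one <- metastatistics(data.frame(xi = c(1, 1), energy = 0))
  expect_error(solve_lambda(one, 1), "distinct")
})

test_that("modulation weights follow the exponential tilt", {
  ms <- metastatistics(data.frame(xi = c(0, 1), energy = 0))
  expect_equal(modulation_weights(ms, log(3)), c(0.75, 0.25),
               tolerance = 1e-12)
  ms2 <- tiny_ms()
  expect_equal(modulation_weights(ms2, 0), metastat_probability(ms2),
               tolerance = 1e-14)
  for (lam in c(-700, -3, 0.7, 900))      # max-shift guards huge exponents
    expect_equal(sum(modulation_weights(ms2, lam)), 1, tolerance = 1e-12)
})

test_that("cross-entropy maximum equals minus the KL divergence", {
  ms <- tiny_ms()
  expect_equal(cross_entropy_max(ms, 0,
                                 sum(metastat_probability(ms) * ms$xi)),
               0, tolerance = 1e-9)
  for (s in c(0.4, 0.8, 1.3)) {
    lam <- solve_lambda(ms, s)
    sc <- cross_entropy_max(ms, lam, s)     # internally asserts the identity
    expect_lte(sc, 1e-12)
    # direct functional evaluation (absolute agreement)
    p <- modulation_weights(ms, lam)
    pt <- metastat_probability(ms)
    expect_lt(abs(sc - (-sum(p * log(p / pt)))), 1e-9)
  }
  # mismatched lambda/s pair is rejected
  expect_error(cross_entropy_max(ms, 2.0, 1.4), "identity")
})

test_that("constrained averages reproduce hand-computed tilts", {
  ms <- tiny_ms()
  pt <- metastat_probability(ms)
  expect_equal(constrained_average(ms, 0, ms$energy), sum(pt * ms$energy),
               tolerance = 1e-12)
  lam <- solve_lambda(ms, 0.7)
  expect_equal(constrained_average(ms, lam, ms$xi), 0.7, tolerance = 1e-9)
  w <- pt * exp(-lam * ms$xi)
  expect_equal(constrained_average(ms, lam, ms$energy),
               sum(w * ms$energy) / sum(w), tolerance = 1e-10)
  expect_error(constrained_average(ms, 0, 1:2), "align")
})

test_that("tilted solution matches brute-force constrained maximization", {
  set.seed(12)
  for (rep in 1:4) {
    n <- sample(4:12, 1)
    xi <- sort(runif(n, 0, 16))
    mult <- runif(n, 0.2, 2)
    ms <- metastatistics(data.frame(xi = xi, energy = rnorm(n),
                                    multiplicity = mult))
    pt <- metastat_probability(ms)
    s <- runif(1, quantile(xi, 0.25), quantile(xi, 0.75))
    lam <- solve_lambda(ms, s)
    p_tilt <- modulation_weights(ms, lam)
    p_brute <- brute_force_mec(pt, xi, s)
    expect_lt(max(abs(p_tilt - p_brute)), 1e-7)
    # the two routes agree on the attained maximum as well
    sc_tilt <- cross_entropy_max(ms, lam, s)
    sc_brute <- -sum(p_brute * log(p_brute / pt))
    expect_lt(abs(sc_tilt - sc_brute), 1e-7)
  }
})

test_that("lambda is strictly decreasing along the target grid", {
  spec <- ensemble_spec(n_frames = 5000, n_walkers = 5, sigma_E = 1,
                        seed = 3)
  ms <- sample_metastatistics(spec)
  s_grid <- seq(3, 14, by = 1)
  lams <- vapply(s_grid, function(s) solve_lambda(ms, s), numeric(1))
  expect_true(all(diff(lams) < 0))
  # S_c <= 0 with equality only at the unconstrained mean
  scs <- vapply(seq_along(s_grid), function(i)
    cross_entropy_max(ms, lams[i], s_grid[i]), numeric(1))
  expect_true(all(scs <= 1e-10))
  s_mean <- mean(ms$xi)
  expect_gt(min(abs(scs[abs(s_grid - s_mean) > 1])), 1e-4)
})

test_that("free energy at the unconstrained mean is the plain mean energy", {
  ms <- tiny_ms()
  s_mean <- sum(metastat_probability(ms) * ms$xi)
  sol <- free_energy_mec(ms, s_mean, T_eff = 300)
  expect_equal(sol$lambda, 0, tolerance = 1e-8)
  expect_equal(sol$G, sum(metastat_probability(ms) * ms$energy),
               tolerance = 1e-6)
  # the -T kB Sc term is never negative
  for (s in c(0.4, 1.2))
    expect_gte(free_energy_mec(ms, s)$G,
               constrained_average(ms, solve_lambda(ms, s), ms$energy) - 1e-12)
})

test_that("profiles are referenced, jackknifed and flag unreachable points", {
  spec <- ensemble_spec(n_frames = 4000, n_walkers = 8, sigma_E = 1,
                        seed = 5)
  ms <- sample_metastatistics(spec)
  prof <- mec_profile(ms, s_grid = c(4, 7, 10, 14), s0 = 14, T_eff = 300)
  expect_equal(prof$G[prof$s == 14], 0)
  expect_true(all(is.finite(prof$G_err)))
  expect_true(all(prof$G_err[prof$s != 14] > 0))
  prof0 <- mec_profile(ms, s_grid = 14, s0 = 14, uncertainty = "none")
  expect_equal(prof0$G, 0)
  expect_true(is.na(prof0$G_err))
  expect_warning(mec_profile(ms, s_grid = c(7, 40), s0 = 14,
                             uncertainty = "none"), "unreachable")
})

test_that("MEC profile recovers the generator's free-energy differences", {
  spec <- ensemble_spec(n_frames = 40000, n_walkers = 10, sigma_E = 2,
                        seed = 11)
  ms <- sample_metastatistics(spec)
  s_grid <- c(4, 8, 11, 14)
  prof <- mec_profile(ms, s_grid, s0 = 14, T_eff = 300)
  gs <- g_star(spec, s_grid) - g_star(spec, 14)
  # within 3 jackknife SE at every grid point away from the reference
  for (i in which(s_grid != 14))
    expect_lt(abs(prof$G[i] - gs[i]), 3 * prof$G_err[i] + 1e-9)
})

test_that("injected stability gap is recovered as the ddG", {
  ref <- sample_metastatistics(ensemble_spec(
    n_frames = 30000, n_walkers = 6, sigma_E = 2, delta_stab = 0,
    seed = 21))
  var <- sample_metastatistics(ensemble_spec(
    n_frames = 30000, n_walkers = 6, sigma_E = 2, delta_stab = 6,
    seed = 22))
  s_grid <- c(4, 9, 14)
  pr <- mec_profile(ref, s_grid, s0 = 14, uncertainty = "none")
  pv <- mec_profile(var, s_grid, s0 = 14, uncertainty = "none")
  dd <- ddg(pv, pr, s_unfolded = 4, s_folded = 14)
  expect_equal(dd, 6, tolerance = 0.15)
  # identical profiles give exactly zero
  expect_equal(ddg(pr, pr, 4, 14), 0)
})
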