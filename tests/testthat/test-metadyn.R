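# Well-tempered bias construction, altruistic combination, the toy
# Langevin sampler and reweighting.

test_that("bias evaluation matches the Gaussian sum arithmetic", {
  b <- bias_potential()
  expect_equal(evaluate_bias(b, c(-3, 0, 7)), c(0, 0, 0))
  b <- bias_potential(hills = data.frame(time = 0, center = 5, sigma = 1,
                                         height = 2))
  expect_equal(evaluate_bias(b, 5), 2)
  expect_equal(evaluate_bias(b, 6), 2 * exp(-1 / 2), tolerance = 1e-12)
  b$offset <- 1.5
  expect_equal(evaluate_bias(b, 5), 3.5)
})

test_that("tempered hill heights follow the bias history", {
  p <- wt_params(T = 300, biasf = 20, w = 1, delta = 1)
  expect_equal(p$deltaT, 5700)
  expect_equal(biasing_factor(p), 20)
  b <- deposit_hill(bias_potential(), 5, p, 0)
  expect_equal(b$hills$height, 1)                      # exp(0) = 1
  b <- deposit_hill(b, 5, p, 20)
  expect_equal(b$hills$height[2], p$w * exp(-p$w / (p$kB * p$deltaT)),
               tolerance = 1e-12)
  # independent recursion over repeated deposits at a fixed center
  b2 <- bias_potential()
  v <- 0
  for (k in 1:6) {
    h_expect <- p$w * exp(-v / (p$kB * p$deltaT))
    b2 <- deposit_hill(b2, 2, p, 20 * k)
    expect_equal(b2$hills$height[k], h_expect, tolerance = 1e-10)
    v <- v + h_expect
  }
  # heights are non-increasing at a revisited center
  expect_true(all(diff(b2$hills$height) <= 0))
})

test_that("untempered deposits keep the bare height", {
  p <- wt_params(T = 300, w = 0.7, tempered = FALSE)
  b <- bias_potential()
  for (k in 1:5) b <- deposit_hill(b, k, p, k)
  expect_equal(b$hills$height, rep(0.7, 5))
})

test_that("bias-to-free-energy conversion uses the WT prefactor", {
  p <- wt_params(T = 300, biasf = 20)
  grid <- data.frame(s = 0:10, V = -(0:10))            # V drops 1 per unit
  b <- bias_potential(grid = grid)
  expect_equal(free_energy_from_bias(b, p, 3, 3), 0)
  expect_equal(free_energy_from_bias(b, p, 1, 0), 6000 / 5700,
               tolerance = 1e-12)
  # offset invariance
  b2 <- b; b2$offset <- 123.4
  expect_equal(free_energy_from_bias(b2, p, 7, 2),
               free_energy_from_bias(b, p, 7, 2), tolerance = 1e-12)
  expect_error(free_energy_from_bias(b, wt_params(tempered = FALSE), 1, 0))
})

test_that("grid cache agrees with the hill sum on its nodes", {
  p <- wt_params(T = 300, biasf = 20, w = 1, delta = 0.8)
  b <- bias_potential()
  set.seed(21)
  for (k in 1:40) b <- deposit_hill(b, runif(1, 0, 10), p, k)
  bc <- cache_bias_grid(b, lo = 0, hi = 10, spacing = 0.1)
  direct <- evaluate_bias(b, bc$grid$s)
  expect_equal(bc$grid$V + b$offset, direct, tolerance = 1e-12)
})

test_that("altruistic combination obeys its limits and hand values", {
  mk <- function(v) bias_potential(grid = data.frame(s = 0:10, V = rep(v, 11)))
  # alpha = 0: identity (the first exchange stage of the production schedule)
  out <- altruistic_combine(list(mk(0), mk(2)), alpha = 0, w_share = 1)
  expect_equal(out[[1]]$grid$V, rep(0, 11))
  expect_equal(out[[2]]$grid$V, rep(2, 11))
  # identical biases are a fixed point at full mixing
  out2 <- altruistic_combine(list(mk(3), mk(3), mk(3)), 1, 0)
  for (o in out2) expect_equal(o$grid$V, rep(3, 11))
  # alpha = 1, w = 1/2, constants 0 and 2 -> 0.5 and 1.5
  out3 <- altruistic_combine(list(mk(0), mk(2)), 1, 0.5)
  expect_equal(out3[[1]]$grid$V, rep(0.5, 11))
  expect_equal(out3[[2]]$grid$V, rep(1.5, 11))
  expect_error(altruistic_combine(list(), 1, 0.5), "empty")
})

test_that("final averaging equals the per-node mean over many walkers", {
  set.seed(5)
  biases <- lapply(1:90, function(i)
    bias_potential(grid = data.frame(s = 0:20, V = rnorm(21))))
  avg <- average_bias_final(biases)
  brute <- rowMeans(vapply(biases, function(b) b$grid$V, numeric(21)))
  expect_equal(avg$grid$V, brute, tolerance = 1e-12)
  # two constants average to their mean
  two <- average_bias_final(list(
    bias_potential(grid = data.frame(s = 0:5, V = 0)),
    bias_potential(grid = data.frame(s = 0:5, V = 4))))
  expect_equal(two$grid$V, rep(2, 6))
})

test_that("quartic interpolant reproduces polynomials and stays C1", {
  s <- seq(0, 16, by = 0.25)
  coef_true <- c(2, -1, 0.5, -0.05, 0.002)
  v <- drop(outer(s - 8, 0:4, `^`) %*% coef_true)    # quartic around mid
  f <- interpolate_bias_poly4(data.frame(s = s, V = v), c(0.5, 15.5))
  expect_equal(attr(f, "coefficients"), coef_true, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f(seq(1, 15, by = 0.1)),
               drop(outer(seq(1, 15, by = 0.1) - 8, 0:4, `^`) %*% coef_true),
               tolerance = 1e-8)
  # C1 continuity at both ends: value jump and slope jump both vanish
  eps <- 1e-5
  for (edge in c(0.5, 15.5)) {
    jump <- f(edge + eps) + f(edge - eps) - 2 * f(edge)
    expect_lt(abs(jump), 1e-9 + 10 * eps^2)     # curvature term only
    slope_in <- (f(edge) - f(edge - eps)) / eps
    slope_out <- (f(edge + eps) - f(edge)) / eps
    expect_equal(slope_in, slope_out, tolerance = 1e-3)
  }
  # linear continuation outside
  expect_equal(f(-2) - f(-1), f(-1) - f(0), tolerance = 1e-8)
  expect_error(interpolate_bias_poly4(data.frame(s = 1:4, V = 1:4),
                                      c(0, 5)), "5 grid nodes")
})

test_that("noisy quartic fit matches an independent normal-equations solve", {
  set.seed(33)
  s <- seq(0, 16, by = 0.2)
  truth <- 0.3 * (s - 8)^2 - 0.01 * (s - 8)^4
  v <- truth + rnorm(length(s), 0, 0.05)
  fit_range <- c(0.5, 15.5)
  f <- interpolate_bias_poly4(data.frame(s = s, V = v), fit_range)
  inside <- s >= fit_range[1] & s <= fit_range[2]
  X <- outer(s[inside] - mean(fit_range), 0:4, `^`)
  beta_ne <- solve(crossprod(X), crossprod(X, v[inside]))
  expect_equal(attr(f, "coefficients"), drop(beta_ne), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("schedule bookkeeping reproduces the production staging", {
  sched <- table_schedule(collect_ns = 10)
  d <- schedule_durations(sched)
  expect_equal(unname(d["construction_ns"]), 22)
  expect_equal(unname(d["pre_collection_ns"]), 30)
  expect_equal(unname(d["total_ns"]), 40)
  # the larger-protein variant only changes the collection stage
  d30 <- schedule_durations(table_schedule(collect_ns = 30))
  expect_equal(unname(d30["construction_ns"]), 22)
  expect_equal(unname(d30["total_ns"]), 60)
  expect_error(md_schedule(data.frame(label = "x", length_ns = -1,
                                      alpha = NA, w_share = NA,
                                      bias_updated = FALSE)))
})

test_that("zero-temperature relaxation stays in a minimum", {
  sys <- make_double_well(barrier = 10, center = 5, half_sep = 2,
                          temperature = 0, s_init = 3, seed = 1)
  sched <- md_schedule(data.frame(label = "collect", length_ns = 0.02,
                                  alpha = NA, w_share = NA,
                                  bias_updated = FALSE))
  p <- wt_params(T = 300, biasf = 20)
  run <- run_toy_walker(sys, p, sched, output_every_ps = 0.1)
  expect_true(all(abs(run$series$xi - 3) < 1e-6))
})

test_that("toy runs are bitwise reproducible from the seed", {
  sys <- make_double_well(seed = 77)
  p <- wt_params(T = 300, biasf = 20, w = 1, delta = 0.3, tau_G = 10)
  sched <- md_schedule(data.frame(
    label = c("build", "collect"), length_ns = c(0.3, 0.2),
    alpha = c(1, NA), w_share = c(0.5, NA), bias_updated = c(TRUE, FALSE)))
  r1 <- run_toy_walker(sys, p, sched, n_walkers = 3, exchange_ns = 0.1)
  r2 <- run_toy_walker(sys, p, sched, n_walkers = 3, exchange_ns = 0.1)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$bias$grid, r2$bias$grid)
  # multi-walker: final bias is shared (walker averaging happened)
  expect_equal(nrow(r1$series) %% 3, 0L)
})

test_that("symmetric double well is sampled evenly after construction", {
  sys <- make_double_well(barrier = 8, center = 8, half_sep = 3, seed = 19)
  p <- wt_params(T = 300, biasf = 20, w = 1, delta = 0.3, tau_G = 10)
  sched <- md_schedule(data.frame(
    label = c("build", "collect"), length_ns = c(6, 3),
    alpha = c(0, NA), w_share = c(1, NA), bias_updated = c(TRUE, FALSE)))
  run <- run_toy_walker(sys, p, sched)
  frac_left <- mean(run$series$xi < 8)
  # both wells visited substantially; symmetric landscape keeps the split
  # within the Monte-Carlo error of a short correlated trajectory
  expect_gt(frac_left, 0.2)
  expect_lt(frac_left, 0.8)
  # reweighted populations also near 1/2
  p_left <- reweight_wt(run$series, run$bias, p,
                        as.numeric(run$series$xi < 8))
  expect_gt(p_left, 0.25)
  expect_lt(p_left, 0.75)
})

test_that("reweighting reduces to the plain mean under flat bias", {
  set.seed(8)
  series <- cv_series(1:500, runif(500, 0, 10))
  vals <- rnorm(500)
  p <- wt_params(T = 300, biasf = 20)
  expect_equal(reweight_wt(series, bias_potential(), p, vals), mean(vals),
               tolerance = 1e-12)
  const <- bias_potential(grid = data.frame(s = c(0, 10), V = c(7, 7)))
  expect_equal(reweight_wt(series, const, p, vals), mean(vals),
               tolerance = 1e-12)
  expect_error(reweight_wt(series, const, p, vals[-1]), "align")
})

test_that("HILLS and bias-grid files round trip", {
  p <- wt_params(T = 300, biasf = 20, w = 1, delta = 0.5)
  b <- bias_potential()
  for (k in 1:5) b <- deposit_hill(b, k / 2, p, 20 * k)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hills(b, path, biasf = biasing_factor(p))
  back <- read_hills(path)
  expect_equal(back$hills$center, b$hills$center, tolerance = 1e-9)
  expect_equal(back$hills$height, b$hills$height, tolerance = 1e-9)
  gpath <- withr::local_tempfile(fileext = ".dat")
  grid <- data.frame(s = seq(0, 5, 0.5), V = sin(seq(0, 5, 0.5)))
  write_bias_grid(grid, gpath, T = 300, deltaT = 5700)
  gback <- read_bias_grid(gpath)
  expect_equal(gback$V, grid$V, tolerance = 1e-9)
  expect_equal(attr(gback, "deltaT"), 5700)
})
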