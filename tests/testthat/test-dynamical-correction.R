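test_that("epsilon fitting recovers exactly constructed hyperbolic data", {
  set.seed(2)
  fc <- runif(300, 0.1, 30)
  expect_equal(fit_epsilon(fc, fc), 0)
  fo <- sqrt(fc^2 + 4)                  # exact hyperbola, eps = 2
  expect_equal(fit_epsilon(fo, fc), 2, tolerance = 1e-6)
  expect_error(fit_epsilon(numeric(0), numeric(0)), "empty")
  # agreement with a fine brute-force grid search
  fo2 <- sqrt(fc^2 + 4) + rnorm(300, 0, 0.5)
  obj <- function(e) sum((fo2 - sqrt(fc^2 + e^2))^2)
  grid <- seq(0, 10, by = 1e-4)
  e_grid <- grid[which.min(vapply(grid, obj, 0))]
  expect_equal(fit_epsilon(fo2, fc), e_grid, tolerance = 1e-3)
})

test_that("scale and epsilon alternation undoes an arbitrary data scale", {
  set.seed(4)
  fc <- runif(500, 0.1, 40)
  fo <- 3.7 * sqrt(fc^2 + 2.5^2)        # scaled exact hyperbola
  fit <- fit_epsilon_scaled(fo, fc)
  expect_equal(fit$k, 3.7, tolerance = 1e-4)
  expect_equal(fit$epsilon, 2.5, tolerance = 1e-4)
})

test_that("binned fits are exact per bin on constructed data", {
  set.seed(6)
  n <- 400
  d <- sort(runif(n, 0.8, 6), decreasing = TRUE)
  rs <- reflection_set(seq_len(n), rep(1, n), rep(1, n), rep(1, n),
                       rep(0, n))
  rs$d <- d
  bng <- assign_resolution_bins(rs, 10)
  fc <- runif(n, 0.5, 25)
  # constant eps = 2 everywhere, constructed exactly
  bins <- fit_epsilon_binned(sqrt(fc^2 + 4), fc, bng)
  expect_equal(bins$epsilon, rep(2, 10), tolerance = 1e-5)
  # one bin with F_obs = F_calc gives zero in that bin
  fo <- sqrt(fc^2 + 4); fo[bng$index[[3]]] <- fc[bng$index[[3]]]
  bins2 <- fit_epsilon_binned(fo, fc, bng)
  expect_equal(bins2$epsilon[3], 0, tolerance = 1e-8)
  # resolution-dependent eps(d) = 0.5 d + 0.2: fitted bins increase with d
  eps_d <- 0.5 * d + 0.2
  bins3 <- fit_epsilon_binned(sqrt(fc^2 + eps_d^2), fc, bng)
  expect_true(all(diff(bins3$epsilon) < 0))   # bins ordered large d -> small
  # under-filled bin falls back to the global value with a warning
  small <- reflection_set(1:8, rep(1, 8), rep(1, 8), rep(1, 8), rep(0, 8))
  small$d <- 8:1
  bs <- assign_resolution_bins(small, 2)
  suppressWarnings(
    expect_warning(fit_epsilon_binned(sqrt((1:8)^2 + 1), 1:8, bs),
                   "global"))
})

test_that("continuous forms are recovered and the step form is exact", {
  bins <- data.frame(mean_d = seq(0.9, 3.6, length.out = 10))
  bins$epsilon <- 3 * bins$mean_d + 1
  bins$d_max <- bins$mean_d + 0.1; bins$d_min <- bins$mean_d - 0.1
  bins$n <- 50
  lin <- fit_continuous(bins, "linear")
  expect_equal(unname(lin$params["a"]), 3, tolerance = 1e-8)
  expect_equal(unname(lin$params["b"]), 1, tolerance = 1e-8)
  expect_equal(epsilon_of_d(lin, 2), 7, tolerance = 1e-8)
  # clamping: below the fitted range the nearest-edge value is used
  expect_equal(epsilon_of_d(lin, 0.1), epsilon_of_d(lin, 0.9))

  # two-term exponential with the shape seen for organic data
  bins2 <- bins
  bins2$epsilon <- 3.64 * exp(0.058 * bins2$mean_d) -
    24.67 * exp(-2.38 * bins2$mean_d)
  ex <- fit_continuous(bins2, "exp2")
  expect_equal(ex$form, "exp2")
  expect_equal(unname(ex$params), c(3.64, 0.058, -24.67, -2.38),
               tolerance = 1e-2)
  expect_equal(epsilon_of_d(ex, bins2$mean_d), pmax(bins2$epsilon, 0),
               tolerance = 1e-6)

  disc <- fit_continuous(bins, "discrete")
  for (i in c(1, 5, 10))
    expect_equal(epsilon_of_d(disc, bins$mean_d[i]), bins$epsilon[i])
  # negative evaluations clamp to zero
  lin2 <- fit_continuous(data.frame(mean_d = c(1, 2), epsilon = c(0, 1),
                                    d_max = c(1.5, 2.5),
                                    d_min = c(0.5, 1.5), n = c(5, 5)),
                         "linear")
  expect_equal(epsilon_of_d(lin2, 0.99), 0)
})

test_that("the intensity inflation factor behaves as a reciprocal Wiener filter", {
  expect_equal(k_dyn(c(1, 10, 100), c(1, 1, 1), 0), c(1, 1, 1))
  expect_equal(k_dyn(4, 1, 2), 2)           # I_kin = eps^2 doubles
  expect_lt(k_dyn(1e6 * 4, 1, 2), 1.000002) # strong limit
  expect_error(k_dyn(-1, 1, 2), "positive")
})

test_that("intensity correction preserves I/sigma and orders, and contracts epsilon", {
  sim <- study_sim(seed = 301)
  rs <- sim$reflections
  rs$sigma <- pmax(0.05 * abs(rs$intensity), 1e-3)  # plausible uncertainties
  fc <- sim$truth$f_kin
  dem <- fit_dynamical_error(rs, fc, form = "linear")
  res <- correct_intensities(rs, dem, f_calc = fc)
  out <- res$reflections

  # identical factor on I and sigma: the ratio is untouched
  expect_equal(out$intensity / out$sigma, rs$intensity / rs$sigma,
               tolerance = 1e-12)
  # factors in (0, 1]; corrected <= observed for positive observations
  expect_true(all(res$report$factor > 0 & res$report$factor <= 1))
  pos <- rs$intensity > 0
  expect_true(all(out$intensity[pos] <= rs$intensity[pos]))
  # with a per-bin (constant within bin) error term, the correction
  # factor is monotone in I, so intensity ordering survives per bin
  dem_disc <- fit_dynamical_error(rs, fc, form = "discrete")
  out_disc <- correct_intensities(rs, dem_disc)$reflections
  bng <- assign_resolution_bins(rs, 10)
  for (b in c(1, 5, 10)) {
    ii <- bng$index[[b]]
    expect_true(all(diff(out_disc$intensity[ii][order(rs$intensity[ii])]) >= 0))
  }
  # refitting on corrected data contracts the error term
  expect_lt(res$report$epsilon_post, res$report$epsilon_pre)

  # a second fit-and-correct pass changes epsilon less than the first
  dem2 <- fit_dynamical_error(out, fc, form = "linear")
  res2 <- correct_intensities(out, dem2, f_calc = fc)
  delta1 <- res$report$epsilon_pre - res$report$epsilon_post
  delta2 <- res2$report$epsilon_pre - res2$report$epsilon_post
  expect_lt(delta2, delta1)
})

test_that("a zero error model is the identity correction", {
  sim <- study_sim(seed = 77, epsilon = 0)
  rs <- sim$reflections
  res <- correct_intensities(rs, 0)
  expect_equal(res$reflections$intensity, rs$intensity)
  expect_equal(res$reflections$sigma, rs$sigma)
  # strong reflections are nearly untouched by a small eps
  res2 <- correct_intensities(
    reflection_set(1, 0, 0, 1e6, 1, cell = unit_cell(10, 10, 10)), 1)
  expect_equal(res2$report$factor, 1, tolerance = 1e-6)
})

test_that("per-bin amplitude correction mirrors the intensity correction", {
  sim <- study_sim(seed = 404, scale = 120)    # protein-scale amplitudes
  rs <- sim$reflections
  fc <- 12 * sim$truth$f_kin                   # calculated on its own scale
  f_obs <- sqrt(pmax(rs$intensity, 0))
  sig_f <- 0.05 * f_obs
  bng <- assign_resolution_bins(rs, 10)
  dem <- fit_dynamical_error(rs, fc, form = "discrete")
  eps_obs <- dem$k * dem$bins$epsilon
  cor <- correct_amplitudes(f_obs, sig_f, bng, eps_obs)

  expect_true(all(cor$factor > 0 & cor$factor <= 1))
  expect_equal(cor$f / cor$sigma, f_obs / sig_f, tolerance = 1e-12)
  # all-zero bins: identity; huge amplitude: factor ~ 1
  id <- correct_amplitudes(f_obs, sig_f, bng, rep(0, 10))
  expect_equal(id$f, f_obs)
  big <- correct_amplitudes(1e8, 1, assign_resolution_bins(
    reflection_set(1, 0, 0, 1, 0, cell = unit_cell(10, 10, 10)), 1), 5)
  expect_equal(big$factor, 1, tolerance = 1e-12)
  # post-correction global epsilon is strictly smaller
  pre <- fit_epsilon_scaled(f_obs, fc)$epsilon
  post <- fit_epsilon_scaled(cor$f, fc)$epsilon
  expect_lt(post, pre)
  # squaring corrected amplitudes reproduces the intensity route
  # (same plug-in: F~ = F_obs when sigma is smaller)
  expect_equal(cor$f^2,
               f_obs^2 * f_obs^2 / (f_obs^2 + eps_obs[bng$assignment]^2),
               tolerance = 1e-10)
})
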