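#' Fit the dynamical error term of the hyperbolic model
#'
#' Dynamical scattering adds a complex-valued component, uncorrelated
#' with the kinematical structure factor, to each observation.  Under
#' that model the expected observed amplitude follows the hyperbola
#' \deqn{\langle|F_{obs}|\rangle = (|F_{calc}|^2 +
#'   \epsilon_{dyn}^2)^{1/2},}
#' whose y intercept is the dynamical error term.  This fits
#' `epsilon >= 0` by unweighted least squares,
#' `min sum (|Fo| - sqrt(Fc^2 + eps^2))^2`, via a bracketing grid
#' followed by 1-D refinement.
#'
#' @param f_obs Observed amplitudes, already on the calculated scale
#'   (see [scale_amplitudes()]).
#' @param f_calc Calculated amplitudes.
#' @return The fitted epsilon (same units as the amplitudes).
#' @export
fit_epsilon <- function(f_obs, f_calc) {
  f_obs <- abs(f_obs); f_calc <- abs(f_calc)
  if (length(f_obs) == 0) stop("cannot fit epsilon on empty input")
  stopifnot(length(f_obs) == length(f_calc))
  obj <- function(e) sum((f_obs - sqrt(f_calc^2 + e * e))^2)
  hi <- max(f_obs, 1e-8)
  grid <- seq(0, hi, length.out = 201)
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  up <- grid[min(i + 1L, length(grid))]
  if (lo == up) return(lo)
  opt <- stats::optimize(obj, c(lo, up), tol = 1e-12 * (1 + hi))
  if (obj(0) <= opt$objective) 0 else opt$minimum
}

#' Jointly fit scale and dynamical error by alternation
#'
#' The observed amplitudes carry an arbitrary scale.  Starting from the
#' plain linear scale of [scale_amplitudes()], the scale `k` and the
#' error term `epsilon` are refined in alternation (`k` given `epsilon`
#' has the closed form `k = sum(Fo m) / sum(m^2)` with
#' `m = sqrt(Fc^2 + eps^2)`), to a relative tolerance of 1e-8, at most
#' 50 rounds.
#'
#' @param f_obs Raw observed amplitudes.
#' @param f_calc Calculated amplitudes.
#' @param rtol Relative convergence tolerance.
#' @param max_iter Maximum number of alternation rounds.
#' @return List with `epsilon` (on the calculated scale), `k`
#'   (amplitude scale observed/calculated) and `iterations`.
#' @export
fit_epsilon_scaled <- function(f_obs, f_calc, rtol = 1e-8, max_iter = 50) {
  f_obs <- abs(f_obs); f_calc <- abs(f_calc)
  k <- scale_amplitudes(f_obs, f_calc)$k
  e <- 0
  for (it in seq_len(max_iter)) {
    e_new <- fit_epsilon(f_obs / k, f_calc)
    m <- sqrt(f_calc^2 + e_new^2)
    k_new <- sum(f_obs * m) / sum(m^2)
    done <- abs(e_new - e) <= rtol * (1 + abs(e)) &&
      abs(k_new - k) <= rtol * (1 + abs(k))
    e <- e_new; k <- k_new
    if (done) break
  }
  list(epsilon = e, k = k, iterations = it)
}

#' Per-bin dynamical error terms
#'
#' Applies [fit_epsilon()] independently within each resolution bin.
#' Bins with fewer than `min_n` reflections fall back to the global fit
#' with a warning.
#'
#' @param f_obs,f_calc Paired amplitudes on a common scale, in the
#'   order used to compute `binning`.
#' @param binning A [assign_resolution_bins()] result on the same set.
#' @param min_n Minimum reflections per bin for an independent fit.
#' @return Data.frame with `mean_d`, `epsilon`, `d_max`, `d_min`, `n`.
#' @export
fit_epsilon_binned <- function(f_obs, f_calc, binning, min_n = 5) {
  f_obs <- abs(f_obs); f_calc <- abs(f_calc)
  stopifnot(inherits(binning, "resolution_binning"),
            length(f_obs) == length(f_calc),
            length(f_obs) == length(binning$assignment))
  eps_global <- NULL
  eps <- vapply(seq_len(binning$n_bins), function(b) {
    ii <- binning$index[[b]]
    if (length(ii) < min_n) {
      warning(sprintf("bin %d has %d < %d reflections; using global epsilon",
                      b, length(ii), min_n))
      if (is.null(eps_global))
        eps_global <<- fit_epsilon(f_obs, f_calc)
      return(eps_global)
    }
    fit_epsilon(f_obs[ii], f_calc[ii])
  }, 0)
  data.frame(mean_d = binning$mean_d, epsilon = eps,
             d_max = binning$d_max, d_min = binning$d_min,
             n = binning$size)
}

#' Fit a continuous resolution dependence of the dynamical error
#'
#' Fits the per-bin error terms as a function of the bin mean
#' d-spacing.  Supported forms: `"linear"` (`eps(d) = a d + b`),
#' `"exp2"` (two-term exponential
#' `eps(d) = a exp(b d) + c exp(e d)`, fitted by multi-start
#' Levenberg-Marquardt; on non-convergence falls back to `"discrete"`
#' with a warning), and `"discrete"` (step function through the bins).
#' Evaluation clamps negative values to zero and clamps `d` to the
#' fitted bin range (no extrapolation).
#'
#' @param bins Data.frame from [fit_epsilon_binned()].
#' @param form `"linear"`, `"exp2"` or `"discrete"`.
#' @param epsilon_global Optional global epsilon stored alongside.
#' @param k Amplitude scale (observed/calculated) the error terms refer
#'   to; recorded so intensity corrections can return to the observed
#'   scale.
#' @return Object of class `"dynamical_error_model"`.
#' @export
fit_continuous <- function(bins, form = c("linear", "exp2", "discrete"),
                           epsilon_global = NA_real_, k = 1) {
  form <- match.arg(form)
  stopifnot(is.data.frame(bins), nrow(bins) >= 1)
  params <- NULL
  if (form == "linear") {
    if (nrow(bins) < 2) stop("linear form needs at least 2 bins")
    co <- stats::coef(stats::lm(epsilon ~ mean_d, data = bins))
    params <- c(a = unname(co[2]), b = unname(co[1]))
  } else if (form == "exp2") {
    if (nrow(bins) < 4) stop("exp2 form needs at least 4 bins")
    fit <- .fit_exp2(bins$mean_d, bins$epsilon)
    if (is.null(fit)) {
      warning("exp2 fit did not converge; falling back to discrete form")
      form <- "discrete"
    } else params <- fit
  }
  structure(list(epsilon_global = epsilon_global, bins = bins,
                 form = form, params = params, k = k,
                 d_range = range(bins$mean_d)),
            class = "dynamical_error_model")
}

# multi-start Levenberg-Marquardt for eps(d) = a exp(b d) + c exp(e d)
.fit_exp2 <- function(d, eps) {
  model <- function(p, d) p[1] * exp(p[2] * d) + p[3] * exp(p[4] * d)
  best <- NULL
  span <- diff(range(d)); span <- if (span > 0) span else 1
  starts <- list()
  for (b0 in c(0.5, 1, 2) / span)
    for (e0 in c(-0.5, -1, -2) / span)
      starts[[length(starts) + 1L]] <-
        c(max(eps) / exp(b0 * max(d)), b0, -min(eps) - 1e-3, e0)
  # also a near-linear start: a exp(small d) + c exp(small d)
  starts[[length(starts) + 1L]] <- c(mean(eps), 1e-3, -1e-3, -1)
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) model(p, d) - eps,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(p = fit$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  # require a sensible fit: better than the flat model
  rss_flat <- sum((eps - mean(eps))^2)
  if (!is.finite(best$rss) || best$rss > rss_flat * (1 + 1e-9)) return(NULL)
  c(a = best$p[1], b = best$p[2], c = best$p[3], e = best$p[4])
}

#' Fit the full dynamical error model for a dataset
#'
#' One-call wrapper: scales observed to calculated amplitudes
#' (alternating scale/epsilon fit), fits the global error term, the
#' per-bin terms, and the chosen continuous form.  Intensities are
#' converted to amplitudes by `F = sqrt(max(I, 0))` for fitting only.
#'
#' @param rs A [reflection_set()] with d-spacings.
#' @param f_calc Calculated amplitudes (or complex structure factors),
#'   aligned with `rs`.
#' @param n_bins Number of resolution bins (default 10).
#' @param form Continuous form, see [fit_continuous()].
#' @return A `"dynamical_error_model"`.
#' @export
fit_dynamical_error <- function(rs, f_calc, n_bins = 10,
                                form = c("linear", "exp2", "discrete")) {
  form <- match.arg(form)
  f_calc <- abs(f_calc)
  f_obs <- sqrt(pmax(rs$intensity, 0))
  glob <- fit_epsilon_scaled(f_obs, f_calc)
  binning <- assign_resolution_bins(rs, n_bins = n_bins)
  bins <- fit_epsilon_binned(f_obs / glob$k, f_calc, binning)
  fit_continuous(bins, form = form, epsilon_global = glob$epsilon,
                 k = glob$k)
}

#' @export
print.dynamical_error_model <- function(x, ...) {
  cat(sprintf("Dynamical error model (%s form): global epsilon %.4g, scale k %.4g\n",
              x$form, x$epsilon_global, x$k))
  if (!is.null(x$params)) {
    cat("  parameters:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                               collapse = ", "), "\n")
  }
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate the resolution-dependent dynamical error
#'
#' @param model A `"dynamical_error_model"`.
#' @param d d-spacings in Angstrom (vectorized).
#' @param warn_outside Warn when `d` falls outside every bin (discrete
#'   form); the nearest bin's value is used.
#' @return Non-negative epsilon values on the calculated-amplitude
#'   scale.
#' @export
epsilon_of_d <- function(model, d, warn_outside = FALSE) {
  stopifnot(inherits(model, "dynamical_error_model"))
  if (model$form == "discrete") {
    bins <- model$bins
    out <- numeric(length(d))
    outside <- rep(FALSE, length(d))
    for (i in seq_along(d)) {
      hit <- which(d[i] <= bins$d_max + 1e-12 & d[i] >= bins$d_min - 1e-12)
      if (length(hit) >= 1) out[i] <- bins$epsilon[hit[1]]
      else {
        outside[i] <- TRUE
        out[i] <- bins$epsilon[which.min(abs(bins$mean_d - d[i]))]
      }
    }
    if (warn_outside && any(outside))
      warning(sprintf("%d reflection(s) outside all bins; nearest bin used",
                      sum(outside)))
    return(pmax(out, 0))
  }
  # continuous forms: clamp d to the fitted abscissa range
  dc <- pmin(pmax(d, model$d_range[1]), model$d_range[2])
  e <- switch(model$form,
    linear = model$params[["a"]] * dc + model$params[["b"]],
    exp2 = model$params[["a"]] * exp(model$params[["b"]] * dc) +
      model$params[["c"]] * exp(model$params[["e"]] * dc))
  pmax(e, 0)
}

#' Dynamical intensity inflation factor
#'
#' The expected observed intensity of a reflection with kinematic
#' intensity `I_kin` is inflated by
#' `k_dyn = (I_kin + eps(d)^2) / I_kin`, the reciprocal of a
#' generalized Wiener filter `S/(S + N)`.
#'
#' @param i_kin Kinematic intensities; must be positive.
#' @param d d-spacings (Angstrom).
#' @param model A `"dynamical_error_model"`; alternatively a single
#'   numeric epsilon.
#' @return Factors >= 1.
#' @export
k_dyn <- function(i_kin, d, model) {
  if (any(i_kin <= 0))
    stop("k_dyn requires positive kinematic intensities; floor them first")
  eps <- if (is.numeric(model)) rep(model, length(i_kin))
         else epsilon_of_d(model, d)
  (i_kin + eps^2) / i_kin
}

#' Correct intensities for dynamical scattering
#'
#' Applies the Wiener-style down-weighting to every reflection:
#' intensity and sigma are both multiplied by `1 / k_dyn`, evaluated
#' with the plug-in kinematic estimate `I~ = max(I_obs, sigma)` (the
#' floor keeps the factor defined for zero or negative weak
#' measurements, which are retained and down-weighted most strongly):
#' \deqn{I_{corr} = I_{obs} \; \tilde I / (\tilde I + \epsilon(d)^2).}
#' Because sigma is scaled by the same factor, `I/sigma` is exactly
#' preserved.  The model's epsilon values live on the calculated
#' amplitude scale; they are moved to the observed intensity scale with
#' the stored amplitude scale `k` before use.
#'
#' @param rs A [reflection_set()] with d-spacings.
#' @param model A `"dynamical_error_model"` (or a single numeric
#'   epsilon, taken to be on the observed scale).
#' @param f_calc Optional calculated amplitudes; if given, the report
#'   includes pre/post epsilon and R1.
#' @return List with `reflections` (corrected set, writable as HKLF4)
#'   and `report` (class `"correction_report"`).
#' @export
correct_intensities <- function(rs, model, f_calc = NULL) {
  if (is.numeric(model)) {
    eps_obs <- rep(model, nrow(rs))
  } else {
    eps_obs <- model$k * epsilon_of_d(model, rs$d)
  }
  itil <- pmax(rs$intensity, rs$sigma)
  factor <- ifelse(itil <= 0 & eps_obs == 0, 1,
                   itil / (itil + eps_obs^2))
  out <- rs
  out$intensity <- rs$intensity * factor
  out$sigma <- rs$sigma * factor
  report <- list(factor = factor, epsilon_d = eps_obs, n = nrow(rs))
  if (!is.null(f_calc)) {
    f_calc <- abs(f_calc)
    pre <- fit_epsilon_scaled(sqrt(pmax(rs$intensity, 0)), f_calc)
    post <- fit_epsilon_scaled(sqrt(pmax(out$intensity, 0)), f_calc)
    report$epsilon_pre <- pre$epsilon
    report$epsilon_post <- post$epsilon
    report$r1_pre <- r1(sqrt(pmax(rs$intensity, 0)) / pre$k, f_calc)
    report$r1_post <- r1(sqrt(pmax(out$intensity, 0)) / post$k, f_calc)
  }
  class(report) <- "correction_report"
  list(reflections = out, report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("Dynamical correction: %d reflections, factors in [%.4g, %.4g]\n",
              x$n, min(x$factor), max(x$factor)))
  if (!is.null(x$epsilon_pre))
    cat(sprintf("  epsilon %.4g -> %.4g   R1 %.4g -> %.4g\n",
                x$epsilon_pre, x$epsilon_post, x$r1_pre, x$r1_post))
  invisible(x)
}

#' Correct structure-factor amplitudes per resolution bin
#'
#' Protein data are refined against amplitudes; here the correction is
#' applied discretely per resolution bin (no continuous fit).  Each
#' amplitude and its sigma are multiplied by the amplitude-domain
#' factor `F~ / sqrt(F~^2 + eps_bin^2)` with the plug-in estimate
#' `F~ = max(F_obs, sigma_F)` - the square root of the intensity-domain
#' `1/k_dyn`, so intensities formed from the corrected amplitudes match
#' [correct_intensities()].
#'
#' @param f_obs Observed amplitudes.
#' @param sigma Their standard uncertainties.
#' @param binning [assign_resolution_bins()] result for these
#'   reflections.
#' @param eps_bins Per-bin epsilon values (length `binning$n_bins`), on
#'   the observed amplitude scale; typically
#'   `model$k * model$bins$epsilon`.
#' @return List with `f` (corrected amplitudes), `sigma` and `factor`.
#' @export
correct_amplitudes <- function(f_obs, sigma, binning, eps_bins) {
  stopifnot(inherits(binning, "resolution_binning"),
            length(eps_bins) == binning$n_bins,
            length(f_obs) == length(binning$assignment),
            length(sigma) == length(f_obs))
  eps <- eps_bins[binning$assignment]
  ftil <- pmax(f_obs, sigma)
  factor <- ifelse(ftil <= 0 & eps == 0, 1,
                   ftil / sqrt(ftil^2 + eps^2))
  list(f = f_obs * factor, sigma = sigma * factor, factor = factor)
}
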