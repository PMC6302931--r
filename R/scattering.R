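#' Load a five-Gaussian electron form-factor table
#'
#' Electron atomic scattering factors are parameterized as a sum of
#' five Gaussians, `f(s) = sum_i a_i exp(-b_i s^2)` with
#' `s = sin(theta)/lambda` in 1/Angstrom.  The built-in table carries
#' the standard published coefficients for H, C, N, O and S, which
#' cover common small organic molecules; user tables for other elements
#' can be supplied as CSV with columns `element, a1..a5, b1..b5`.
#'
#' @param path CSV path; `NULL` loads the built-in table.
#' @return Named list of `"gauss5"` coefficient objects, one per
#'   element.
#' @export
load_scattering_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "electron_sf_gauss5.csv",
                        package = "dynred", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", paste0("a", 1:5), paste0("b", 1:5))
  if (!all(need %in% names(tab)))
    stop("coefficient table must have columns element, a1..a5, b1..b5")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- structure(list(element = tab$element[i],
                        a = as.numeric(tab[i, paste0("a", 1:5)]),
                        b = as.numeric(tab[i, paste0("b", 1:5)])),
                   class = "gauss5")
    if (any(g$b < 0)) stop("Gaussian widths b_i must be non-negative")
    if (sum(g$a) <= 0) stop("f(0) = sum(a_i) must be positive")
    g
  })
  names(out) <- tab$element
  out
}

#' Evaluate an atomic form factor
#'
#' @param coeffs A `"gauss5"` (5-Gaussian) or `"cm9"`
#'   (4-Gaussian-plus-constant Cromer-Mann) coefficient object.
#' @param s Scattering vector `sin(theta)/lambda` in 1/Angstrom;
#'   must be >= 0 (vectorized).
#' @return Form-factor values f(s) in Angstrom.
#' @export
evaluate_form_factor <- function(coeffs, s) {
  if (any(s < 0)) stop("s = sin(theta)/lambda must be non-negative")
  s2 <- s * s
  f <- numeric(length(s))
  for (i in seq_along(coeffs$a)) f <- f + coeffs$a[i] * exp(-coeffs$b[i] * s2)
  if (!is.null(coeffs$c)) f <- f + coeffs$c
  f
}

#' Refit a five-Gaussian form factor to the nine Cromer-Mann
#' coefficients
#'
#' Small-molecule refinement programs expect form factors in the
#' Cromer-Mann parameterization (four Gaussians plus a constant, nine
#' coefficients).  This performs an unweighted least-squares refit of
#' that form to a five-Gaussian source curve on a grid of `s` values.
#' Initialization takes the four largest-amplitude source Gaussians as
#' starting `(a_i, b_i)` and the fifth amplitude as the constant; the
#' Gaussian widths are bounded below by zero.  The Levenberg-Marquardt
#' fit never increases the sum of squares relative to this start.
#'
#' @param g5 A `"gauss5"` coefficient object.
#' @param s_grid Fit grid in 1/Angstrom (default 0 to 2, step 0.01,
#'   the working resolution range of atomic-resolution data).
#' @return An object of class `"cm9"`: list with `element`, `a` (4),
#'   `b` (4), `c`, `max_abs_residual`, `rss`.
#' @export
fit_cromer_mann9 <- function(g5, s_grid = seq(0, 2, by = 0.01)) {
  stopifnot(inherits(g5, "gauss5"))
  target <- evaluate_form_factor(g5, s_grid)
  ord <- order(g5$a, decreasing = TRUE)
  par0 <- c(g5$a[ord[1:4]], g5$b[ord[1:4]], g5$a[ord[5]])
  model <- function(p, s) {
    s2 <- s * s
    p[1] * exp(-p[5] * s2) + p[2] * exp(-p[6] * s2) +
      p[3] * exp(-p[7] * s2) + p[4] * exp(-p[8] * s2) + p[9]
  }
  resid <- function(p) model(p, s_grid) - target
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid,
    lower = c(rep(-Inf, 4), rep(0, 4), -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  rss0 <- sum(resid(par0)^2)
  rss <- sum(fit$fvec^2)
  if (rss > rss0 + 1e-12)
    stop(sprintf("refit failed to improve on initialization (rss %.3g)", rss))
  p <- fit$par
  structure(list(element = g5$element,
                 a = p[1:4], b = p[5:8], c = p[9],
                 max_abs_residual = max(abs(fit$fvec)),
                 rss = rss, s_range = range(s_grid)),
            class = "cm9")
}

#' @export
print.cm9 <- function(x, ...) {
  cat(sprintf("Cromer-Mann 9-coefficient fit for %s (max |resid| %.2e)\n",
              x$element, x$max_abs_residual))
  cat(sfac_line(x), "\n")
  invisible(x)
}

#' Format a fitted form factor as a SHELX SFAC line
#'
#' Emits the coefficients in SFAC instruction order:
#' `SFAC elem a1 b1 a2 b2 a3 b3 a4 b4 c f' f'' mu r wt`.  Dispersion
#' terms are zero for the kinematic electron case; covalent radius and
#' atomic weight default to zero placeholders unless given.
#'
#' @param cm9 A `"cm9"` object.
#' @param radius,weight Optional covalent radius (Angstrom) and atomic
#'   weight for the trailing SFAC fields.
#' @return A single SFAC-formatted string.
#' @export
sfac_line <- function(cm9, radius = 0, weight = 0) {
  stopifnot(inherits(cm9, "cm9"))
  sprintf("SFAC %-4s%9.4f%9.4f%9.4f%9.4f%9.4f%9.4f%9.4f%9.4f%9.4f  0.0000  0.0000%9.4f%9.4f%9.3f",
          cm9$element,
          cm9$a[1], cm9$b[1], cm9$a[2], cm9$b[2],
          cm9$a[3], cm9$b[3], cm9$a[4], cm9$b[4], cm9$c,
          0, radius, weight)
}
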