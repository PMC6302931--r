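#' Kinematic structure factors of a crystal model
#'
#' Computes the complex kinematic structure factor for each reflection,
#' \deqn{F(h) = \sum_{sym} \sum_{atoms} occ \; f_{elem}(s) \; T(h)
#'   \; e^{2\pi i \, h \cdot (Rx + t)},}
#' with `s = sin(theta)/lambda = 1/(2d)`, the isotropic Debye-Waller
#' factor `T = exp(-8 pi^2 U_iso s^2)` and the anisotropic form
#' `T = exp(-2 pi^2 sum_ij U_ij h_i h_j a*_i a*_j)`.  Symmetry is
#' handled by index transformation: the copy at `Rx + t` contributes
#' with transformed index `h' = h R` and translation phase
#' `exp(2 pi i h.t)`, so anisotropic ADPs are evaluated at `h'`.
#'
#' @param model A [crystal_model()].
#' @param hkl Integer matrix or data.frame with columns h, k, l.
#' @param table Scattering coefficients: named list from
#'   [load_scattering_table()] (5-Gaussian) or of fitted `"cm9"`
#'   objects; default the built-in electron table.
#' @return Complex vector of structure factors, one per reflection.
#' @export
calc_structure_factors <- function(model, hkl,
                                   table = load_scattering_table()) {
  stopifnot(inherits(model, "crystal_model"))
  hkl <- as.matrix(as.data.frame(hkl)[, 1:3])
  storage.mode(hkl) <- "double"
  n <- nrow(hkl)
  d <- d_spacing(hkl[, 1], hkl[, 2], hkl[, 3], model$cell)
  s <- 1 / (2 * d)
  s2 <- s * s

  atoms <- model$atoms
  missing_el <- setdiff(unique(atoms$element), names(table))
  if (length(missing_el) > 0)
    stop(sprintf("no scattering coefficients for element(s): %s",
                 paste(missing_el, collapse = ", ")))
  fel <- lapply(unique(atoms$element),
                function(e) evaluate_form_factor(table[[e]], s))
  names(fel) <- unique(atoms$element)

  astar <- cell_reciprocal_lengths(model$cell)
  aniso <- is.finite(atoms$u11)
  X <- t(as.matrix(atoms[, c("x", "y", "z")]))   # 3 x n_atoms

  F <- complex(real = numeric(n), imaginary = numeric(n))
  for (op in model$symmetry) {
    hp <- hkl %*% op$R                                   # n x 3, h' = h R
    ph_t <- 2 * pi * as.vector(hkl %*% op$t)             # translation phase
    hs <- sweep(hp, 2, astar, `*`)                       # h'_i a*_i
    for (j in seq_len(nrow(atoms))) {
      T <- if (aniso[j]) {
        exp(-2 * pi^2 * (
          atoms$u11[j] * hs[, 1]^2 + atoms$u22[j] * hs[, 2]^2 +
          atoms$u33[j] * hs[, 3]^2 +
          2 * atoms$u12[j] * hs[, 1] * hs[, 2] +
          2 * atoms$u13[j] * hs[, 1] * hs[, 3] +
          2 * atoms$u23[j] * hs[, 2] * hs[, 3]))
      } else {
        exp(-8 * pi^2 * atoms$u_iso[j] * s2)
      }
      phase <- 2 * pi * as.vector(hp %*% X[, j]) + ph_t
      F <- F + atoms$occ[j] * fel[[atoms$element[j]]] * T *
        complex(real = cos(phase), imaginary = sin(phase))
    }
  }
  unname(F)
}

#' Scale observed to calculated amplitudes
#'
#' Linear least squares through the origin:
#' `k = sum(|Fo||Fc|) / sum(|Fc|^2)`; dividing the observed amplitudes
#' by `k` puts them on the calculated scale.
#'
#' @param f_obs,f_calc Paired amplitude vectors.
#' @return List with `k` and `scaled` (`f_obs / k`).
#' @export
scale_amplitudes <- function(f_obs, f_calc) {
  f_obs <- abs(f_obs); f_calc <- abs(f_calc)
  stopifnot(length(f_obs) == length(f_calc))
  den <- sum(f_calc^2)
  if (den == 0) stop("all calculated amplitudes are zero; no scale defined")
  k <- sum(f_obs * f_calc) / den
  list(k = k, scaled = f_obs / k)
}

#' Crystallographic R1 residual
#'
#' `R1 = sum ||Fo| - |Fc|| / sum |Fo|` over paired amplitudes on a
#' common scale.
#'
#' @param f_obs,f_calc Paired amplitude vectors.
#' @return R1 as a fraction.
#' @export
r1 <- function(f_obs, f_calc) {
  f_obs <- abs(f_obs); f_calc <- abs(f_calc)
  stopifnot(length(f_obs) == length(f_calc))
  den <- sum(f_obs)
  if (den == 0) stop("R1 undefined: sum of observed amplitudes is zero")
  sum(abs(f_obs - f_calc)) / den
}
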