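#' Construct a unit cell
#'
#' Builds a triclinic unit cell from its six lattice parameters and
#' derives the cell volume via the standard closed form
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param a,b,c Axis lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'   Default 90 (orthorhombic/orthogonal).
#' @return An object of class `"unit_cell"`: a list with elements
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma` and the derived `volume`
#'   (Angstrom^3).
#' @examples
#' cell <- unit_cell(8.090, 9.940, 17.700)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("cell axis lengths must be positive and finite")
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell")
  v <- cell_volume(cell)
  if (!is.finite(v) || v <= 0)
    stop("degenerate unit cell: volume is not positive")
  cell$volume <- v
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Unit-cell volume
#'
#' @param cell A [unit_cell()] object.
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell$a * cell$b * cell$c * sqrt(max(arg, 0))
}

#' Real-space metric tensor of a unit cell
#'
#' @param cell A [unit_cell()] object.
#' @return A 3x3 matrix `G` with `G[i,j] = a_i . a_j` (Angstrom^2).
#' @export
cell_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  a <- cell$a; b <- cell$b; cc <- cell$c
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3, byrow = TRUE)
}

#' Reciprocal metric tensor
#'
#' Inverse of the real-space metric; `1/d^2 = h' G* h` for Miller index
#' column vector `h`.
#'
#' @param cell A [unit_cell()] object.
#' @return A 3x3 matrix (Angstrom^-2).
#' @export
cell_reciprocal_metric <- function(cell) {
  solve(cell_metric(cell))
}

#' Reciprocal axis lengths
#'
#' Moduli of the reciprocal basis vectors, used in the anisotropic
#' Debye-Waller factor.
#'
#' @param cell A [unit_cell()] object.
#' @return Numeric vector `c(a*, b*, c*)` in Angstrom^-1.
#' @export
cell_reciprocal_lengths <- function(cell) {
  sqrt(diag(cell_reciprocal_metric(cell)))
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard PDB convention: `a` along x, `b` in the xy plane.
#'
#' @param cell A [unit_cell()] object.
#' @return A 3x3 matrix `M` such that Cartesian coordinates are
#'   `M %*% x_frac` (Angstrom).
#' @export
cell_orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg), 3, 3, byrow = TRUE)
}

#' Resolution (d-spacing) of reflections
#'
#' Interplanar spacing of reflection (h,k,l) from the general triclinic
#' reciprocal metric tensor; for an orthorhombic cell this reduces to
#' `1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2`.
#'
#' @param h,k,l Integer Miller indices (vectorized).
#' @param cell A [unit_cell()] object.
#' @return d-spacings in Angstrom.
#' @examples
#' d_spacing(1, 0, 0, unit_cell(8.090, 9.940, 17.700))  # == a
#' @export
d_spacing <- function(h, k, l, cell) {
  if (length(h) != length(k) || length(k) != length(l))
    stop("h, k, l must have equal length")
  if (any(h == 0 & k == 0 & l == 0))
    stop("d-spacing undefined for (0,0,0)")
  g <- cell_reciprocal_metric(cell)
  inv_d2 <- h * h * g[1, 1] + k * k * g[2, 2] + l * l * g[3, 3] +
    2 * h * k * g[1, 2] + 2 * h * l * g[1, 3] + 2 * k * l * g[2, 3]
  1 / sqrt(inv_d2)
}
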