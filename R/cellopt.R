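#' Parse SHELX-style distance restraints
#'
#' Reads DFIX (1-2 bond distance) and DANG (1-3 angle distance)
#' instruction lines.  Each line carries a target distance, a sigma,
#' and atom labels consumed pairwise in order; an odd atom count is an
#' error.  Unknown instructions are skipped with a warning.  A missing
#' sigma defaults to the SHELX conventions (0.02 for DFIX, 0.04 for
#' DANG).
#'
#' @param lines Character vector of instruction lines, or a file via
#'   `file`.
#' @param file Optional path.
#' @return Data.frame of class `"restraint_set"` with columns `kind`,
#'   `target`, `sigma`, `atom1`, `atom2`.
#' @export
parse_restraints <- function(lines = NULL, file = NULL) {
  if (!is.null(file)) lines <- readLines(file, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "!") || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    kind <- toupper(toks[1])
    if (!kind %in% c("DFIX", "DANG")) {
      warning(sprintf("line %d: unknown instruction '%s' skipped", ln, toks[1]))
      next
    }
    nums <- suppressWarnings(as.numeric(toks[-1]))
    n_num <- which(is.na(nums))[1] - 1L
    if (is.na(n_num)) n_num <- length(nums)
    if (n_num < 1) stop(sprintf("line %d: %s needs a target distance", ln, kind))
    target <- nums[1]
    sigma <- if (n_num >= 2) nums[2] else if (kind == "DFIX") 0.02 else 0.04
    atoms <- toks[-(1:(1 + n_num))]
    if (length(atoms) == 0 || length(atoms) %% 2 != 0)
      stop(sprintf("line %d: %s has an unpaired atom list", ln, kind))
    if (target <= 0 || sigma <= 0)
      stop(sprintf("line %d: target and sigma must be positive", ln))
    for (p in seq(1, length(atoms), by = 2)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = kind, target = target, sigma = sigma,
        atom1 = atoms[p], atom2 = atoms[p + 1],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(kind = character(0), target = numeric(0),
               sigma = numeric(0), atom1 = character(0),
               atom2 = character(0))
  class(res) <- c("restraint_set", "data.frame")
  res
}

# distance between atom i and the nearest symmetry/lattice image of atom j
.model_distance <- function(cell, ops, xi, xj) {
  M <- cell_orth_matrix(cell)
  best <- Inf
  for (op in ops) {
    y <- (op$R %*% xj + op$t)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      df <- as.numeric(xi) - (as.numeric(y) + c(dx, dy, dz))
      best <- min(best, sqrt(sum((M %*% df)^2)))
    }
  }
  best
}

#' Model distances for a restraint set
#'
#' Interatomic distances implied by the current cell and fixed
#' fractional coordinates, each taken to the nearest symmetry/lattice
#' image of the second atom (bonded pairs may straddle cell
#' boundaries).
#'
#' @param model A [crystal_model()].
#' @param restraints A [parse_restraints()] result.
#' @param cell Optional replacement cell (default the model's).
#' @return Numeric vector of distances (Angstrom).
#' @export
restraint_distances <- function(model, restraints, cell = model$cell) {
  i1 <- match(restraints$atom1, model$atoms$label)
  i2 <- match(restraints$atom2, model$atoms$label)
  bad <- c(restraints$atom1[is.na(i1)], restraints$atom2[is.na(i2)])
  if (length(bad) > 0)
    stop(sprintf("restraint atom label(s) not in model: %s",
                 paste(unique(bad), collapse = ", ")))
  X <- as.matrix(model$atoms[, c("x", "y", "z")])
  vapply(seq_len(nrow(restraints)), function(r)
    .model_distance(cell, model$symmetry, X[i1[r], ], X[i2[r], ]), 0)
}

#' Refine unit-cell parameters against distance restraints
#'
#' The electron wavelength couples cell dimensions and detector
#' distance, so the lattice is instead refined against idealized
#' interatomic distances: with fractional coordinates held fixed, this
#' minimizes the weighted residual
#' `sum ((d_model(cell) - target) / sigma)^2` over the free cell
#' parameters (orthorhombic default: a, b, c free, angles fixed at 90
#' degrees).  A derivative-free Nelder-Mead simplex with restarts is
#' used, converging at 1e-10 relative residual change.
#'
#' @param model A [crystal_model()]; its cell is the starting point.
#' @param restraints A [parse_restraints()] result (non-empty).
#' @param free Character vector naming the free parameters among
#'   `c("a", "b", "c", "alpha", "beta", "gamma")`.
#' @return List with `cell` (refined [unit_cell()]), `initial_residual`,
#'   `final_residual`, and `table` of per-restraint deviations at the
#'   refined cell.
#' @export
refine_cell <- function(model, restraints, free = c("a", "b", "c")) {
  if (nrow(restraints) == 0) stop("restraint set is empty")
  free <- match.arg(free, c("a", "b", "c", "alpha", "beta", "gamma"),
                    several.ok = TRUE)
  if (nrow(restraints) < length(free))
    stop("under-determined: fewer restraints than free cell parameters")
  start <- unlist(model$cell[c("a", "b", "c", "alpha", "beta", "gamma")])
  make_cell <- function(par) {
    p <- start; p[free] <- par
    p <- unname(p)
    unit_cell(p[1], p[2], p[3], p[4], p[5], p[6])
  }
  objective <- function(par) {
    if (any(par[free %in% c("a", "b", "c")] <= 0)) return(1e30)
    cl <- tryCatch(make_cell(par), error = function(e) NULL)
    if (is.null(cl)) return(1e30)
    dm <- restraint_distances(model, restraints, cell = cl)
    sum(((dm - restraints$target) / restraints$sigma)^2)
  }
  par <- start[free]
  res0 <- objective(par)
  best <- list(par = par, value = res0)
  if (length(free) == 1) {
    opt <- stats::optimize(function(v) objective(stats::setNames(v, free)),
                           interval = c(0.5, 2) * par, tol = 1e-12)
    best <- list(par = stats::setNames(opt$minimum, free),
                 value = opt$objective)
  } else {
    for (round in 1:20) {
      opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-15))
      improved <- best$value - opt$value
      if (opt$value <= best$value) best <- list(par = opt$par, value = opt$value)
      if (round > 1 && improved <= 1e-12 * (1 + best$value)) break
    }
  }
  if (best$value > res0 + 1e-12)
    best <- list(par = par, value = res0)   # never worse than the start
  cell <- make_cell(best$par)
  dm <- restraint_distances(model, restraints, cell = cell)
  list(cell = cell,
       initial_residual = res0,
       final_residual = best$value,
       table = data.frame(restraints,
                          model_distance = dm,
                          deviation = dm - restraints$target))
}

#' Side of the solvent cube per missing molecule
#'
#' When a cell shrinks by `delta_volume` upon losing `z` solvent
#' molecules (one per asymmetric unit, `z` the symmetry multiplicity),
#' each missing molecule accounts for a cube of side
#' `(delta_volume / z)^(1/3)`.
#'
#' @param delta_volume Cell-volume shrinkage in Angstrom^3 (> 0).
#' @param z Number of missing molecules per cell (integer >= 1).
#' @return Cube side in Angstrom.
#' @examples
#' solvent_cube_side(90, 4)   # orthorhombic P2(1)2(1)2(1), Z = 4
#' @export
solvent_cube_side <- function(delta_volume, z) {
  if (delta_volume <= 0) stop("delta_volume must be positive")
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  (delta_volume / z)^(1 / 3)
}
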