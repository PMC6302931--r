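#' Generate a random toy crystal structure
#'
#' Places atoms uniformly in the cell with a minimum-distance rejection
#' rule of 1.0 Angstrom against all previously placed atoms and all
#' their symmetry/lattice images (and each atom's own images, which
#' also keeps atoms off special positions).  Isotropic ADPs are drawn
#' uniformly from 0.01 to 0.05 Angstrom^2.  Deterministic given the
#' seed.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param cell A [unit_cell()].
#' @param elements Element pool sampled uniformly per atom.
#' @param symmetry Operator list (see [parse_symop_xyz()]) or a
#'   space-group name known to the package ("P1", "P212121", "P21212").
#' @param seed Integer seed (mandatory; the global RNG state is left
#'   untouched).
#' @param min_dist Minimum interatomic distance (Angstrom).
#' @return A [crystal_model()].
#' @export
random_toy_structure <- function(n_atoms, cell, elements = c("C", "O"),
                                 symmetry = "P212121", seed,
                                 min_dist = 1.0) {
  stopifnot(n_atoms >= 1)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  ops <- if (is.character(symmetry)) {
    o <- .builtin_symops(symmetry)
    if (is.null(o)) stop(sprintf("unknown space group '%s'", symmetry))
    o
  } else symmetry
  sg_name <- if (is.character(symmetry)) symmetry else "custom"
  M <- cell_orth_matrix(cell)

  # all symmetry images of fractional point x within +-1 cell translations
  images <- function(x) {
    out <- matrix(0, nrow = 0, ncol = 3)
    for (op in ops) {
      y <- (op$R %*% x + op$t) %% 1
      out <- rbind(out, t(y))
    }
    out
  }
  min_sep <- function(x, others) {
    # minimum Cartesian distance from x to any point in `others`,
    # over the 27 neighbouring lattice translations
    if (nrow(others) == 0) return(Inf)
    best <- Inf
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      df <- sweep(others, 2, as.numeric(x), `-`) +
        matrix(rep(c(dx, dy, dz), each = nrow(others)), ncol = 3)
      cart <- df %*% t(M)
      best <- min(best, sqrt(min(rowSums(cart^2))))
    }
    best
  }

  withr::with_seed(seed, {
    placed <- matrix(0, nrow = 0, ncol = 3)  # symmetry-expanded positions
    pos <- matrix(0, nrow = 0, ncol = 3)
    rejections <- 0L
    while (nrow(pos) < n_atoms) {
      x <- stats::runif(3)
      img <- images(x)
      self_ok <- if (length(ops) > 1) {
        # distance of x to its own non-identity images
        min_sep(x, img[-1, , drop = FALSE]) >= min_dist
      } else TRUE
      if (self_ok && min_sep(x, placed) >= min_dist) {
        pos <- rbind(pos, x)
        placed <- rbind(placed, img)
      } else {
        rejections <- rejections + 1L
        if (rejections > 1e4)
          stop("could not place atoms after 10000 rejections; cell too crowded")
      }
    }
    atoms <- data.frame(
      label = paste0("X", seq_len(n_atoms)),
      element = sample(elements, n_atoms, replace = TRUE),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occ = 1,
      u_iso = stats::runif(n_atoms, 0.01, 0.05),
      u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
      u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
      stringsAsFactors = FALSE)
    crystal_model(cell, atoms, ops, space_group = sg_name)
  })
}

#' Simulate observed reflection data with a dynamical perturbation
#'
#' Generates every unique reflection to the resolution limit, computes
#' the kinematic structure factor, adds a complex-valued dynamical
#' component that is uncorrelated with it - independent Gaussian real
#' and imaginary parts of standard deviation `eps(d)/sqrt(2)`, so that
#' `E|F_dyn|^2 = eps(d)^2` - and forms
#' `I_obs = |F_kin + F_dyn|^2` before applying counting noise.  On
#' average this overestimates the weak intensities and leaves the
#' strong ones nearly untouched, the signature of dynamical scattering.
#'
#' @param model A [crystal_model()].
#' @param d_min High-resolution limit (Angstrom).
#' @param epsilon Dynamical error profile: a single number (constant),
#'   a function of d, or a `"dynamical_error_model"`.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_param Gaussian standard deviation, or Poisson counts
#'   scale (counts per intensity unit).
#' @param seed Integer seed (mandatory for any stochastic path).
#' @param scale Overall amplitude scale applied to the kinematic
#'   structure factors before the dynamical component is added.  Real
#'   integrated data carry an arbitrary scale from the detector and
#'   scaling pipeline; `epsilon` is expressed on the scaled (observed)
#'   amplitude scale, exactly as a fitted error term would be.
#' @param n_crystals Number of crystal wedges; if > 1 the output is an
#'   unmerged set in which each crystal re-draws its dynamical
#'   component and noise and carries an independent log-normal scale
#'   (sdlog 0.1), to exercise merging statistics.
#' @param laue Laue group used to enumerate unique reflections.
#' @param table Scattering-factor table.
#' @return List with `reflections` (a [reflection_set()]) and `truth`
#'   (data.frame `h, k, l, d, f_kin, epsilon` of the noise-free ground
#'   truth).
#' @export
simulate_observed <- function(model, d_min, epsilon = 0,
                              noise = c("none", "gaussian", "poisson"),
                              noise_param = 1, seed = NULL, scale = 1,
                              n_crystals = 1, laue = "mmm",
                              table = load_scattering_table()) {
  noise <- match.arg(noise)
  stopifnot(scale > 0)
  stochastic <- !(is.numeric(epsilon) && length(epsilon) == 1 &&
                    epsilon == 0) || noise != "none" || n_crystals > 1
  if (stochastic && is.null(seed))
    stop("a seed is required for stochastic simulation")
  hkl <- enumerate_unique_hkl(model$cell, d_min, laue = laue)
  f_kin <- scale * calc_structure_factors(model, hkl, table = table)
  eps_d <- if (is.function(epsilon)) epsilon(hkl$d)
    else if (inherits(epsilon, "dynamical_error_model"))
      epsilon_of_d(epsilon, hkl$d)
    else rep(epsilon, nrow(hkl))
  if (any(eps_d < 0)) stop("epsilon profile must be non-negative")

  n <- nrow(hkl)
  draw_crystal <- function() {
    f_dyn <- complex(real = stats::rnorm(n, 0, eps_d / sqrt(2)),
                     imaginary = stats::rnorm(n, 0, eps_d / sqrt(2)))
    i_obs <- Mod(f_kin + f_dyn)^2
    if (noise == "gaussian") {
      i_obs <- i_obs + stats::rnorm(n, 0, noise_param)
      sig <- rep(noise_param, n)
    } else if (noise == "poisson") {
      counts <- stats::rpois(n, i_obs * noise_param)
      i_obs <- counts / noise_param
      sig <- sqrt(pmax(counts, 1)) / noise_param
    } else {
      sig <- rep(0, n)
    }
    list(i = i_obs, sig = sig)
  }

  gen <- function() {
    if (n_crystals == 1) {
      dc <- draw_crystal()
      rs <- reflection_set(hkl$h, hkl$k, hkl$l, dc$i, dc$sig,
                           cell = model$cell, merged = TRUE)
    } else {
      obs <- lapply(seq_len(n_crystals), function(cid) {
        sc <- stats::rlnorm(1, 0, 0.1)
        dc <- draw_crystal()
        data.frame(h = hkl$h, k = hkl$k, l = hkl$l,
                   i = dc$i * sc, sig = pmax(dc$sig * sc, 1e-12),
                   crystal = cid)
      })
      obs <- do.call(rbind, obs)
      rs <- reflection_set(obs$h, obs$k, obs$l, obs$i, obs$sig,
                           cell = model$cell, merged = FALSE,
                           crystal = obs$crystal)
    }
    rs
  }
  rs <- if (stochastic) withr::with_seed(seed, gen()) else gen()
  list(reflections = rs,
       truth = data.frame(h = hkl$h, k = hkl$k, l = hkl$l, d = hkl$d,
                          f_kin = Mod(f_kin), epsilon = eps_d))
}
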