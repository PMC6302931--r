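# Shared fixtures and independent oracles.  Oracles are written from
# first principles (explicit lattice vectors, plain loops) so they do
# not share code paths with the package functions they check.

# direct and reciprocal lattice vectors of a triclinic cell, built from
# the textbook orthogonalization and cross products only
lattice_vectors <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  av <- c(a, 0, 0)
  bv <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  cv <- c(cx, cy, cz)
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  vol <- sum(av * cross(bv, cv))
  list(a = av, b = bv, c = cv,
       as = cross(bv, cv) / vol,
       bs = cross(cv, av) / vol,
       cs = cross(av, bv) / vol)
}

# brute-force d-spacing: length of the reciprocal-lattice vector
oracle_d <- function(h, k, l, a, b, c, alpha, beta, gamma) {
  lv <- lattice_vectors(a, b, c, alpha, beta, gamma)
  g <- h * lv$as + k * lv$bs + l * lv$cs
  1 / sqrt(sum(g * g))
}

# direct-summation structure factor over a pre-expanded atom list
# (element, occ, u_iso, x, y, z fractional); no symmetry shortcuts
oracle_sf <- function(cellpar, atoms, hkl, table) {
  out <- complex(length.out = nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    h <- hkl[r, 1]; k <- hkl[r, 2]; l <- hkl[r, 3]
    d <- oracle_d(h, k, l, cellpar[1], cellpar[2], cellpar[3],
                  cellpar[4], cellpar[5], cellpar[6])
    s <- 1 / (2 * d)
    acc <- 0 + 0i
    for (j in seq_len(nrow(atoms))) {
      co <- table[[atoms$element[j]]]
      f <- 0
      for (m in seq_along(co$a)) f <- f + co$a[m] * exp(-co$b[m] * s^2)
      t_dw <- exp(-8 * pi^2 * atoms$u_iso[j] * s^2)
      ph <- 2 * pi * (h * atoms$x[j] + k * atoms$y[j] + l * atoms$z[j])
      acc <- acc + atoms$occ[j] * f * t_dw * exp(1i * ph)
    }
    out[r] <- acc
  }
  out
}

random_triclinic_cell <- function() {
  unit_cell(runif(1, 6, 12), runif(1, 6, 12), runif(1, 6, 12),
            runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 100))
}

# random P1 model with <= n_max atoms, isotropic ADPs
random_p1_model <- function(n_max = 8) {
  n <- sample(seq_len(n_max), 1)
  atoms <- data.frame(
    label = paste0("A", seq_len(n)),
    element = sample(c("H", "C", "N", "O", "S"), n, replace = TRUE),
    x = runif(n), y = runif(n), z = runif(n),
    occ = runif(n, 0.5, 1), u_iso = runif(n, 0, 0.05),
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
    stringsAsFactors = FALSE)
  crystal_model(random_triclinic_cell(), atoms)
}

# the package's canonical simulation study conditions (documented in
# the methods vignette): orthorhombic P2(1)2(1)2(1) toy structure,
# atomic resolution, amplitude scale 10, constant dynamical error
study_sim <- function(seed, epsilon = 2, n_atoms = 16, d_min = 0.8,
                      scale = 10, noise = "none", noise_param = 1) {
  cell <- unit_cell(15, 18, 19)
  model <- random_toy_structure(n_atoms, cell,
                                elements = c(rep("C", 4), "O"),
                                seed = seed)
  simulate_observed(model, d_min, epsilon = epsilon, noise = noise,
                    noise_param = noise_param, seed = seed + 1000L,
                    scale = scale)
}

# minimal synthetic model CIF text (P2(1)2(1)2(1), mixed iso/aniso)
toy_cif_text <- function() {
  c("data_SYNTH",
    "_cell_length_a 8.090(2)",
    "_cell_length_b 9.940(2)",
    "_cell_length_c 17.700(4)",
    "_cell_angle_alpha 90",
    "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    "_symmetry_space_group_name_H-M 'P 21 21 21'",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "'-x+1/2,-y,z+1/2'",
    "'x+1/2,-y+1/2,-z'",
    "'-x,y+1/2,-z+1/2'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_U_iso_or_equiv",
    "C1 C 0.1234 0.2345 0.0456 1.0 0.025",
    "C2 C 0.3456 0.1234 0.1234 1.0 0.030",
    "O1 O 0.2222 0.4444 0.0789 1.0 0.028",
    "H1 H 0.1000 0.3000 0.1500 1.0 0.040",
    "loop_",
    "_atom_site_aniso_label",
    "_atom_site_aniso_U_11",
    "_atom_site_aniso_U_22",
    "_atom_site_aniso_U_33",
    "_atom_site_aniso_U_23",
    "_atom_site_aniso_U_13",
    "_atom_site_aniso_U_12",
    "C1 0.020 0.030 0.025 0.002 -0.001 0.003")
}
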