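test_that("HKLF4 lines parse into reflections and the terminator stops reading", {
  rs <- read_hklf4(text = c("   1   0   0  100.00    5.00",
                            "  -2   3   1   12.34    0.56",
                            "   0   0   0    0.00    0.00",
                            "   9   9   9  999.00    9.00"))
  expect_equal(nrow(rs), 2)
  expect_equal(rs$h, c(1L, -2L))
  expect_equal(rs$intensity, c(100.00, 12.34))
  expect_equal(rs$sigma, c(5.00, 0.56))
  # EOF-ended files (no terminator) are accepted too
  rs2 <- read_hklf4(text = "   1   0   0  100.00    5.00")
  expect_equal(nrow(rs2), 1)
  # batch columns beyond the sigma field are ignored
  rs3 <- read_hklf4(text = "   1   0   0  100.00    5.00   1")
  expect_equal(rs3$sigma, 5.00)
  expect_error(read_hklf4(text = "   a   0   0  100.00    5.00"),
               "line 1")
})

test_that("HKLF4 writing is fixed-width and guards its field widths", {
  rs <- reflection_set(1, 0, 0, 100, 5)
  expect_equal(write_hklf4(rs, terminator = FALSE)[1],
               "   1   0   0  100.00    5.00")
  expect_equal(write_hklf4(reflection_set(1, 0, 0, 1, 1))[2],
               "   0   0   0    0.00    0.00")
  # empty set -> terminator-only output
  empty <- reflection_set(integer(0), integer(0), integer(0),
                          numeric(0), numeric(0))
  expect_equal(write_hklf4(empty), "   0   0   0    0.00    0.00")
  expect_error(write_hklf4(reflection_set(1, 0, 0, 12345678, 1)),
               "rescale")
})

test_that("HKLF4 round-trip preserves all fields at format precision", {
  set.seed(3)
  n <- 200
  rs <- reflection_set(sample(-20:20, n, TRUE), sample(-20:20, n, TRUE),
                       sample(c(-20:-1, 1:20), n, TRUE),
                       round(runif(n, -50, 9000), 2),
                       round(runif(n, 0, 500), 2))
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hklf4(rs, path)
  back <- read_hklf4(path)
  expect_equal(back$h, rs$h)
  expect_equal(back$intensity, rs$intensity, tolerance = 1e-9)
  expect_equal(back$sigma, rs$sigma, tolerance = 1e-9)
  # writer is deterministic byte-for-byte
  expect_identical(write_hklf4(back), write_hklf4(rs))
})

test_that("d-spacings reduce correctly for orthorhombic cells and match a brute-force oracle", {
  ortho <- unit_cell(8.090, 9.940, 17.700)
  expect_equal(d_spacing(1, 0, 0, ortho), 8.090)  # d(100) = a
  cubic <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(1, 1, 1, cubic), 10 / sqrt(3), tolerance = 1e-12)
  expect_error(d_spacing(0, 0, 0, cubic), "0,0,0")
  set.seed(11)
  for (rep in 1:20) {
    cl <- random_triclinic_cell()
    h <- sample(-8:8, 1); k <- sample(-8:8, 1); l <- sample(c(-8:-1, 1:8), 1)
    expect_equal(d_spacing(h, k, l, cl),
                 oracle_d(h, k, l, cl$a, cl$b, cl$c,
                          cl$alpha, cl$beta, cl$gamma),
                 tolerance = 1e-10)
  }
})

test_that("cell volume matches the triclinic closed form and guards degeneracy", {
  cl <- unit_cell(8, 9, 10, 80, 95, 100)
  lv <- lattice_vectors(8, 9, 10, 80, 95, 100)
  vol <- sum(lv$a * c(lv$b[2] * lv$c[3] - lv$b[3] * lv$c[2],
                      lv$b[3] * lv$c[1] - lv$b[1] * lv$c[3],
                      lv$b[1] * lv$c[2] - lv$b[2] * lv$c[1]))
  expect_equal(cl$volume, vol, tolerance = 1e-12)
  expect_error(unit_cell(-1, 9, 10), "positive")
  expect_error(unit_cell(8, 9, 10, gamma = 181), "angles")
})

test_that("equal-count binning partitions reflections, largest d first", {
  set.seed(5)
  d <- runif(101, 0.8, 12)
  rs <- reflection_set(rep(1, 101), rep(2, 101), seq_len(101),
                       rexp(101), rep(1, 101))
  rs$d <- d
  b <- assign_resolution_bins(rs, 10)
  expect_equal(sort(b$size, decreasing = TRUE), c(11, rep(10, 9)))
  expect_equal(b$size[1], 11)               # remainder goes to low resolution
  expect_setequal(unlist(b$index), seq_len(101))
  expect_true(all(diff(b$mean_d) < 0))      # strictly decreasing mean d
  expect_true(all(b$d_min[-10] >= b$d_max[-1]))
  # n_bins = 1 collects everything; exact division gives equal bins
  expect_equal(assign_resolution_bins(rs, 1)$size, 101L)
  b2 <- assign_resolution_bins(rs[1:100, ], 10)
  expect_true(all(b2$size == 10))
  expect_error(assign_resolution_bins(rs, 200), "more bins")
})

test_that("merging statistics match hand computation and are scale invariant", {
  cell <- unit_cell(10, 11, 12)
  # one unique reflection observed as {10, 12}: R_merge = 2/22
  rs <- reflection_set(c(1, -1), c(2, 2), c(3, -3), c(10, 12), c(1, 1),
                       cell = cell)
  ms <- merge_stats(rs, n_bins = 1, laue = "mmm")
  expect_equal(ms$overall$r_merge, 2 / 22, tolerance = 1e-12)
  expect_equal(ms$overall$r_meas, sqrt(2) * 2 / 22, tolerance = 1e-12)
  expect_equal(ms$overall$multiplicity, 2)

  # every unique observed once: R factors absent, not zero
  rs1 <- reflection_set(1:4, rep(1, 4), rep(2, 4), runif(4, 1, 5),
                        rep(0.5, 4), cell = cell)
  ms1 <- merge_stats(rs1, n_bins = 1)
  expect_true(is.na(ms1$overall$r_merge))
  expect_true(is.na(ms1$overall$cc_half))

  # two identical half-datasets: CC1/2 = 1
  h <- c(1, 2, 3, 4); k <- rep(0, 4); l <- rep(1, 4)
  ii <- c(5, 9, 2, 14)
  rs2 <- reflection_set(rep(h, 2), rep(k, 2), rep(l, 2), rep(ii, 2),
                        rep(1, 8), cell = cell)
  expect_equal(merge_stats(rs2, n_bins = 1)$overall$cc_half, 1,
               tolerance = 1e-12)

  # scale invariance of R_merge, R_meas, CC1/2
  set.seed(21)
  hh <- sample(1:6, 60, TRUE); kk <- sample(0:5, 60, TRUE)
  ll <- sample(1:6, 60, TRUE)
  rsu <- reflection_set(hh, kk, ll, rexp(60, 0.1) + 1, runif(60, 0.5, 2),
                        cell = cell)
  a <- merge_stats(rsu, n_bins = 3, seed = 7)
  b <- local({
    rsc <- rsu; rsc$intensity <- rsc$intensity * 37.5
    merge_stats(rsc, n_bins = 3, seed = 7)
  })
  expect_equal(a$overall$r_merge, b$overall$r_merge, tolerance = 1e-12)
  expect_equal(a$overall$r_meas, b$overall$r_meas, tolerance = 1e-12)
  expect_equal(a$overall$cc_half, b$overall$cc_half, tolerance = 1e-12)
})

test_that("CIF structure-factor loops read into a reflection set", {
  txt <- c("data_x",
           "_cell_length_a 10", "_cell_length_b 11", "_cell_length_c 12",
           "loop_",
           "_refln_index_h", "_refln_index_k", "_refln_index_l",
           "_refln_F_squared_meas", "_refln_F_squared_sigma",
           "1 0 0 100.0 5.0",
           "0 2 0  25.0 2.0")
  rs <- read_cif_reflections(text = txt)
  expect_equal(rs$intensity, c(100, 25))
  expect_equal(rs$d[1], 10)
})
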