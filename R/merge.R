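#' Symmetry-reduce Miller indices to a canonical representative
#'
#' Maps each (h,k,l) to a canonical equivalent under the chosen Laue
#' group, so that symmetry-mates share one key.  Supported groups:
#' `"-1"` (Friedel pairs only) and `"mmm"` (orthorhombic Laue symmetry,
#' the group used for primitive orthorhombic space groups such as
#' P2(1)2(1)2(1)).  Alternatively a list of 3x3 rotation matrices can be
#' given and the lexicographically largest image (including Friedel
#' mates) is chosen.
#'
#' @param h,k,l Integer Miller indices (vectorized).
#' @param laue `"mmm"`, `"-1"`, or a list of 3x3 integer rotation
#'   matrices.
#' @return Integer matrix with columns h, k, l of canonical indices.
#' @export
canonical_hkl <- function(h, k, l, laue = "mmm") {
  if (is.character(laue) && laue == "mmm") {
    return(cbind(h = abs(h), k = abs(k), l = abs(l)))
  }
  if (is.character(laue) && laue == "-1") {
    flip <- (h < 0) | (h == 0 & k < 0) | (h == 0 & k == 0 & l < 0)
    s <- ifelse(flip, -1L, 1L)
    return(cbind(h = h * s, k = k * s, l = l * s))
  }
  if (is.list(laue)) {
    rots <- c(laue, lapply(laue, function(r) -r))
    hm <- cbind(h, k, l)
    out <- hm
    for (r in rots) {
      cand <- hm %*% r
      better <- (cand[, 1] > out[, 1]) |
        (cand[, 1] == out[, 1] & cand[, 2] > out[, 2]) |
        (cand[, 1] == out[, 1] & cand[, 2] == out[, 2] & cand[, 3] > out[, 3])
      out[better, ] <- cand[better, ]
    }
    colnames(out) <- c("h", "k", "l")
    return(out)
  }
  stop("unsupported Laue group specification")
}

#' Theoretical unique reflection count
#'
#' Direct enumeration of the reciprocal lattice between two resolution
#' limits, reduced under the given Laue group.  Used for completeness;
#' systematic absences are not subtracted (documented convention).
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution limit (Angstrom).
#' @param d_max Low-resolution limit (default `Inf`).
#' @param laue Laue group passed to [canonical_hkl()].
#' @return Number of unique reflections.
#' @export
theoretical_unique_count <- function(cell, d_min, d_max = Inf, laue = "mmm") {
  nrow(enumerate_unique_hkl(cell, d_min, d_max = d_max, laue = laue))
}

#' Enumerate unique reflections to a resolution limit
#'
#' @inheritParams theoretical_unique_count
#' @return A data.frame with columns `h, k, l, d`, sorted by d
#'   descending.
#' @export
enumerate_unique_hkl <- function(cell, d_min, d_max = Inf, laue = "mmm") {
  if (d_min <= 0) stop("d_min must be positive")
  # generous index bounds, then filter by true d
  hmax <- ceiling(cell$a / d_min) + 1L
  kmax <- ceiling(cell$b / d_min) + 1L
  lmax <- ceiling(cell$c / d_min) + 1L
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  can <- canonical_hkl(g$h, g$k, g$l, laue = laue)
  can <- unique(as.data.frame(can))
  d <- d_spacing(can$h, can$k, can$l, cell)
  keep <- d >= d_min & d <= d_max
  out <- data.frame(h = can$h[keep], k = can$k[keep], l = can$l[keep],
                    d = d[keep])
  out[order(-out$d), , drop = FALSE]
}

#' Merging statistics of an unmerged reflection set
#'
#' Computes the standard data-quality indicators, overall and in
#' equal-count resolution bins:
#' \itemize{
#'   \item `R_merge = sum_hkl sum_i |I_i - <I>| / sum_hkl sum_i I_i`
#'   \item `R_meas` - as `R_merge` with the multiplicity factor
#'     `sqrt(n/(n-1))` on each deviation
#'   \item `CC1/2` - Pearson correlation between mean intensities of two
#'     random half-datasets
#'   \item mean `I/sigma` and multiplicity.
#' }
#' R-factors are computed over reflections observed at least twice; if
#' there are none they are reported as `NA` (absent, not zero).  The
#' high-resolution cutoff diagnostics report both the first bin failing
#' `I/sigma > 1` and the first failing `CC1/2 > 50%`; neither rule is
#' applied automatically.
#'
#' @param rs Unmerged [reflection_set()] with d-spacings.
#' @param n_bins Number of resolution bins for the shell table.
#' @param laue Laue group for symmetry reduction (see [canonical_hkl()]).
#' @param seed Seed for the random half-dataset split (kept separate
#'   from the global RNG state).
#' @param cell Optional cell for completeness; defaults to the set's.
#' @return List of class `"merge_stats"` with `overall` (one-row
#'   data.frame), `shells` (per-bin data.frame), and `cutoff`
#'   diagnostics.
#' @export
merge_stats <- function(rs, n_bins = 10, laue = "mmm", seed = 42,
                        cell = attr(rs, "cell")) {
  can <- canonical_hkl(rs$h, rs$k, rs$l, laue = laue)
  key <- paste(can[, 1], can[, 2], can[, 3], sep = ",")
  groups <- split(seq_len(nrow(rs)), key)
  d_unique <- vapply(groups, function(ii) mean(rs$d[ii]), 0)
  n_obs <- vapply(groups, length, 0L)

  halves <- withr::with_seed(seed, lapply(groups, function(ii) {
    if (length(ii) < 2) return(NULL)
    p <- sample(ii)
    list(a = mean(rs$intensity[p[seq(1, length(p), 2)]]),
         b = mean(rs$intensity[p[seq(2, length(p), 2)]]))
  }))

  stat_block <- function(sel) {   # sel: logical over unique reflections
    gs <- groups[sel]
    ns <- n_obs[sel]
    multi <- ns >= 2
    num_rm <- num_rms <- den <- 0
    for (g in gs[multi]) {
      ii <- rs$intensity[g]
      dev <- abs(ii - mean(ii))
      num_rm <- num_rm + sum(dev)
      num_rms <- num_rms + sqrt(length(ii) / (length(ii) - 1)) * sum(dev)
      den <- den + sum(ii)
    }
    hv <- halves[sel]
    hv <- hv[!vapply(hv, is.null, TRUE)]
    cc <- if (length(hv) >= 3) {
      a <- vapply(hv, `[[`, 0, "a"); b <- vapply(hv, `[[`, 0, "b")
      if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
    } else NA_real_
    obs <- unlist(gs)
    isig <- rs$intensity[obs] / rs$sigma[obs]
    data.frame(
      n_obs = length(obs), n_unique = length(gs),
      multiplicity = length(obs) / max(length(gs), 1),
      r_merge = if (den > 0) num_rm / den else NA_real_,
      r_meas = if (den > 0) num_rms / den else NA_real_,
      cc_half = cc,
      i_over_sigma = mean(isig[is.finite(isig)]))
  }

  nb <- min(n_bins, length(groups))
  bin <- assign_resolution_bins(d_unique, n_bins = nb)
  shells <- do.call(rbind, lapply(seq_len(nb), function(b) {
    sel <- logical(length(groups)); sel[bin$index[[b]]] <- TRUE
    cbind(data.frame(bin = b, d_max = bin$d_max[b], d_min = bin$d_min[b]),
          stat_block(sel))
  }))
  overall <- stat_block(rep(TRUE, length(groups)))

  if (!is.null(cell)) {
    theo <- theoretical_unique_count(cell, d_min = min(rs$d),
                                     d_max = max(rs$d), laue = laue)
    overall$completeness <- overall$n_unique / theo
  }

  first_fail <- function(ok) {
    fail <- which(!ok)
    if (length(fail) == 0) NA_integer_ else fail[1]
  }
  cutoff <- list(
    first_bin_failing_i_over_sigma =
      first_fail(shells$i_over_sigma > 1.0),
    first_bin_failing_cc_half =
      first_fail(is.na(shells$cc_half) | shells$cc_half > 0.5))

  structure(list(overall = overall, shells = shells, cutoff = cutoff,
                 laue = if (is.character(laue)) laue else "custom"),
            class = "merge_stats")
}

#' @export
print.merge_stats <- function(x, ...) {
  cat("Overall merging statistics:\n")
  ov <- x$overall
  cat(sprintf("  n_obs %d  unique %d  multiplicity %.2f\n",
              ov$n_obs, ov$n_unique, ov$multiplicity))
  cat(sprintf("  R_merge %s  R_meas %s  CC1/2 %s  <I/sigma> %.2f\n",
              if (is.na(ov$r_merge)) "NA" else sprintf("%.1f%%", 100 * ov$r_merge),
              if (is.na(ov$r_meas)) "NA" else sprintf("%.1f%%", 100 * ov$r_meas),
              if (is.na(ov$cc_half)) "NA" else sprintf("%.1f%%", 100 * ov$cc_half),
              ov$i_over_sigma))
  cat("Resolution shells:\n")
  print(x$shells, row.names = FALSE, digits = 3)
  invisible(x)
}
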