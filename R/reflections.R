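#' Build a reflection set
#'
#' The central data container: an ordered table of indexed reflections
#' with intensities and their standard uncertainties, optionally carrying
#' a unit cell from which d-spacings are derived.
#'
#' @param h,k,l Integer Miller indices.
#' @param intensity Intensities (arbitrary scaled counts).
#' @param sigma Standard uncertainties, same scale; must be >= 0.
#' @param cell Optional [unit_cell()]; if given, d-spacings are computed.
#' @param merged Logical flag: one record per symmetry-unique reflection.
#' @param crystal Optional integer crystal/batch id per observation
#'   (unmerged multi-crystal data).
#' @return A data.frame of class `"reflection_set"` with columns
#'   `h, k, l, intensity, sigma, d` (and `crystal` if supplied), plus
#'   attributes `cell` and `merged`.
#' @export
reflection_set <- function(h, k, l, intensity, sigma,
                           cell = NULL, merged = FALSE, crystal = NULL) {
  n <- length(h)
  if (length(intensity) == 1) intensity <- rep(intensity, n)
  if (length(sigma) == 1) sigma <- rep(sigma, n)
  stopifnot(length(k) == n, length(l) == n,
            length(intensity) == n, length(sigma) == n)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (any(h == 0 & k == 0 & l == 0))
    stop("reflection (0,0,0) is not a valid data record")
  rs <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   intensity = as.numeric(intensity),
                   sigma = as.numeric(sigma),
                   d = rep(NA_real_, n))
  if (!is.null(crystal)) rs$crystal <- as.integer(crystal)
  class(rs) <- c("reflection_set", "data.frame")
  attr(rs, "merged") <- isTRUE(merged)
  if (!is.null(cell)) rs <- set_cell(rs, cell)
  rs
}

#' Attach a unit cell and compute d-spacings
#'
#' @param rs A [reflection_set()].
#' @param cell A [unit_cell()].
#' @return The reflection set with the `d` column filled in.
#' @export
set_cell <- function(rs, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  attr(rs, "cell") <- cell
  rs$d <- d_spacing(rs$h, rs$k, rs$l, cell)
  rs
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("Reflection set: %d observations%s%s\n", nrow(x),
              if (isTRUE(attr(x, "merged"))) " (merged)" else "",
              if (!is.null(attr(x, "cell")))
                sprintf(", d %.2f-%.2f A", max(x$d), min(x$d)) else ""))
  NextMethod()
}

# fixed columns of the SHELX HKLF 4 record: 3I4, 2F8.2
.hklf4_fields <- function(line) {
  c(h = substr(line, 1, 4), k = substr(line, 5, 8), l = substr(line, 9, 12),
    i = substr(line, 13, 20), s = substr(line, 21, 28))
}

#' Read SHELX HKLF4 reflection data
#'
#' Parses the fixed-width SHELX reflection format (3I4, 2F8.2: h k l
#' intensity sigma).  An all-zero index line, if present, terminates the
#' data; trailing lines after the terminator are ignored, as are batch
#' numbers beyond column 28.  Files without a terminator are read to the
#' end.
#'
#' @param file Path to an `.hkl` file, or a character vector of lines
#'   (given as `text`).
#' @param text Optional character vector of lines, bypassing `file`.
#' @param cell Optional [unit_cell()] to attach.
#' @return A [reflection_set()] in file order.
#' @export
read_hklf4 <- function(file = NULL, text = NULL, cell = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  h <- k <- l <- integer(0); i <- s <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    f <- .hklf4_fields(line)
    idx <- suppressWarnings(as.integer(f[1:3]))
    if (any(is.na(idx)))
      stop(sprintf("malformed HKLF4 index fields on line %d: '%s'", ln, line))
    if (all(idx == 0L)) break  # SHELX terminator record
    val <- suppressWarnings(as.numeric(f[4:5]))
    if (any(is.na(val)))
      stop(sprintf("malformed HKLF4 value fields on line %d: '%s'", ln, line))
    h <- c(h, idx[1]); k <- c(k, idx[2]); l <- c(l, idx[3])
    i <- c(i, val[1]); s <- c(s, val[2])
  }
  reflection_set(h, k, l, i, s, cell = cell)
}

#' Write SHELX HKLF4 reflection data
#'
#' Deterministic fixed-width output (3I4, 2F8.2).  Values that do not
#' fit their field raise an error suggesting a rescale.
#'
#' @param rs A [reflection_set()].
#' @param file Output path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @param terminator Append the conventional all-zero terminator record.
#' @return Invisibly, the character vector of lines written.
#' @export
write_hklf4 <- function(rs, file = NULL, terminator = TRUE) {
  fmt_int <- function(x, what) {
    out <- sprintf("%4d", x)
    bad <- nchar(out) > 4
    if (any(bad))
      stop(sprintf("%s value %d does not fit the 4-column HKLF4 field",
                   what, x[which(bad)[1]]))
    out
  }
  fmt_num <- function(x, what) {
    out <- sprintf("%8.2f", x)
    bad <- nchar(out) > 8
    if (any(bad))
      stop(sprintf(
        "%s value %g overflows the 8-column HKLF4 field; rescale the data",
        what, x[which(bad)[1]]))
    out
  }
  lines <- character(0)
  if (nrow(rs) > 0) {
    lines <- paste0(fmt_int(rs$h, "h"), fmt_int(rs$k, "k"),
                    fmt_int(rs$l, "l"),
                    fmt_num(rs$intensity, "intensity"),
                    fmt_num(rs$sigma, "sigma"))
  }
  if (terminator)
    lines <- c(lines, "   0   0   0    0.00    0.00")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read reflections from a CIF structure-factor block
#'
#' Reads `_refln` loops with `index_h/_k/_l` and either
#' `F_squared_meas`/`F_squared_sigma` or `F_meas`/`F_sigma` (amplitudes
#' are squared into intensities with sigma propagated as
#' `sigma(F^2) = 2 F sigma(F)`).
#'
#' @param file Path to a CIF file, or `text` lines.
#' @param text Optional character vector of lines.
#' @param cell Optional [unit_cell()]; if absent and the block carries
#'   `_cell_length_*`, that cell is used.
#' @return A [reflection_set()].
#' @export
read_cif_reflections <- function(file = NULL, text = NULL, cell = NULL) {
  blocks <- cif_parse(file = file, text = text)
  for (bl in blocks) {
    loop <- cif_find_loop(bl, c("_refln_index_h", "_refln.index_h"))
    if (is.null(loop)) next
    nm <- names(loop)
    pick <- function(cands) {
      hit <- intersect(cands, nm)
      if (length(hit) == 0) return(NULL)
      suppressWarnings(as.numeric(loop[[hit[1]]]))
    }
    h <- pick(c("_refln_index_h", "_refln.index_h"))
    k <- pick(c("_refln_index_k", "_refln.index_k"))
    l <- pick(c("_refln_index_l", "_refln.index_l"))
    i2 <- pick(c("_refln_F_squared_meas", "_refln.F_squared_meas"))
    s2 <- pick(c("_refln_F_squared_sigma", "_refln.F_squared_sigma"))
    if (is.null(i2)) {
      fm <- pick(c("_refln_F_meas", "_refln.F_meas", "_refln_F_meas_au"))
      fs <- pick(c("_refln_F_sigma", "_refln.F_sigma", "_refln_F_meas_sigma_au"))
      if (is.null(fm)) stop("refln loop has neither F_squared_meas nor F_meas")
      i2 <- fm^2
      s2 <- if (is.null(fs)) rep(0, length(fm)) else 2 * abs(fm) * fs
    }
    if (is.null(s2)) s2 <- rep(0, length(i2))
    if (is.null(cell) && !is.null(bl$items[["_cell_length_a"]]))
      cell <- .cif_cell(bl)
    return(reflection_set(h, k, l, i2, s2, cell = cell))
  }
  stop("no _refln loop found in CIF input")
}

#' Partition reflections into equal-count resolution bins
#'
#' Reflections are ordered by d-spacing from low resolution (large d) to
#' high resolution (small d) with a stable sort, then split into
#' `n_bins` contiguous groups whose sizes differ by at most one (the
#' low-resolution bins take any remainder).
#'
#' @param rs A [reflection_set()] with d-spacings assigned.
#' @param n_bins Number of bins (default 10).
#' @return An object of class `"resolution_binning"`: list with
#'   `n_bins`, `assignment` (bin id per reflection, input order),
#'   `index` (list of reflection indices per bin), `mean_d`, `d_max`,
#'   `d_min`, and `size` per bin.
#' @export
assign_resolution_bins <- function(rs, n_bins = 10) {
  d <- if (inherits(rs, "reflection_set")) rs$d else as.numeric(rs)
  n <- length(d)
  if (any(!is.finite(d))) stop("all reflections need a d-spacing before binning")
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > n) stop("more bins than reflections")
  ord <- order(-d)                       # stable: ties keep input order
  base <- n %/% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= n %% n_bins)
  stop_at <- cumsum(sizes)
  start_at <- c(1L, head(stop_at, -1L) + 1L)
  index <- lapply(seq_len(n_bins), function(b) ord[start_at[b]:stop_at[b]])
  assignment <- integer(n)
  for (b in seq_len(n_bins)) assignment[index[[b]]] <- b
  structure(list(
    n_bins = n_bins,
    assignment = assignment,
    index = index,
    mean_d = vapply(index, function(ii) mean(d[ii]), 0),
    d_max = vapply(index, function(ii) max(d[ii]), 0),
    d_min = vapply(index, function(ii) min(d[ii]), 0),
    size = sizes), class = "resolution_binning")
}

#' @export
print.resolution_binning <- function(x, ...) {
  cat(sprintf("Resolution binning: %d bins\n", x$n_bins))
  print(data.frame(bin = seq_len(x$n_bins), n = x$size,
                   d_max = round(x$d_max, 3), d_min = round(x$d_min, 3),
                   mean_d = round(x$mean_d, 3)), row.names = FALSE)
  invisible(x)
}
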