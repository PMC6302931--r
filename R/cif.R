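# Minimal core-CIF reader: data blocks, key-value items, loop_ tables,
# quoted strings and semicolon text fields.  Covers the subset used by
# small-molecule model and structure-factor CIFs.

.cif_tokenize_line <- function(line) {
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == '"') {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      toks <- c(toks, substr(line, i + 1L, j - 1L))
      i <- j + 1L
      next
    }
    j <- i
    while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
    toks <- c(toks, substr(line, i, j - 1L))
    i <- j
  }
  toks
}

#' Parse CIF text into data blocks
#'
#' @param file Path to a CIF file, or lines via `text`.
#' @param text Optional character vector of lines.
#' @return List of blocks; each block is a list with `name`, `items`
#'   (named character vector) and `loops` (list of data.frames of
#'   character columns).
#' @export
cif_parse <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  blocks <- list()
  block <- NULL
  i <- 1L; n <- length(lines)
  flush_block <- function() if (!is.null(block)) blocks[[length(blocks) + 1L]] <<- block

  read_value <- function() {   # reads one value starting at lines[i]
    if (startsWith(lines[i], ";")) {
      val <- sub("^;", "", lines[i]); i <<- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        val <- paste(val, lines[i], sep = "\n"); i <<- i + 1L
      }
      i <<- i + 1L
      return(val)
    }
    toks <- .cif_tokenize_line(lines[i]); i <<- i + 1L
    if (length(toks) == 0) return(read_value())
    toks[1]
  }

  while (i <= n) {
    line <- lines[i]
    toks <- .cif_tokenize_line(line)
    if (length(toks) == 0) { i <- i + 1L; next }
    t1 <- toks[1]
    if (grepl("^data_", t1, ignore.case = TRUE)) {
      flush_block()
      block <- list(name = sub("^data_", "", t1, ignore.case = TRUE),
                    items = list(), loops = list())
      i <- i + 1L
    } else if (tolower(t1) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n) {
        tk <- .cif_tokenize_line(lines[i])
        if (length(tk) == 1 && startsWith(tk[1], "_")) {
          tags <- c(tags, tk[1]); i <- i + 1L
        } else break
      }
      vals <- character(0)
      while (i <= n) {
        ln <- lines[i]
        tk <- .cif_tokenize_line(ln)
        if (length(tk) == 0) {
          if (startsWith(ln, ";")) {
            vals <- c(vals, read_value()); next
          }
          i <- i + 1L; next
        }
        if (startsWith(tk[1], "_") || tolower(tk[1]) == "loop_" ||
            grepl("^data_", tk[1], ignore.case = TRUE)) break
        vals <- c(vals, tk); i <- i + 1L
      }
      if (length(tags) > 0 && length(vals) %% length(tags) == 0 &&
          length(vals) > 0) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tags
        if (is.null(block)) block <- list(name = "", items = list(), loops = list())
        block$loops[[length(block$loops) + 1L]] <- df
      } else if (length(vals) > 0) {
        stop("malformed CIF loop: value count not a multiple of tag count")
      }
    } else if (startsWith(t1, "_")) {
      if (is.null(block)) block <- list(name = "", items = list(), loops = list())
      if (length(toks) >= 2) {
        block$items[[t1]] <- toks[2]; i <- i + 1L
      } else {
        i <- i + 1L
        block$items[[t1]] <- read_value()
      }
    } else {
      i <- i + 1L
    }
  }
  flush_block()
  blocks
}

cif_find_loop <- function(block, any_of) {
  for (lp in block$loops)
    if (any(any_of %in% names(lp))) return(lp)
  NULL
}

# numeric value with a trailing standard-uncertainty "(..)" stripped
cif_num <- function(x) {
  suppressWarnings(as.numeric(sub("\\(.*\\)$", "", x)))
}

.cif_cell <- function(block) {
  it <- block$items
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need %in% names(it))) stop("CIF block lacks cell lengths")
  ang <- function(tag) if (tag %in% names(it)) cif_num(it[[tag]]) else 90
  unit_cell(cif_num(it[["_cell_length_a"]]),
            cif_num(it[["_cell_length_b"]]),
            cif_num(it[["_cell_length_c"]]),
            ang("_cell_angle_alpha"), ang("_cell_angle_beta"),
            ang("_cell_angle_gamma"))
}

#' Parse a symmetry operator in xyz notation
#'
#' Converts strings such as `"-x+1/2,-y,z+1/2"` into a rotation matrix
#' and translation vector.
#'
#' @param xyz Operator string with three comma-separated components.
#' @return List with `R` (3x3) and `t` (length 3, reduced mod 1).
#' @export
parse_symop_xyz <- function(xyz) {
  parts <- strsplit(tolower(gsub(" ", "", xyz)), ",")[[1]]
  if (length(parts) != 3) stop(sprintf("bad symmetry operator '%s'", xyz))
  if (grepl("[^xyz0-9+./-]", paste(parts, collapse = "")))
    stop(sprintf("bad symmetry operator '%s'", xyz))
  R <- matrix(0, 3, 3); t <- numeric(3)
  ev <- function(expr, x, y, z)
    eval(parse(text = expr), envir = list(x = x, y = y, z = z))
  for (i in 1:3) {
    t[i] <- ev(parts[i], 0, 0, 0)
    R[i, 1] <- ev(parts[i], 1, 0, 0) - t[i]
    R[i, 2] <- ev(parts[i], 0, 1, 0) - t[i]
    R[i, 3] <- ev(parts[i], 0, 0, 1) - t[i]
  }
  list(R = R, t = t %% 1)
}

# standard general-position operators for a few space groups used here
.builtin_symops <- function(name) {
  key <- toupper(gsub("[ ()_]", "", name))
  ops <- switch(key,
    "P1" = "x,y,z",
    "P212121" = c("x,y,z", "-x+1/2,-y,z+1/2",
                  "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
    "P21212" = c("x,y,z", "-x,-y,z", "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
    NULL)
  if (is.null(ops)) return(NULL)
  lapply(ops, parse_symop_xyz)
}

#' Assemble a crystal model
#'
#' @param cell A [unit_cell()].
#' @param symmetry List of operators from [parse_symop_xyz()] (identity
#'   first); default P1.
#' @param atoms Data.frame with columns `label`, `element`, `x`, `y`,
#'   `z`, `occ`, `u_iso` and optionally `u11, u22, u33, u23, u13, u12`
#'   (NA where isotropic).
#' @param space_group Space-group name (free text).
#' @return Object of class `"crystal_model"`.
#' @export
crystal_model <- function(cell, atoms, symmetry = list(parse_symop_xyz("x,y,z")),
                          space_group = "P 1") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  need <- c("label", "element", "x", "y", "z", "occ", "u_iso")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns label, element, x, y, z, occ, u_iso")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("fractional coordinates must be finite")
  if (any(atoms$occ <= 0 | atoms$occ > 1))
    stop("occupancies must lie in (0, 1]")
  if (any(is.finite(atoms$u_iso) & atoms$u_iso < 0))
    stop("U_iso must be non-negative")
  structure(list(cell = cell, symmetry = symmetry, atoms = atoms,
                 space_group = space_group),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("Crystal model: %d atoms, %d symmetry operators, %s\n",
              nrow(x$atoms), length(x$symmetry), x$space_group))
  print(x$cell)
  invisible(x)
}

#' Read a small-molecule model from CIF
#'
#' Reads cell, symmetry (from an xyz operator loop, or a recognized
#' space-group name as fallback), the atom-site loop and any
#' anisotropic-ADP loop (matched to atoms by label; an aniso label with
#' no matching atom is an error).
#'
#' @param file CIF path, or lines via `text`.
#' @param text Optional character vector of lines.
#' @param block Optional data-block name to select.
#' @return A [crystal_model()].
#' @export
parse_model_cif <- function(file = NULL, text = NULL, block = NULL) {
  blocks <- cif_parse(file = file, text = text)
  if (!is.null(block)) {
    blocks <- Filter(function(b) identical(b$name, block), blocks)
    if (length(blocks) == 0) stop(sprintf("no data block '%s' in CIF", block))
  }
  for (bl in blocks) {
    site <- cif_find_loop(bl, c("_atom_site_label", "_atom_site.label"))
    if (is.null(site) || !"_cell_length_a" %in% names(bl$items)) next
    cell <- .cif_cell(bl)

    symloop <- cif_find_loop(bl, c("_symmetry_equiv_pos_as_xyz",
                                   "_space_group_symop_operation_xyz"))
    sg <- bl$items[["_symmetry_space_group_name_H-M"]]
    if (is.null(sg)) sg <- bl$items[["_space_group_name_H-M_alt"]]
    if (is.null(sg)) sg <- "P 1"
    symmetry <- if (!is.null(symloop)) {
      col <- intersect(c("_symmetry_equiv_pos_as_xyz",
                         "_space_group_symop_operation_xyz"),
                       names(symloop))[1]
      lapply(symloop[[col]], parse_symop_xyz)
    } else {
      ops <- .builtin_symops(sg)
      if (is.null(ops))
        stop(sprintf("no symmetry operator loop and unknown space group '%s'", sg))
      ops
    }

    lab <- site[["_atom_site_label"]]
    elem <- site[["_atom_site_type_symbol"]]
    if (is.null(elem)) elem <- lab
    # leading letters of the label/symbol, e.g. "C12" -> "C", "H5B" -> "H"
    elem <- sub("^([A-Za-z]+).*", "\\1", elem)
    occ <- if ("_atom_site_occupancy" %in% names(site))
      cif_num(site[["_atom_site_occupancy"]]) else rep(1, length(lab))
    occ[is.na(occ)] <- 1
    uiso <- if ("_atom_site_U_iso_or_equiv" %in% names(site))
      cif_num(site[["_atom_site_U_iso_or_equiv"]]) else rep(0, length(lab))
    uiso[is.na(uiso)] <- 0
    atoms <- data.frame(
      label = lab, element = elem,
      x = cif_num(site[["_atom_site_fract_x"]]),
      y = cif_num(site[["_atom_site_fract_y"]]),
      z = cif_num(site[["_atom_site_fract_z"]]),
      occ = occ, u_iso = uiso,
      u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
      u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
      stringsAsFactors = FALSE)

    aniso <- cif_find_loop(bl, c("_atom_site_aniso_label",
                                 "_atom_site_aniso.label"))
    if (!is.null(aniso)) {
      alab <- aniso[["_atom_site_aniso_label"]]
      idx <- match(alab, atoms$label)
      if (any(is.na(idx)))
        stop(sprintf("anisotropic ADP label '%s' matches no atom",
                     alab[which(is.na(idx))[1]]))
      for (uu in c("11", "22", "33", "23", "13", "12")) {
        tag <- paste0("_atom_site_aniso_U_", uu)
        if (tag %in% names(aniso))
          atoms[[paste0("u", uu)]][idx] <- cif_num(aniso[[tag]])
      }
    }
    return(crystal_model(cell, atoms, symmetry, space_group = sg))
  }
  stop("CIF input has no block with both a cell and an atom-site loop")
}

#' Read a protein model from PDB-format records
#'
#' Minimal reader for the protein use case: CRYST1 gives the cell,
#' ATOM/HETATM records give element, Cartesian coordinates (converted
#' to fractional), occupancy and B factor (`U_iso = B / 8 pi^2`).
#' ANISOU records are applied only for orthogonal cells, where the
#' Cartesian U tensor coincides with the CIF convention.
#'
#' @param file PDB path, or lines via `text`.
#' @param text Optional character vector of lines.
#' @return A [crystal_model()] (symmetry P1 unless the CRYST1 space
#'   group is recognized).
#' @export
read_pdb_model <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) == 0) stop("PDB input lacks a CRYST1 record")
  cr <- cr[1]
  cell <- unit_cell(as.numeric(substr(cr, 7, 15)),
                    as.numeric(substr(cr, 16, 24)),
                    as.numeric(substr(cr, 25, 33)),
                    as.numeric(substr(cr, 34, 40)),
                    as.numeric(substr(cr, 41, 47)),
                    as.numeric(substr(cr, 48, 54)))
  sg <- trimws(substr(cr, 56, 66))
  ops <- .builtin_symops(sg)
  if (is.null(ops)) ops <- list(parse_symop_xyz("x,y,z"))

  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(at) == 0) stop("PDB input has no ATOM/HETATM records")
  xyz_cart <- cbind(as.numeric(substr(at, 31, 38)),
                    as.numeric(substr(at, 39, 46)),
                    as.numeric(substr(at, 47, 54)))
  frac <- t(solve(cell_orth_matrix(cell)) %*% t(xyz_cart))
  elem <- trimws(substr(at, 77, 78))
  name <- trimws(substr(at, 13, 16))
  elem[!nzchar(elem)] <- sub("^[0-9]*([A-Za-z]).*", "\\1", name[!nzchar(elem)])
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  b <- as.numeric(substr(at, 61, 66))
  atoms <- data.frame(
    label = paste0(name, "_", seq_along(at)), element = elem,
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occ = pmin(as.numeric(substr(at, 55, 60)), 1),
    u_iso = b / (8 * pi^2),
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u23 = NA_real_, u13 = NA_real_, u12 = NA_real_,
    stringsAsFactors = FALSE)

  orthogonal <- all(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) < 1e-6)
  anis <- lines[startsWith(lines, "ANISOU")]
  if (length(anis) > 0 && orthogonal) {
    serial_at <- as.integer(substr(at, 7, 11))
    serial_an <- as.integer(substr(anis, 7, 11))
    idx <- match(serial_an, serial_at)
    get <- function(a, b) as.numeric(substr(anis, a, b)) / 1e4
    atoms$u11[idx] <- get(29, 35); atoms$u22[idx] <- get(36, 42)
    atoms$u33[idx] <- get(43, 49); atoms$u12[idx] <- get(50, 56)
    atoms$u13[idx] <- get(57, 63); atoms$u23[idx] <- get(64, 70)
  } else if (length(anis) > 0) {
    warning("ANISOU records ignored for a non-orthogonal cell; using U_iso")
  }
  crystal_model(cell, atoms, ops, space_group = if (nzchar(sg)) sg else "P 1")
}
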