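#' Build a small-molecule structure model
#'
#' @param atoms data frame with columns `element`, `label`, `ligand`
#'   (chelating-ligand id or NA), `x`, `y`, `z` (Angstrom).
#' @param provenance free-text origin (file name, "generated", ...).
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, provenance = "constructed") {
  need <- c("element", "label", "ligand", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms (%s)\n",
              nrow(x$atoms), x$provenance))
  print(table(x$atoms$element))
  invisible(x)
}

#' Read an XYZ coordinate file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records.
#' Labels are `element` + per-element index; ligand ids are not encoded
#' in XYZ and are left NA (see [find_coordination()] for id-free
#' pairing).
#'
#' @param path XYZ file.
#' @return A `structure_model`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file")
  fields <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  if (any(lengths(fields) < 4)) stop("malformed XYZ atom record")
  el <- vapply(fields, `[`, "", 1)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-finite coordinate in XYZ file")
  atoms <- data.frame(
    element = el,
    label = paste0(el, ave(seq_along(el), el, FUN = seq_along)),
    ligand = NA_character_,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  structure_model(atoms, provenance = paste0("xyz:", path))
}

#' Write a structure model to XYZ
#' @param s a `structure_model`.
#' @param path output file.
#' @param comment comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(s, path, comment = "") {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms
  writeLines(c(
    as.character(nrow(a)), comment,
    sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z)
  ), path)
  invisible(path)
}

# Orthogonalisation matrix from unit-cell parameters (a along x,
# b in the xy plane; standard crystallographic convention).
cell_orth_matrix <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(a, b * cg, c * cb,
           0, b * sg, c * (ca - cb * cg) / sg,
           0, 0, c * v / sg), nrow = 3, byrow = TRUE)
}

#' Read a minimal small-molecule CIF
#'
#' Parses the unit cell (`_cell_length_*`, `_cell_angle_*`) and the
#' `_atom_site` loop. Fractional coordinates are orthogonalised through
#' the cell; Cartesian (`_atom_site_Cartn_*`) columns are taken as-is.
#' Only the fields needed for coordination geometry are read; symmetry
#' expansion, disorder and anisotropic displacement are out of scope.
#' Ligand ids are taken from a residue/component field when present
#' (`_atom_site_disorder_group` is not used for this).
#'
#' @param path CIF file.
#' @return A `structure_model`.
#' @export
read_cif_min <- function(path) {
  lines <- readLines(path)
  stripped <- trimws(lines)
  getnum <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), stripped, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    val <- strsplit(ln[1], "\\s+")[[1]][2]
    as.numeric(sub("\\(.*\\)", "", val)) # strip s.u. parentheses
  }
  # locate the _atom_site loop
  loop_starts <- grep("^loop_", stripped)
  atoms <- NULL
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character()
    while (i <= length(stripped) && startsWith(stripped[i], "_")) {
      tags <- c(tags, strsplit(stripped[i], "\\s+")[[1]][1])
      i <- i + 1
    }
    if (!any(grepl("^_atom_site[._]", tags))) next
    rows <- list()
    while (i <= length(stripped) && nzchar(stripped[i]) &&
           !startsWith(stripped[i], "_") &&
           !startsWith(stripped[i], "loop_") &&
           !startsWith(stripped[i], "#")) {
      f <- strsplit(stripped[i], "\\s+")[[1]]
      if (length(f) == length(tags)) rows[[length(rows) + 1]] <- f
      i <- i + 1
    }
    if (length(rows) == 0) next
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- tags
    atoms <- tab
    break
  }
  if (is.null(atoms)) stop("no _atom_site loop found")
  pick <- function(...) {
    for (t in c(...)) if (t %in% names(atoms)) return(atoms[[t]])
    NULL
  }
  label <- pick("_atom_site_label", "_atom_site.label_atom_id")
  symbol <- pick("_atom_site_type_symbol", "_atom_site.type_symbol")
  if (is.null(symbol)) symbol <- gsub("[0-9'].*$", "", label)
  ligand <- pick("_atom_site.auth_comp_id", "_atom_site_residue_id")
  fx <- pick("_atom_site_fract_x", "_atom_site.fract_x")
  if (!is.null(fx)) {
    cell <- c(a = getnum("_cell_length_a"), b = getnum("_cell_length_b"),
              c = getnum("_cell_length_c"),
              alpha = getnum("_cell_angle_alpha"),
              beta = getnum("_cell_angle_beta"),
              gamma = getnum("_cell_angle_gamma"))
    if (any(is.na(cell))) {
      stop("fractional coordinates but incomplete cell parameters")
    }
    frac <- rbind(
      as.numeric(sub("\\(.*\\)", "", fx)),
      as.numeric(sub("\\(.*\\)", "",
                     pick("_atom_site_fract_y", "_atom_site.fract_y"))),
      as.numeric(sub("\\(.*\\)", "",
                     pick("_atom_site_fract_z", "_atom_site.fract_z")))
    )
    xyz <- t(cell_orth_matrix(cell["a"], cell["b"], cell["c"],
                              cell["alpha"], cell["beta"],
                              cell["gamma"]) %*% frac)
  } else {
    xyz <- cbind(
      as.numeric(pick("_atom_site_Cartn_x", "_atom_site.Cartn_x")),
      as.numeric(pick("_atom_site_Cartn_y", "_atom_site.Cartn_y")),
      as.numeric(pick("_atom_site_Cartn_z", "_atom_site.Cartn_z"))
    )
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinate in CIF file")
  structure_model(
    data.frame(element = symbol, label = label,
               ligand = if (is.null(ligand)) NA_character_ else ligand,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    provenance = paste0("cif:", path)
  )
}

#' Load coordinates from XYZ or minimal CIF
#' @param path coordinate file.
#' @param format `"auto"` (by extension), `"xyz"` or `"cif"`.
#' @return A `structure_model`.
#' @export
load_structure <- function(path, format = c("auto", "xyz", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif"
              else "xyz"
  }
  switch(format, xyz = read_xyz(path), cif = read_cif_min(path))
}

#' Generate an ideal bis-chelate coordination model
#'
#' One metal centre at the origin with two bidentate N-donor ligands:
#' each donor pair subtends the requested bite angle at the metal at
#' distance `bond_len`, and the two three-atom chelate planes
#' (metal + donor pair) meet at the requested dihedral. A dihedral of
#' 90 degrees is the ideal tetrahedral bis-chelate; 0 is square planar.
#' The construction is exact, so [chelate_geometry()] recovers the
#' inputs to numerical precision.
#'
#' @param bite_deg donor-metal-donor angle within one ligand, degrees,
#'   in (0, 180).
#' @param dihedral_deg angle between the two chelate planes, degrees,
#'   in [0, 90].
#' @param bond_len metal-donor distance, Angstrom.
#' @return A `structure_model` (Cu + N1..N4, ligands L1/L2).
#' @export
gen_bischelate <- function(bite_deg, dihedral_deg, bond_len = 2.05) {
  if (bite_deg <= 0 || bite_deg >= 180) stop("bite_deg must be in (0, 180)")
  if (dihedral_deg < 0 || dihedral_deg > 90) {
    stop("dihedral_deg must be in [0, 90]")
  }
  if (bond_len <= 0) stop("bond_len must be > 0")
  h <- bite_deg / 2 * pi / 180
  th <- dihedral_deg * pi / 180
  r <- bond_len
  # ligand 1 in the z = 0 plane, bisector +x; ligand 2 bisector -x with
  # its in-plane axis rotated by the dihedral about x
  atoms <- data.frame(
    element = c("Cu", "N", "N", "N", "N"),
    label = c("Cu1", "N1", "N2", "N3", "N4"),
    ligand = c(NA, "L1", "L1", "L2", "L2"),
    x = c(0, r * cos(h), r * cos(h), -r * cos(h), -r * cos(h)),
    y = c(0, r * sin(h), -r * sin(h),
          r * sin(h) * cos(th), -r * sin(h) * cos(th)),
    z = c(0, 0, 0, r * sin(h) * sin(th), -r * sin(h) * sin(th)),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, provenance = sprintf(
    "generated bis-chelate (bite %.6g, dihedral %.6g, r %.6g)",
    bite_deg, dihedral_deg, bond_len))
}

#' Assign donor atoms to chelating ligand pairs around each metal centre
#'
#' Donors within `cutoff` of a centre are collected; centres with
#' exactly four donors are split into two bidentate pairs, using ligand
#' ids when every donor carries one, otherwise by exhaustive enumeration
#' of the three pairings of four donors, minimising the summed
#' within-pair donor-donor distance (chelating donors are held close by
#' the ligand backbone). Centres without exactly four donors are
#' reported as skipped.
#'
#' @param s a `structure_model`.
#' @param center,donor element symbols (defaults Cu, N).
#' @param cutoff bonding distance cutoff, Angstrom (default 2.5).
#' @return A `coordination_assignment` list with one entry per centre:
#'   `center_label`, `center`, `donors` (data frame), `pairs` (list of
#'   two index pairs into `donors`) or NULL with a `skip_reason`.
#' @export
find_coordination <- function(s, center = "Cu", donor = "N",
                              cutoff = 2.5) {
  stopifnot(inherits(s, "structure_model"))
  a <- s$atoms
  centers <- which(a$element == center)
  if (length(centers) == 0) stop("no ", center, " centre in structure")
  donors_all <- which(a$element == donor)
  out <- list()
  for (ci in centers) {
    cx <- as.numeric(a[ci, c("x", "y", "z")])
    d <- sqrt(colSums((t(as.matrix(a[donors_all, c("x", "y", "z")])) -
                         cx)^2))
    near <- donors_all[d <= cutoff]
    entry <- list(center_label = a$label[ci], center = cx,
                  donors = a[near, , drop = FALSE], pairs = NULL,
                  skip_reason = NULL)
    if (length(near) != 4) {
      entry$skip_reason <- sprintf("%d donor(s) within cutoff, need 4",
                                   length(near))
    } else {
      lig <- a$ligand[near]
      if (!anyNA(lig) && length(unique(lig)) == 2 &&
          all(table(lig) == 2)) {
        u <- unique(lig)
        entry$pairs <- list(which(lig == u[1]), which(lig == u[2]))
      } else {
        xyz <- as.matrix(a[near, c("x", "y", "z")])
        pairings <- list(list(c(1, 2), c(3, 4)),
                         list(c(1, 3), c(2, 4)),
                         list(c(1, 4), c(2, 3)))
        cost <- vapply(pairings, function(p) {
          sum(vapply(p, function(ij) {
            sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2))
          }, 0))
        }, 0)
        entry$pairs <- pairings[[which.min(cost)]]
      }
    }
    out[[length(out) + 1]] <- entry
  }
  structure(out, class = "coordination_assignment")
}

# Angle in degrees between two 3-vectors, with a clamped arc-cosine.
vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Bite angles and chelate-plane dihedral of bis-chelate complexes
#'
#' For each assigned metal centre: the bite angle of each ligand is the
#' donor-metal-donor angle of its pair; each chelate plane is defined
#' exactly by the three atoms metal, donor, donor (normal = cross
#' product of the two metal-donor vectors); the dihedral between the
#' two planes is the angle between the normals folded into [0, 90]
#' degrees, which makes the report independent of normal orientation.
#'
#' @param x a `structure_model` (coordination is assigned with default
#'   [find_coordination()] settings) or a `coordination_assignment`.
#' @param ... passed to [find_coordination()] when `x` is a structure.
#' @return A `chelate_geometry` data frame, one row per complex:
#'   `center`, `bite1`, `bite2`, `mean_bite`, `dihedral`, `cu_n_min`,
#'   `cu_n_max`; attributes `mean_bite` and `mean_dihedral` average over
#'   complexes. Skipped centres are dropped with a warning.
#' @export
chelate_geometry <- function(x, ...) {
  assign <- if (inherits(x, "structure_model")) {
    find_coordination(x, ...)
  } else x
  stopifnot(inherits(assign, "coordination_assignment"))
  rows <- list()
  for (entry in assign) {
    if (is.null(entry$pairs)) {
      warning("skipping centre ", entry$center_label, ": ",
              entry$skip_reason)
      next
    }
    xyz <- as.matrix(entry$donors[, c("x", "y", "z")])
    cu <- entry$center
    bites <- numeric(2); normals <- vector("list", 2); dists <- numeric(0)
    for (k in 1:2) {
      v1 <- xyz[entry$pairs[[k]][1], ] - cu
      v2 <- xyz[entry$pairs[[k]][2], ] - cu
      bites[k] <- vec_angle_deg(v1, v2)
      nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      if (sqrt(sum(nrm^2)) < 1e-9 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
        stop("collinear metal-donor-donor triple: chelate plane undefined")
      }
      normals[[k]] <- nrm
      dists <- c(dists, sqrt(sum(v1^2)), sqrt(sum(v2^2)))
    }
    ang <- vec_angle_deg(normals[[1]], normals[[2]])
    dihedral <- min(ang, 180 - ang) # fold: plane orientation is arbitrary
    rows[[length(rows) + 1]] <- data.frame(
      center = entry$center_label,
      bite1 = bites[1], bite2 = bites[2], mean_bite = mean(bites),
      dihedral = dihedral,
      cu_n_min = min(dists), cu_n_max = max(dists),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no complete 4-donor centre to analyse")
  out <- do.call(rbind, rows)
  attr(out, "mean_bite") <- mean(c(out$bite1, out$bite2))
  attr(out, "mean_dihedral") <- mean(out$dihedral)
  class(out) <- c("chelate_geometry", "data.frame")
  out
}

#' @export
print.chelate_geometry <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 1) # display to nearest 0.1 degree
  print(df)
  cat(sprintf("mean bite %.1f deg, mean dihedral %.1f deg over %d complex(es)\n",
              attr(x, "mean_bite"), attr(x, "mean_dihedral"), nrow(x)))
  invisible(x)
}
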