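random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

test_that("XYZ files round-trip and reject bad records", {
  s <- gen_bischelate(81, 82.8)
  s$atoms <- rbind(s$atoms,
                   data.frame(element = "C", label = paste0("C", 1:4),
                              ligand = NA, x = 3:6, y = 0, z = 0))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, path, comment = "bis-chelate plus carbons")
  back <- read_xyz(path)
  expect_identical(nrow(back$atoms), 9L)
  expect_identical(back$atoms$element, s$atoms$element)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-7, ignore_attr = TRUE)

  writeLines(c("2", "bad", "Cu 0 0 0", "N NaN 0 0"), path)
  expect_error(read_xyz(path), "non-finite")
})

test_that("minimal CIF parsing orthogonalises fractional coordinates", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_synthetic_test",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "_cell_angle_alpha 90.0",
    "_cell_angle_beta 90.0",
    "_cell_angle_gamma 90.0",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "Cu1 Cu 0.5 0.5 0.5",
    "N1 N 0.6 0.5 0.5"
  ), path)
  s <- load_structure(path)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")]), c(x = 5, y = 5, z = 5))
  expect_equal(s$atoms$x[2], 6)
  expect_identical(s$atoms$element, c("Cu", "N"))

  # missing cell parameters with fractional coordinates is an error
  writeLines(c(
    "data_bad", "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "Cu1 Cu 0.5 0.5 0.5"
  ), path)
  expect_error(read_cif_min(path), "cell parameters")
})

test_that("bite angles and plane dihedrals match hand constructions", {
  # right-angle donor pair: N(2,0,0), Cu(0,0,0), N(0,2,0)
  s <- structure_model(data.frame(
    element = c("Cu", "N", "N", "N", "N"),
    label = c("Cu1", "N1", "N2", "N3", "N4"),
    ligand = c(NA, "a", "a", "b", "b"),
    x = c(0, 2, 0, -2, 0), y = c(0, 0, 2, 0, 0), z = c(0, 0, 0, 0, -2)
  ))
  g <- chelate_geometry(s)
  expect_equal(g$bite1, 90)
  expect_equal(g$bite2, 90)

  expect_equal(chelate_geometry(gen_bischelate(90, 90))$dihedral, 90,
               tolerance = 1e-9)
  expect_equal(chelate_geometry(gen_bischelate(90, 0))$dihedral, 0,
               tolerance = 1e-9)
})

test_that("generator and geometry close a round trip across a grid", {
  for (bite in c(60, 81, 90, 120)) {
    for (dih in c(0, 30, 82.8, 90)) {
      g <- chelate_geometry(gen_bischelate(bite, dih))
      expect_lt(abs(g$bite1 - bite), 1e-6)
      expect_lt(abs(g$bite2 - bite), 1e-6)
      expect_lt(abs(g$dihedral - dih), 1e-6)
    }
  }
  expect_error(gen_bischelate(0, 45), "bite")
  expect_error(gen_bischelate(90, 120), "dihedral")
})

test_that("geometry is invariant under rigid motions", {
  set.seed(4)
  s <- gen_bischelate(81, 82.8)
  g0 <- chelate_geometry(s)
  for (i in 1:5) {
    s2 <- apply_rigid(s, random_rotation(), rnorm(3, sd = 10))
    g <- chelate_geometry(s2)
    expect_lt(abs(g$mean_bite - g0$mean_bite), 1e-9)
    expect_lt(abs(g$dihedral - g0$dihedral), 1e-9)
  }
})

test_that("donor pairing without ligand ids matches a brute-force oracle", {
  # exhaustive oracle over the three pairings of four donors
  oracle_pairing <- function(xyz) {
    pairings <- list(list(c(1, 2), c(3, 4)),
                     list(c(1, 3), c(2, 4)),
                     list(c(1, 4), c(2, 3)))
    cost <- vapply(pairings, function(p) {
      sum(vapply(p, function(ij) {
        sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2))
      }, 0))
    }, 0)
    pairings[[which.min(cost)]]
  }
  set.seed(9)
  for (i in 1:10) {
    s <- gen_bischelate(runif(1, 60, 100), runif(1, 20, 90))
    s$atoms$ligand <- NA_character_
    assign <- find_coordination(s)[[1]]
    want <- oracle_pairing(as.matrix(assign$donors[, c("x", "y", "z")]))
    norm <- function(p) sort(vapply(p, function(ij) {
      paste(sort(ij), collapse = "-")
    }, ""))
    expect_identical(norm(assign$pairs), norm(want))
  }
  # for a typical cuprous bis-diimine (tight bite, near-tetrahedral
  # twist) the distance pairing recovers the true ligands
  for (i in 1:5) {
    s <- gen_bischelate(runif(1, 70, 90), runif(1, 60, 90))
    with_ids <- chelate_geometry(s)
    s$atoms$ligand <- NA_character_
    no_ids <- chelate_geometry(s)
    expect_equal(no_ids$mean_bite, with_ids$mean_bite, tolerance = 1e-9)
    expect_equal(no_ids$dihedral, with_ids$dihedral, tolerance = 1e-9)
  }
})

test_that("coordination assignment respects the distance cutoff", {
  s <- gen_bischelate(81, 82.8, bond_len = 2.0)
  # push one donor just outside the default 2.5 A cutoff
  far <- s
  v <- unlist(far$atoms[2, c("x", "y", "z")])
  far$atoms[2, c("x", "y", "z")] <- as.list(v * 2.6 / 2.0)
  assign <- find_coordination(far)
  expect_identical(nrow(assign[[1]]$donors), 3L)
  expect_match(assign[[1]]$skip_reason, "need 4")
  expect_warning(expect_error(chelate_geometry(far), "no complete"),
                 "skipping")

  # collinear metal-donor-donor triple has no defined plane
  lin <- structure_model(data.frame(
    element = c("Cu", "N", "N", "N", "N"),
    label = c("Cu1", "N1", "N2", "N3", "N4"),
    ligand = c(NA, "a", "a", "b", "b"),
    x = c(0, 1, 2, -1, -1), y = c(0, 0, 0, 1, -1), z = 0
  ))
  expect_error(chelate_geometry(lin), "collinear")
})

test_that("multi-complex structures report per-complex and mean values", {
  a <- gen_bischelate(81, 82.8)
  b <- gen_bischelate(85, 75)
  b$atoms$label <- paste0(b$atoms$label, "b")
  b$atoms$ligand <- ifelse(is.na(b$atoms$ligand), NA, paste0(b$atoms$ligand, "b"))
  b$atoms$x <- b$atoms$x + 50 # well separated
  both <- structure_model(rbind(a$atoms, b$atoms))
  g <- chelate_geometry(both)
  expect_identical(nrow(g), 2L)
  expect_equal(sort(g$mean_bite), c(81, 85), tolerance = 1e-9)
  expect_equal(attr(g, "mean_dihedral"), mean(c(82.8, 75)),
               tolerance = 1e-9)
})
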