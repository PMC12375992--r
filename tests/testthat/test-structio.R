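test_that("PDB parsing reads models, residues and confidence", {
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  ens <- read_structure(text = minimal_pdb(xyz))
  expect_equal(nrow(ens), 1)
  expect_equal(nrow(ens$residues[[1]]), 2)
  expect_equal(ens$residues[[1]]$aa, c("A", "A"))

  # three MODEL blocks -> ensemble of three
  block <- minimal_pdb(xyz)
  multi <- paste0(
    "MODEL        1\n", block, "\nENDMDL\n",
    "MODEL        2\n", block, "\nENDMDL\n",
    "MODEL        3\n", block, "\nENDMDL\nEND"
  )
  ens3 <- read_structure(text = multi)
  expect_equal(ens3$model_index, 1:3)

  # temperature factor column is stored as confidence
  conf <- read_structure(text = minimal_pdb(xyz, bfactor = c(92.5, 30)))
  expect_equal(conf$residues[[1]]$confidence, c(92.5, 30))
})

test_that("PDB parse errors are explicit", {
  expect_error(read_structure(text = "HEADER    NOTHING"), "no ATOM records")
  bad <- "ATOM      1  CA  ALA A   1      xxx.000   0.000   0.000  1.00  0.00           C"
  expect_error(read_structure(text = bad), "line 1")
})

test_that("alternate locations resolve to highest occupancy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 20.00           C"
  )
  ens <- read_structure(text = paste(lines, collapse = "\n"))
  expect_equal(nrow(ens$residues[[1]]), 1)
  expect_equal(ens$residues[[1]]$x, 5.0)
})

test_that("structure write-read round trip preserves coordinates and agrees with bio3d", {
  cs <- synth_canonical_structure()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cs, f)
  back <- model_residues(read_structure(f))
  expect_equal(back$x, cs$x, tolerance = 1e-3)
  expect_equal(back$aa, cs$aa)
  expect_equal(back$sg_x, cs$sg_x, tolerance = 1e-3)

  # independent reader cross-check
  skip_if_not_installed("bio3d")
  b <- bio3d::read.pdb(f)
  ca <- b$atom[b$atom$elety == "CA", ]
  expect_equal(nrow(ca), nrow(cs))
  expect_equal(ca$x, cs$x, tolerance = 1e-3)
  expect_equal(unname(AA_THREE_TO_ONE[ca$resid]), cs$aa)
})

test_that("disulfide detection pairs sulfurs under the covalent cutoff", {
  two_cys <- function(gap) {
    r <- make_residues(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                             c(30, 0, 0)),
                       aa = c("C", "A", "A", "C"))
    r$sg_x[1] <- 0; r$sg_y[1] <- 5; r$sg_z[1] <- 0
    r$sg_x[4] <- gap; r$sg_y[4] <- 5; r$sg_z[4] <- 0
    r
  }
  close_pair <- detect_disulfides(two_cys(2.04))
  expect_equal(nrow(close_pair$bonds), 1)
  expect_equal(close_pair$bonds$distance, 2.04, tolerance = 1e-9)
  expect_length(close_pair$free_cys, 0)

  far_pair <- detect_disulfides(two_cys(3.5))
  expect_equal(nrow(far_pair$bonds), 0)
  expect_equal(far_pair$free_cys, c(1L, 2L))
})

test_that("the synthetic canonical structure yields 4 bonds matching the canonical topology", {
  cs <- synth_canonical_structure()
  top <- detect_disulfides(cs)
  expect_equal(nrow(top$bonds), 4)
  expect_true(top$canonical_match)
  got <- purrr::map2(top$bonds$ordinal_i, top$bonds$ordinal_j, c)
  expect_setequal(got, list(c(1L, 6L), c(2L, 5L), c(3L, 4L), c(7L, 8L)))
  expect_equal(glance(top)$n_bonds, 4)
  expect_equal(nrow(tidy(top)), 4)
})

test_that("disulfide topology is invariant under rigid motion", {
  cs <- synth_canonical_structure()
  rot <- rotation_about_axis(c(1, 2, 3), 37 * pi / 180)
  moved <- hydrophobinr:::apply_rigid(cs, rot, c(5, -3, 12))
  top <- detect_disulfides(moved)
  expect_equal(nrow(top$bonds), 4)
  expect_true(top$canonical_match)
  expect_equal(top$bonds$distance, detect_disulfides(cs)$bonds$distance,
               tolerance = 1e-9)
})

test_that("non-canonical bonds are mapped onto the canonical pattern", {
  cs <- synth_canonical_structure()
  # swap the SG coordinates of C1 and C2: bonds become C2-C6 and C1-C5
  swapped <- cs
  cys <- which(cs$aa == "C")
  for (col in c("sg_x", "sg_y", "sg_z")) {
    tmp <- swapped[[col]][cys[1]]
    swapped[[col]][cys[1]] <- swapped[[col]][cys[2]]
    swapped[[col]][cys[2]] <- tmp
  }
  top <- detect_disulfides(swapped, reference = cs)
  expect_false(top$canonical_match)
  expect_false(is.null(top$mapping_to_canonical))
  mp <- top$mapping_to_canonical
  expect_equal(mp$maps_to[mp$bond == "C2-C6"], "C1-C6")
  expect_equal(mp$maps_to[mp$bond == "C1-C5"], "C2-C5")
})

test_that("SASA matches the analytic sphere and handles burial", {
  atom <- tibble::tibble(resno = 1, atom = "CA", element = "C",
                         x = 0, y = 0, z = 0)
  s <- shrake_rupley_sasa(atom)
  expect_equal(s$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # exactly coincident duplicate contributes nothing extra
  dup <- dplyr::bind_rows(atom, atom)
  expect_equal(shrake_rupley_sasa(dup)$total, s$total, tolerance = 1e-9)

  # an atom enclosed in a dense shell is buried
  sphere <- hydrophobinr:::fibonacci_sphere(200) * 3.5
  shell <- tibble::tibble(
    resno = 2, atom = "CA", element = "C",
    x = sphere[, 1], y = sphere[, 2], z = sphere[, 3]
  )
  buried <- shrake_rupley_sasa(dplyr::bind_rows(atom, shell))
  expect_lt(buried$per_residue$area[buried$per_residue$resno == 1], 1)
})

test_that("SASA is rigid-motion invariant and quadrature-stable", {
  cs <- synth_canonical_structure()
  atoms <- residues_as_atoms(cs)
  s1 <- shrake_rupley_sasa(atoms, n_points = 960)
  rot <- rotation_about_axis(c(0, 1, 1), 1.1)
  moved <- hydrophobinr:::apply_rigid(cs, rot, c(-4, 8, 2))
  s2 <- shrake_rupley_sasa(residues_as_atoms(moved), n_points = 960)
  expect_equal(s2$total, s1$total, tolerance = 0.005)

  s_half <- shrake_rupley_sasa(atoms, n_points = 480)
  expect_lt(abs(s_half$total - s1$total) / s1$total, 0.02)

  # unknown elements fall back with a warning, not an error
  odd <- atoms
  odd$element[1] <- "Q"
  expect_warning(shrake_rupley_sasa(odd, n_points = 60), "default radius")
})
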