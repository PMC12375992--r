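test_that("Kabsch superposition recovers identity and rigid motions", {
  xyz <- coords_of(helix_template(20))
  fit0 <- kabsch_superpose(xyz, xyz)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  rot <- rotation_about_axis(c(1, -1, 2), 37 * pi / 180)
  moved <- xyz %*% t(rot) + matrix(c(4, -7, 2), nrow(xyz), 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, xyz)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(xyz[1:2, ], xyz[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch is optimal against a brute-force rotation-grid oracle", {
  # oracle: exhaustive search over an Euler-angle grid, centred point sets
  grid_rmsd <- function(mobile, reference, step = pi / 18) {
    a <- sweep(mobile, 2, colMeans(mobile))
    b <- sweep(reference, 2, colMeans(reference))
    angles <- seq(0, 2 * pi - step, by = step)
    half <- seq(0, pi, by = step)
    best <- Inf
    for (p in angles) for (t in half) for (s in angles) {
      rz1 <- rotation_about_axis(c(0, 0, 1), p)
      ry <- rotation_about_axis(c(0, 1, 0), t)
      rz2 <- rotation_about_axis(c(0, 0, 1), s)
      r <- rz2 %*% ry %*% rz1
      best <- min(best, sqrt(mean(rowSums((a %*% t(r) - b)^2))))
    }
    best
  }
  set.seed(5)
  for (rep in 1:2) {
    ref <- matrix(rnorm(30, sd = 5), 10, 3)
    mob <- ref + matrix(rnorm(30, sd = 1), 10, 3)
    kab <- kabsch_superpose(mob, ref)$rmsd
    oracle <- grid_rmsd(mob, ref)
    expect_lte(kab, oracle + 1e-9)  # grid can never beat the SVD optimum
    expect_lt(oracle - kab, 1.0)    # and agrees within the 10-degree grid
  }
})

test_that("TM-score is 1 for identical structures and follows the d0 formula", {
  t1 <- helix_template(50)
  expect_equal(tm_score(t1, t1)$tm_score, 1.0, tolerance = 1e-9)
  expect_equal(tm_score(t1, t1)$d0, max(0.5, 1.24 * (50 - 15)^(1 / 3) - 1.8))

  # short chains floor d0 at 0.5
  t_short <- helix_template(12)
  expect_equal(tm_score(t_short, t_short)$d0, 0.5)

  # every distance exactly d0 gives 0.5 by the formula
  lref <- 40
  d0 <- max(0.5, 1.24 * (lref - 15)^(1 / 3) - 1.8)
  expect_equal(sum(1 / (1 + (rep(d0, lref) / d0)^2)) / lref, 0.5)

  expect_error(tm_score(helix_template(10)[1:2, ], helix_template(10)[1:2, ]),
               "3 corresponding")
})

test_that("TM-score decreases strictly with coordinate noise", {
  t1 <- helix_template(60)
  tms <- purrr::map_dbl(c(0.5, 1, 2, 4), function(s) {
    p <- synth_structure_pair(t1, noise_sd = s, seed = 99)
    tm_score(p$perturbed$residues[[1]], t1)$tm_score
  })
  expect_true(all(diff(tms) < 0))
})

test_that("lDDT-Calpha implements the four-threshold preserved-distance logic", {
  t1 <- helix_template(40)
  expect_equal(lddt_ca(t1, t1), 1.0)

  # all qualifying distances off by exactly 3 A: only the 4 A threshold holds
  expect_equal(lddt_ca(triangle_residues(10), triangle_residues(7)), 0.25)
  # off by 10 A: nothing is preserved
  expect_equal(lddt_ca(triangle_residues(17), triangle_residues(7)), 0)
  # superposition-free: independent rigid motions change nothing
  rotA <- rotation_about_axis(c(1, 0, 0), 1.0)
  rotB <- rotation_about_axis(c(0, 1, 0), 2.2)
  p <- synth_structure_pair(t1, noise_sd = 1, seed = 12)$perturbed$residues[[1]]
  base <- lddt_ca(p, t1)
  movedA <- hydrophobinr:::apply_rigid(p, rotA, c(3, 3, 3))
  movedB <- hydrophobinr:::apply_rigid(t1, rotB, c(-9, 0, 4))
  expect_equal(lddt_ca(movedA, movedB), base, tolerance = 1e-9)

  # no qualifying pairs within 15 A is an error
  sparse <- make_residues(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)))
  expect_error(lddt_ca(sparse, sparse), "inclusion radius")
})

test_that("all three metrics are invariant under a common rigid motion", {
  t1 <- helix_template(45)
  p <- synth_structure_pair(t1, noise_sd = 1.5, seed = 31)$perturbed$residues[[1]]
  rot <- rotation_about_axis(c(2, 1, 0), 0.8)
  p2 <- hydrophobinr:::apply_rigid(p, rot, c(1, 2, 3))
  t2 <- hydrophobinr:::apply_rigid(t1, rot, c(1, 2, 3))
  pairing <- pair_residues(p, t1)
  expect_equal(
    kabsch_superpose(coords_of(p2), coords_of(t2))$rmsd,
    kabsch_superpose(coords_of(p), coords_of(t1))$rmsd,
    tolerance = 1e-9
  )
  expect_equal(tm_score(p2, t2, pairing)$tm_score,
               tm_score(p, t1, pairing)$tm_score, tolerance = 1e-6)
  expect_equal(lddt_ca(p2, t2, pairing), lddt_ca(p, t1, pairing),
               tolerance = 1e-9)
})

test_that("sequence-based pairing aligns unequal chains", {
  t1 <- helix_template(30, aa = strsplit("ACDEFGHIKLMNPQRSTVWYACDEFGHIKL", "")[[1]])
  t2 <- t1[c(1:10, 16:30), ]  # drop 5 residues
  pairing <- pair_residues(t2, t1)
  expect_equal(nrow(pairing), 25)
  expect_equal(pairing$idx_ref, c(1:10, 16:30))
  res <- benchmark_model(t2, t1)
  expect_equal(res$n_aligned, 25)
  expect_lt(res$rmsd, 1e-6)
})

test_that("benchmarking chooses the ensemble member with lowest RMSD", {
  t1 <- helix_template(40)
  noisy1 <- synth_structure_pair(t1, noise_sd = 2, seed = 1)$perturbed$residues[[1]]
  noisy2 <- synth_structure_pair(t1, noise_sd = 3, seed = 2)$perturbed$residues[[1]]
  ensemble <- list(noisy1, t1, noisy2)  # member 2 is the predicted itself
  res <- benchmark_model(t1, ensemble)
  expect_equal(res$chosen_model_index, 2L)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(res$tm_score, 1, tolerance = 1e-9)
  expect_equal(res$lddt_ca, 1, tolerance = 1e-9)
  expect_true(all(res$rmsd_good, res$lddt_good, res$tm_good))

  # rigidly moved copy still scores perfectly
  moved <- hydrophobinr:::apply_rigid(t1, rotation_about_axis(c(1, 1, 1), 1), c(8, 8, 8))
  res2 <- benchmark_model(moved, t1)
  expect_lt(res2$rmsd, 1e-6)
  expect_true(all(res2$rmsd_good, res2$lddt_good, res2$tm_good))

  # single-member ensembles reduce to the bare metrics
  pairing <- pair_residues(noisy1, t1)
  single <- benchmark_model(noisy1, t1)
  expect_equal(single$rmsd,
               kabsch_superpose(coords_of(noisy1), coords_of(t1))$rmsd)
  expect_equal(single$tm_score, tm_score(noisy1, t1, pairing)$tm_score)
  expect_equal(single$lddt_ca, lddt_ca(noisy1, t1, pairing))

  expect_error(benchmark_model(t1, list()), "empty")
})

test_that("batch benchmarking summarises per class", {
  t1 <- helix_template(40)
  t2 <- helix_template(48, wobble_amp = 6)
  mk <- function(tmpl, s, seed) {
    synth_structure_pair(tmpl, noise_sd = s, seed = seed)$perturbed$residues[[1]]
  }
  pairs <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    predicted = list(mk(t1, 0.5, 1), mk(t1, 0.8, 2), mk(t2, 0.5, 3), mk(t2, 0.8, 4)),
    experimental = list(t1, t1, t2, t2),
    class_label = c("class_I", "class_I", "class_II", "class_II")
  )
  res <- benchmark_models(pairs)
  expect_equal(nrow(res), 4)
  summ <- summarise_benchmark(res)
  expect_equal(sort(summ$class_label), c("class_I", "class_II"))
  expect_equal(summ$n, c(2L, 2L))
  expect_true(all(summ$rmsd_mean > 0))
  expect_true(all(summ$frac_tm_good == 1))
})
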