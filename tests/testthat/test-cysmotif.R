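test_that("the EAS octet motif is found with its loops and doublets", {
  m <- scan_cys_motif(EAS)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_cys, 8L)
  expect_equal(m$positions[[1]], c(10L, 19L, 20L, 31L, 40L, 46L, 47L, 66L))
  expect_equal(m$spacing[[1]], c(8L, 0L, 10L, 8L, 5L, 0L, 18L))
  expect_equal(m$doublets[[1]], list(c(2L, 3L), c(6L, 7L)))

  loops <- m$loops[[1]]
  l78 <- loops[loops$loop == "C7-C8", ]
  expect_equal(l78$start, 48L)
  expect_equal(l78$end, 65L)
  # the aggregation segment FLIIN sits inside the C7-C8 loop
  expect_true(grepl("FLIIN", l78$subsequence))
  expect_equal(as.integer(regexpr("FLIIN", EAS)), 58L)
})

test_that("motif scan handles absent, shifted and repeated motifs", {
  # 7 cysteines cannot form the octet
  seven <- sub("C", "A", EAS)  # removes the first C
  expect_equal(nrow(scan_cys_motif(seven)), 0)

  # prepending k residues shifts positions by exactly k
  k <- 7L
  shifted <- scan_cys_motif(paste0(strrep("G", k), EAS))
  expect_equal(shifted$positions[[1]], scan_cys_motif(EAS)$positions[[1]] + k)

  # two motifs in a two-domain construction with a linker
  core <- substring(EAS, 10, 66)  # C1..C8 inclusive
  double <- paste0(core, strrep("G", 10), core)
  m2 <- scan_cys_motif(double)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$motif_index, c(1L, 2L))

  # spacing bounds are honoured: a 76-residue loop breaks the default scan
  wide <- paste0(core, strrep("A", 76), "C")
  expect_equal(nrow(scan_cys_motif(wide)), 1)
})

test_that("decet mode matches planted ten-cysteine variants", {
  gen <- synth_sequences(n = 6, n_ten_cys = 2, n_extended_tail = 0,
                         n_poly = 0, seed = 4)
  ten_ids <- gen$truth$id[gen$truth$feature == "ten_cys"]
  for (id in ten_ids) {
    s <- gen$sequences$residues[gen$sequences$id == id]
    m10 <- scan_cys_motif(s, decet = TRUE)
    expect_equal(m10$n_cys[1], 10L)
    expect_equal(length(m10$positions[[1]]), 10L)
  }
})

test_that("nearest-centroid classification assigns EAS to class I", {
  seqs <- read_fasta(text = paste0(">eas\n", EAS))
  cls <- classify_hydrophobin(seqs)
  expect_equal(cls$predicted_class, "class_I")
  expect_true(cls$motif_found)
  expect_gt(cls$confidence, 0)
})

test_that("classification recovers generated class labels and rejects non-hydrophobins", {
  gen <- synth_sequences(n = 80, n_ten_cys = 0, n_extended_tail = 0,
                         n_poly = 0, seed = 21)
  cls <- classify_hydrophobin(gen$sequences)
  hit <- cls$motif_found
  acc <- mean(cls$predicted_class[hit] ==
                gen$truth$class_label[match(cls$id[hit], gen$truth$id)])
  expect_gte(acc, 0.95)
  expect_gte(mean(hit), 0.95)

  none <- classify_hydrophobin(read_fasta(text = ">x\nAAAAGGGG"))
  expect_equal(none$predicted_class, "not_hydrophobin")
  expect_false(none$motif_found)
})

test_that("centroids can be regenerated from labelled data", {
  gen <- synth_sequences(n = 60, n_ten_cys = 0, n_extended_tail = 0,
                         n_poly = 0, seed = 8)
  ct <- spacing_centroids(gen$sequences)
  expect_equal(sort(ct$class_label), c("class_I", "class_II"))
  defaults <- default_spacing_centroids()
  for (cl in ct$class_label) {
    est <- ct$spacing[[which(ct$class_label == cl)]]
    ref <- defaults$spacing[[which(defaults$class_label == cl)]]
    expect_lt(sqrt(sum((est - ref)^2)), 3)  # near the generating means
  }
})

test_that("non-canonical mining applies the exact thresholds", {
  # 10 cysteines and length < 250 -> five-disulfide candidate
  gen <- synth_sequences(n = 4, n_ten_cys = 1, n_extended_tail = 1,
                         n_poly = 1, seed = 14)
  mine <- mine_noncanonical(gen$sequences)
  truth <- gen$truth
  m <- mine[match(truth$id, mine$id), ]
  expect_equal(m$five_disulfide_candidate, truth$feature == "ten_cys")
  expect_equal(m$extended_ntail, truth$feature == "extended_tail")
  expect_equal(m$polyhydrophobin, truth$feature == "polyhydrophobin")
  expect_equal(m$domain_label[truth$feature == "polyhydrophobin"],
               "trihydrophobin")
  expect_true(all(m$length[m$five_disulfide_candidate] < 250))
  expect_true(all(m$n_tail_length[m$extended_ntail] >= 70))

  # threshold edges: 69-residue tail is not extended, 70 is
  core <- substring(EAS, 10, 68)
  at69 <- read_fasta(text = paste0(">t69\n", strrep("A", 69), core))
  at70 <- read_fasta(text = paste0(">t70\n", strrep("A", 70), core))
  expect_false(mine_noncanonical(at69)$extended_ntail)
  expect_true(mine_noncanonical(at70)$extended_ntail)
  expect_equal(mine_noncanonical(at70)$n_tail_length, 70L)

  # EAS: 9-residue tail, 8 Cys, one domain, no flags
  eas_mine <- mine_noncanonical(read_fasta(text = paste0(">eas\n", EAS)))
  expect_equal(eas_mine$cys_count, 8L)
  expect_equal(eas_mine$domain_count, 1L)
  expect_equal(eas_mine$domain_label, "monohydrophobin")
  expect_false(any(eas_mine$five_disulfide_candidate,
                   eas_mine$extended_ntail, eas_mine$polyhydrophobin))
})

test_that("mining recovers all planted features exactly on the default corpus", {
  gen <- synth_sequences(seed = 2024)  # n=100: 10 ten-Cys, 10 tails, 5 tri
  mine <- mine_noncanonical(gen$sequences)
  truth <- gen$truth
  m <- mine[match(truth$id, mine$id), ]
  # precision = recall = 1 for each planted subset
  expect_equal(m$five_disulfide_candidate, truth$feature == "ten_cys")
  expect_equal(m$extended_ntail, truth$feature == "extended_tail")
  expect_equal(m$polyhydrophobin, truth$feature == "polyhydrophobin")
  expect_equal(sum(m$five_disulfide_candidate), 10L)
  expect_equal(sum(m$extended_ntail), 10L)
  expect_equal(sum(m$polyhydrophobin), 5L)
})

test_that("infeasible generator specs are rejected", {
  expect_error(synth_sequences(n = 5, n_ten_cys = 3, n_extended_tail = 3,
                               n_poly = 0, seed = 1), "infeasible")
  expect_error(synth_sequences(n = 10, poly_domains = 6, seed = 1),
               "infeasible")
})
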