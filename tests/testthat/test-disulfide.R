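test_that("disulphide detection windows and pairing behave as specified", {
  s <- toy_cystine()
  b <- detect_disulfides(s)
  expect_equal(nrow(b), 1)
  expect_equal(b$sg_distance, 2.05, tolerance = 1e-6)
  expect_equal(b$bond_id, "C1-C2")

  # pull the sulfurs 4 A apart: outside the window, no bond
  far <- s
  sg2 <- far$atoms$atom_name == "SG" & far$atoms$res_seq == 2
  sg1 <- far$atoms$atom_name == "SG" & far$atoms$res_seq == 1
  u <- atom_xyz(far$atoms[sg2, ]) - atom_xyz(far$atoms[sg1, ])
  u <- u / sqrt(sum(u^2))
  shift <- as.vector(u * (4.0 - 2.05))
  move <- far$atoms$res_seq == 2
  far$atoms$x[move] <- far$atoms$x[move] + shift[1]
  far$atoms$y[move] <- far$atoms$y[move] + shift[2]
  far$atoms$z[move] <- far$atoms$z[move] + shift[3]
  expect_equal(nrow(detect_disulfides(far)), 0)
})

test_that("chi measurement matches the torsions the builder prescribed, and mirrors negate", {
  # planar trans four-point check
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0)
  chi <- c(-60, -90, 100, -90, -60)
  s <- toy_cystine(chi)
  b <- detect_disulfides(s)
  m <- chi_angles(s, b[1, ])
  expect_equal(unname(m), chi, tolerance = 1e-6)
  mirror <- s
  mirror$atoms$z <- -mirror$atoms$z
  expect_equal(unname(chi_angles(mirror, b[1, ])), -chi, tolerance = 1e-6)
  # missing-atom contract
  s3 <- s
  s3$atoms <- s3$atoms[!(s3$atoms$atom_name == "CB" & s3$atoms$res_seq == 1), ]
  expect_error(chi_angles(s3, b[1, ]), class = "ssphot_missing_atoms_error")
  # cross-check the dihedral primitive against bio3d on the chi3 atom chain
  ch <- s$atoms[match(c("CB", "SG"), s$atoms$atom_name), ]
  ats <- dplyr::bind_rows(
    s$atoms[s$atoms$atom_name == "CB" & s$atoms$res_seq == 1, ],
    s$atoms[s$atoms$atom_name == "SG" & s$atoms$res_seq == 1, ],
    s$atoms[s$atoms$atom_name == "SG" & s$atoms$res_seq == 2, ],
    s$atoms[s$atoms$atom_name == "CB" & s$atoms$res_seq == 2, ])
  ref <- bio3d::torsion.xyz(as.vector(t(atom_xyz(ats))), atm.inc = 4)
  expect_equal(unname(m[["chi3"]]), ref[[1]], tolerance = 1e-6)
})

test_that("geometry classification follows the sign decision table", {
  expect_equal(classify_geometry(c(-60, -120, 100, -50, -70)), "-RHStaple")
  expect_equal(classify_geometry(c(-60, -80, -85, -80, -60)), "-LHSpiral")
  expect_equal(classify_geometry(c(60, 80, 85, 80, 60)), "+RHSpiral")
  expect_equal(classify_geometry(c(-60, 80, 85, -80, 70)), "+/-RHHook")
  expect_warning(lab <- classify_geometry(c(0, 80, 85, -80, 70)), "zero")
  expect_equal(lab, "unclassified")

  # exhaustive sign grid: builder and classifier agree for all 32 patterns,
  # and every bond lands in exactly one class
  mags <- c(60, 90, 75, 100, 120)
  labels <- character(0)
  for (i in 0:31) {
    sgn <- ifelse(bitwAnd(i, 2^(0:4)) > 0, 1, -1)
    chi <- sgn * mags
    st <- gen_disulfide_model(chi)
    bb <- detect_disulfides(st)
    m <- chi_angles(st, bb[1, ])
    expect_equal(unname(m), chi, tolerance = 1)
    labels <- c(labels, classify_geometry(m))
    expect_equal(classify_geometry(m), classify_geometry(chi))
  }
  expect_true(all(grepl("^(\\+|-|\\+/-)(RH|LH)(Spiral|Hook|Staple)$", labels)))
  # chi3 sign flip flips handedness
  expect_equal(sum(grepl("RH", labels)), 16)
})

test_that("strain energy evaluates the torsional potential and is swap-symmetric", {
  expect_equal(strain_energy(c(-60, -60, -90, -60, -60)), 2.51, tolerance = 1e-9)
  expect_equal(strain_energy(c(180, 180, 180, 180, 180)), 29.28, tolerance = 1e-9)
  chi <- c(-45, -110, 95, -70, -150)
  expect_equal(strain_energy(chi), strain_energy(chi[c(5, 4, 3, 2, 1)]),
               tolerance = 1e-12)
  expect_true(strain_energy(c(-87, -93, 101, -88, -59)) >= 0)
})

test_that("min_distance is exact and equals the brute-force oracle", {
  expect_equal(min_distance(matrix(0, 1, 3), matrix(c(3, 4, 0), 1))$distance, 5)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(min_distance(a, a)$distance, 0)
  withr::with_seed(7, {
    for (rep in 1:5) {
      a <- matrix(rnorm(300, sd = 5), ncol = 3)
      b <- matrix(rnorm(300, sd = 5), ncol = 3)
      expect_equal(min_distance(a, b)$distance, brute_min_distance(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(min_distance(a[0, , drop = FALSE], a),
               class = "ssphot_input_error")
})

test_that("aromatic proximity recovers constructed probe distances and counts", {
  s <- toy_cystine()
  p <- gen_aromatic_probe(s, 4.50, residue = "TRP")
  prox <- aromatic_ss_proximity(p)
  expect_equal(nrow(prox), 1)
  expect_equal(prox$distance, 4.50, tolerance = 0.05)
  # second, farther probe: nearest distance reported per pair, cutoffs filter
  p2 <- gen_aromatic_probe(p, 10.0, residue = "TYR")
  prox2 <- aromatic_ss_proximity(p2)
  expect_equal(nrow(prox2), 2)
  expect_equal(sort(prox2$distance), c(4.50, 10.0), tolerance = 0.05)
  expect_equal(nrow(aromatic_ss_proximity(p2, cutoff = 6)), 1)

  counts8 <- count_aromatics_near_ss(p2, threshold = 8)
  expect_equal(counts8$n_trp, 1)
  expect_equal(counts8$n_tyr, 0)
  expect_equal(counts8$total_tyr, 1)
  expect_equal(count_aromatics_near_ss(p2, threshold = 0)$n_trp, 0)
  cInf <- count_aromatics_near_ss(p2, threshold = Inf)
  expect_equal(c(cInf$n_trp, cInf$n_tyr), c(cInf$total_trp, cInf$total_tyr))
})

test_that("tyrosine pair distances cluster by single linkage at the threshold", {
  s <- toy_cystine()
  p <- gen_aromatic_probe(s, 4.5)           # Tyr 12
  # Tyr 22: a copy of Tyr 12 shifted 4 A out of its ring plane (clusters)
  copy <- p$atoms[p$atoms$res_seq == 12, ]
  copy$res_seq <- 22L
  copy$z <- copy$z + 4
  copy$serial <- copy$serial + 100L
  p$atoms <- dplyr::bind_rows(p$atoms, copy)
  p <- gen_aromatic_probe(p, 40)            # Tyr 32, far away
  pairs <- tyr_pair_distances(p)
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$distance > 0))
  near <- pairs[pairs$tyr1 == 12 & pairs$tyr2 == 22, ]
  expect_true(near$cluster_distance < 6)
  expect_equal(near$cluster_id, 1L)
  expect_true(all(is.na(pairs$cluster_id[pairs$tyr2 == 32])))
  members <- tyr_clusters(pairs)
  expect_equal(sort(members$res_seq), c(12, 22))
  # two far-apart tyrosines alone form no cluster
  s2 <- gen_aromatic_probe(gen_aromatic_probe(toy_cystine(), 4.5), 40)
  pairs2 <- tyr_pair_distances(s2)
  expect_equal(nrow(tyr_clusters(pairs2)), 0)
})

test_that("disulphide fraction arithmetic and chain-length profile", {
  expect_equal(ss_fraction(24, 767), 100 * 24 / 767)
  expect_equal(round(ss_fraction(24, 767), 1), 3.1)
  expect_equal(ss_fraction(0, 500), 0)
  expect_equal(ss_fraction(1, 100), 1)
  expect_error(ss_fraction(1, 0), class = "ssphot_input_error")

  # closed-form synthetic dataset: fraction = 1000/length percent
  lens <- seq(100, 1000, by = 25)
  ds <- tibble::tibble(n_ss = 10, n_res = lens)
  prof <- ss_fraction_profile(ds, bin_width = 50)
  expect_equal(nrow(prof), length(unique(floor((lens - 1) / 50))))
  got <- prof$mean_fraction[prof$bin_lo == 101]
  expect_equal(got, mean(1000 / lens[lens >= 101 & lens <= 150]))
  one <- ss_fraction_profile(tibble::tibble(n_ss = 3, n_res = 120))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_fraction, ss_fraction(3, 120))

  # an SS-rich query against a 0.1% background bin is ~30x enriched
  bg <- tibble::tibble(n_ss = 0.78, n_res = 780)
  prof_bg <- ss_fraction_profile(bg)
  enr <- ss_fraction_enrichment(prof_bg, 24, 767)
  expect_equal(enr$ratio, ss_fraction(24, 767) / 0.1, tolerance = 1e-9)
  expect_true(enr$outlier)
})
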