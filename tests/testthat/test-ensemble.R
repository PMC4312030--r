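test_that("superposition undoes rigid motions, rejects mirrors, never hurts", {
  base <- toy_cystine(context = "decapeptide")
  rigid <- gen_ensemble(base, sigma = 0, n_frames = 6, seed = 11, rigid = TRUE)
  sup <- superpose(rigid, reference = 1, selection = "all")
  for (m in 2:6) expect_lt(frame_rmsd(sup, 1, m, selection = "all"), 1e-6)

  # mirror-image frame cannot be superposed by a proper rotation
  xyz <- atom_xyz(base$atoms)
  mir <- xyz
  mir[, 3] <- -mir[, 3]
  ens_mir <- as_ensemble(base, list(xyz, mir))
  sup_mir <- superpose(ens_mir, reference = 1, selection = "all")
  expect_gt(frame_rmsd(sup_mir, 1, 2, selection = "all"), 0.3)

  # jitter + rigid motion: RMSD to reference never increases, lands near the
  # jitter level, and matches the bio3d fitting oracle
  jit <- gen_ensemble(base, sigma = 0.3, n_frames = 10, seed = 21, rigid = TRUE)
  before <- frame_rmsd(jit, 1, 5, selection = "all")
  supj <- superpose(jit, reference = 1, selection = "all")
  after <- frame_rmsd(supj, 1, 5, selection = "all")
  expect_lte(after, before + 1e-9)
  expect_lt(after, 1.2)
  fixed <- as.vector(t(jit$frames[, , 1]))
  mobile <- as.vector(t(jit$frames[, , 5]))
  oracle <- bio3d::fit.xyz(fixed, mobile,
                           fixed.inds = seq_along(fixed),
                           mobile.inds = seq_along(mobile))
  oracle_rmsd <- sqrt(mean(rowSums(
    (matrix(oracle, ncol = 3, byrow = TRUE) -
       matrix(fixed, ncol = 3, byrow = TRUE))^2)))
  expect_equal(after, oracle_rmsd, tolerance = 1e-4)

  # degenerate (collinear) selections are refused
  line <- new_structure(tibble::tibble(
    atom_name = "CA", res_name = "GLY", chain_id = "A",
    res_seq = 1:4, x = 1:4, y = 0, z = 0, element = "C"))
  ens_line <- as_ensemble(line, list(atom_xyz(line$atoms), atom_xyz(line$atoms)))
  expect_error(superpose(ens_line, selection = "all"),
               class = "ssphot_degeneracy_error")
})

test_that("RMSF recovers the prescribed fluctuation structure", {
  base <- toy_cystine(context = "decapeptide")
  still <- gen_ensemble(base, sigma = 0, n_frames = 4, seed = 3)
  expect_true(all(rmsf(still, selection = "heavy")$rmsf == 0))
  expect_error(rmsf(as_ensemble(base, list(atom_xyz(base$atoms)))),
               class = "ssphot_input_error")

  # isotropic sigma-jitter: per-residue RMSF ~ sigma * sqrt(3) within 5%
  jit <- gen_ensemble(base, sigma = 0.5, n_frames = 500, seed = 99)
  prof <- rmsf(jit, selection = "heavy")
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.05)

  # RMSF is invariant under one global rigid motion applied to every frame
  rot <- ssphotolysis:::.random_rotation()
  moved <- jit
  for (m in seq_len(n_frames(moved))) {
    moved$frames[, , m] <- moved$frames[, , m] %*% t(rot)
  }
  expect_equal(rmsf(moved, selection = "heavy")$rmsf, prof$rmsf,
               tolerance = 1e-9)

  # two-tier sigma map: the profile separates loop from core residues
  tier <- gen_ensemble(base, sigma = c("1" = 0.2, "2" = 0.6), n_frames = 300,
                       seed = 7)
  ptier <- rmsf(tier, selection = "heavy")
  r1 <- ptier$rmsf[ptier$res_seq == 1]
  r2 <- ptier$rmsf[ptier$res_seq == 2]
  r0 <- ptier$rmsf[ptier$res_seq %in% c(-3, 6)]
  expect_gt(r2, 2 * r1)
  expect_true(all(r0 == 0))
})

test_that("exposure series and unit-integral distributions", {
  base <- toy_cystine()
  res <- residues(base)
  cys <- res[res$res_name == "CYS", ]
  still <- gen_ensemble(base, sigma = 0, n_frames = 3, seed = 1)
  ser <- sidechain_asa_series(still, cys[1, ])
  expect_equal(nrow(ser), 3)
  expect_equal(length(unique(ser$asa)), 1)
  expect_error(sidechain_asa_series(still, residue_ref("A", 77)),
               class = "ssphot_input_error")

  d0 <- asa_distribution(rep(12, 10), bin_width = 5)
  expect_equal(sum(d0$density > 0), 1)
  expect_equal(max(d0$density), 1 / 5)
  for (bw in c(1, 2.5, 5, 10)) {
    withr::with_seed(41, {
      d <- asa_distribution(runif(4000, 0, 100), bin_width = bw)
      expect_equal(sum(d$density * bw), 1, tolerance = 1e-9)
    })
  }
  withr::with_seed(42, {
    du <- asa_distribution(runif(5000, 0, 100), bin_width = 5)
    inner <- du$density[du$bin_lo >= 5 & du$bin_hi <= 95]
    expect_equal(mean(inner), 0.01, tolerance = 0.05)
  })
})

test_that("profile comparison reports shifts and overlap coefficients", {
  base <- toy_cystine(context = "decapeptide")
  jit <- gen_ensemble(base, sigma = 0.4, n_frames = 100, seed = 5)
  prof <- rmsf(jit, selection = "heavy")
  same <- compare_profiles(prof, prof)
  expect_true(all(same$diff == 0))

  da <- asa_distribution(rep(10, 50), bin_width = 5)
  expect_equal(compare_profiles(da, da)$overlap, 1, tolerance = 1e-9)
  db <- asa_distribution(rep(80, 50), bin_width = 5)
  cmp <- compare_profiles(da, db)
  expect_equal(cmp$overlap, 0)
  expect_equal(cmp$mean_shift, 70)

  # a shifted synthetic "reduced" exposure ensemble shows a positive shift
  withr::with_seed(8, {
    native <- asa_distribution(rnorm(400, 30, 5), bin_width = 5)
    reduced <- asa_distribution(rnorm(400, 45, 5), bin_width = 5)
  })
  shift <- compare_profiles(native, reduced)
  expect_gt(shift$mean_shift, 10)
  expect_lt(shift$overlap, 0.5)

  disjoint <- rmsf(gen_ensemble(toy_cystine(), sigma = 0.1, n_frames = 5,
                                seed = 2), selection = "heavy")
  disjoint$res_seq <- disjoint$res_seq + 100L
  expect_error(compare_profiles(prof, disjoint), class = "ssphot_input_error")
})

test_that("frame ranges subset the ensemble for equilibration discards", {
  base <- toy_cystine()
  ens <- gen_ensemble(base, sigma = 0.2, n_frames = 10, seed = 61)
  late <- subset_frames(ens, 6:10)
  expect_equal(n_frames(late), 5)
  expect_equal(late$frames[, , 1], ens$frames[, , 6])
  expect_error(subset_frames(ens, 0:3), class = "ssphot_input_error")
  expect_error(subset_frames(ens, 11), class = "ssphot_input_error")
})

test_that("multi-model PDB files round-trip as ensembles", {
  base <- toy_cystine()
  ens <- gen_ensemble(base, sigma = 0.2, n_frames = 4, seed = 31)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_equal(n_frames(back), 4)
  expect_equal(dim(back$frames)[1], nrow(base$atoms))
  expect_equal(back$frames, ens$frames, tolerance = 1e-3)
})
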