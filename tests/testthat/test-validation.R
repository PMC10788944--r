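# Model-vs-reference validation metrics.

test_that("backbone_rmsd is zero on self and invariant to rigid motions", {
  fx <- fx_clean(seed = 3)
  ref <- fx$truth_tc$structure
  expect_equal(as.numeric(backbone_rmsd(fx$truth_tc, ref)), 0,
               tolerance = 1e-9)
  withr::with_seed(8, {
    for (k in 1:3) {
      tf <- tcforge:::new_rigid_transform(tcforge:::random_rotation(),
                                          rnorm(3) * 20)
      moved <- fx$truth_tc
      moved$structure <- apply_transform(moved$structure, tf)
      expect_equal(as.numeric(backbone_rmsd(moved, ref)), 0, tolerance = 1e-8)
      # symmetry of the measure
      expect_equal(as.numeric(backbone_rmsd(fx$truth_tc, moved$structure)),
                   as.numeric(backbone_rmsd(moved, ref)), tolerance = 1e-8)
    }
  })
})

test_that("one protein rotated against the reference matches a direct joint fit", {
  fx <- fx_clean(seed = 5)
  model <- fx$truth_tc
  ref <- model$structure
  # rotate the E3 protein by 180 degrees about the linker midpoint
  mid <- colMeans(coords(ref)[model$linker_atoms, , drop = FALSE])
  rot <- tcforge:::rotation_about_axis(c(1, 0, 0), pi)
  xyz <- coords(ref)
  idx <- model$e3l_atoms
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, mid) %*% t(rot),
                      2, mid, `+`)
  twisted <- ref; coords(twisted) <- xyz
  got <- as.numeric(backbone_rmsd(model, twisted))
  # oracle: direct Kabsch over the matched backbone coordinates
  bb <- which(trimws(ref$atoms$name) %in% c("N", "CA", "C", "O"))
  want <- kabsch_fit(coords(model$structure)[bb, ], xyz[bb, ])$fit_rmsd
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got, 1)                      # genuinely non-rigid difference
})

test_that("gaussian coordinate noise gives the closed-form expected RMSD", {
  # N pseudo-residues of one CA atom each, fitted RMSD ~ sigma sqrt(3) sqrt(1-6/N)
  n <- 200; sigma <- 0.4
  withr::with_seed(21, {
    base <- matrix(rnorm(3 * n, sd = 8), n, 3)
    mk <- function(xyz) mol_structure(
      data.frame(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 name = "CA", residue_name = "ALA", residue_number = seq_len(n),
                 chain_id = "A"))
    vals <- vapply(1:6, function(k) {
      noisy <- base + matrix(rnorm(3 * n, sd = sigma), n, 3)
      as.numeric(backbone_rmsd(mk(noisy), mk(base)))
    }, numeric(1))
    expected <- sigma * sqrt(3) * sqrt(1 - 6 / n)
    expect_lt(abs(mean(vals) - expected) / expected, 0.10)
  })
  # rigid displacement only: removed entirely by the fit
  withr::with_seed(22, {
    base <- matrix(rnorm(90, sd = 5), 30, 3)
    mk <- function(xyz) mol_structure(
      data.frame(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 name = "CA", residue_name = "ALA",
                 residue_number = seq_len(30), chain_id = "A"))
    tf <- tcforge:::new_rigid_transform(tcforge:::random_rotation(), c(3, -7, 2))
    expect_equal(as.numeric(backbone_rmsd(mk(apply_transform(base, tf)),
                                          mk(base))), 0, tolerance = 1e-8)
  })
})

test_that("protac_rmsd measures placement in the fixed frame", {
  fx <- fx_clean(seed = 6)
  tc <- fx$truth_tc
  ref_lig <- subset_structure(tc$structure, tcforge:::protac_atoms(tc))
  expect_equal(as.numeric(protac_rmsd(tc, ref_lig)), 0, tolerance = 1e-12)
  # rigid 2 A shift of the reference ligand in the fixed frame reads as 2 A
  shifted <- ref_lig
  coords(shifted) <- coords(ref_lig) + matrix(rep(c(2, 0, 0), each = n_atoms(ref_lig)), ncol = 3)
  expect_equal(as.numeric(protac_rmsd(tc, shifted)), 2, tolerance = 1e-9)
  # non-isomorphic reference is rejected
  expect_error(protac_rmsd(tc, subset_structure(ref_lig, 1:4)),
               "isomorphic")
})

test_that("protac_rmsd minimises over automorphisms of symmetric degraders", {
  # linear all-carbon chain: reversal is an automorphism
  xyz <- tcforge:::.zigzag_coords(6, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  chain <- mol_structure(
    data.frame(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(i = 1:5, j = 2:6))
  # a fake one-fragment ternary complex wrapper
  tc <- list(structure = chain, warhead_atoms = integer(),
             linker_atoms = seq_len(6), le3_atoms = integer(),
             poi_atoms = integer(), e3l_atoms = integer())
  class(tc) <- "ternary_complex"
  flipped <- chain
  coords(flipped) <- coords(chain)[6:1, ]
  got <- as.numeric(protac_rmsd(tc, flipped))
  # brute force: min over the two automorphisms
  direct <- rmsd(coords(chain), coords(flipped))
  reversed <- rmsd(coords(chain), coords(flipped)[6:1, ])
  expect_equal(got, min(direct, reversed), tolerance = 1e-12)
  expect_equal(got, 0, tolerance = 1e-12)
  expect_equal(attr(protac_rmsd(tc, flipped), "n_mappings"), 2)
})

test_that("crystal-like classification uses a strict 10 A threshold", {
  expect_true(classify_crystal_like(3.5))
  expect_true(classify_crystal_like(0))
  expect_false(classify_crystal_like(10.0))
  expect_true(classify_crystal_like(9.999))
  expect_error(classify_crystal_like(-0.1), "non-negative")
})

test_that("validate_tc assembles the metric table", {
  fx <- fx_clean(seed = 9, perturbation = 5)
  out <- suppressMessages(suppressWarnings(
    model_ternary_complex(fx$poi_half, fx$e3_half)))
  ref_lig <- subset_structure(fx$truth_tc$structure,
                              tcforge:::protac_atoms(fx$truth_tc))
  v <- validate_tc(out$tc, fx$truth_tc$structure, ref_lig)
  expect_true(v$crystal_like)
  expect_lt(v$backbone_rmsd, 0.5)
  expect_lt(v$protac_rmsd, 1.0)
  expect_equal(v$n_matched_backbone, 2 * 8 * 4)   # two cages, N/CA/C/O each
})
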