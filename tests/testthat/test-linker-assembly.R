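# Linker construction, attachment, and the linker-superposition merge.

peg_linker <- function() {
  # triethylene-glycol-like chain: C-C-O-C-C-O-C-C
  els <- c("C", "C", "O", "C", "C", "O", "C", "C")
  mol_structure(data.frame(element = els, x = seq_along(els), y = 0, z = 0),
                data.frame(i = seq_len(7), j = seq_len(7) + 1))
}

test_that("build_linker_3d produces sane, deterministic conformers", {
  lk <- peg_linker()
  c1 <- build_linker_3d(lk, seed = 4, junction_atoms = c(1, 8))
  # bond-length audit over all bonds (including added hydrogens)
  xyz <- coords(c1)
  d <- sqrt(rowSums((xyz[c1$bonds$i, ] - xyz[c1$bonds$j, ])^2))
  expect_true(all(d > 0.8 & d < 1.9))
  # no nonbonded heavy-atom pair closer than 1.5 A
  expect_gte(tcforge:::.min_nonbonded_dist(c1), 1.5)
  # hydrogens were added except at the two junction open valences
  nh <- sum(c1$atoms$element == "H")
  expect_equal(nh, 12)   # four CH2 + two junction carbons with 2 H each
  # determinism
  c2 <- build_linker_3d(lk, seed = 4, junction_atoms = c(1, 8))
  expect_identical(coords(c1), coords(c2))
  # different seed is allowed to differ (exercises the seeded path)
  c3 <- build_linker_3d(lk, seed = 5, junction_atoms = c(1, 8))
  expect_equal(n_atoms(c3), n_atoms(c1))
})

test_that("a single-atom linker and cyclic linkers are handled", {
  one <- mol_structure(data.frame(element = "C", x = 0, y = 0, z = 0))
  out <- build_linker_3d(one, seed = 1, junction_atoms = c(1, 1))
  expect_equal(sum(is_heavy(out)), 1)
  expect_equal(sum(out$atoms$element == "H"), 2)   # CH2 with two open valences
  ring <- mol_structure(
    data.frame(element = rep("C", 3), x = c(0, 1.5, 0.75), y = c(0, 0, 1.2), z = 0),
    data.frame(i = c(1, 2, 3), j = c(2, 3, 1)))
  expect_error(build_linker_3d(ring, seed = 1), "acyclic")
})

test_that("attach_linker respects the moiety pose and standard bond geometry", {
  fx <- fx_clean()
  half0 <- subset_structure(fx$poi_half$structure,
                            sort(c(fx$poi_half$protein_atoms,
                                   fx$poi_half$moiety_atoms)))
  lk <- build_linker_3d(peg_linker(), seed = 2, junction_atoms = c(1, 8))
  moi_j <- fx$poi_half$moiety_junction_atom
  half <- attach_linker(half0, lk, c(moiety = moi_j, linker = 1),
                        junction_distal = 8, side = "POI_SIDE")
  # protein + moiety coordinates bitwise unchanged
  keep <- seq_len(n_atoms(half0))
  expect_identical(coords(half$structure)[keep, ], coords(half0))
  # new junction C-C bond at standard length
  xyz <- coords(half$structure)
  d <- sqrt(sum((xyz[moi_j, ] - xyz[half$linker_junction_local, ])^2))
  expect_equal(d, 1.53, tolerance = 0.03)
  # bookkeeping partitions the atoms
  expect_equal(sort(c(half$protein_atoms, half$moiety_atoms, half$linker_atoms)),
               seq_len(n_atoms(half$structure)))
})

test_that("attach_linker picks the unoccluded torsion among 12 candidates", {
  # moiety: junction atom at origin bonded to an anchor at -z
  moiety <- mol_structure(
    data.frame(element = c("C", "C"), x = 0, y = 0, z = c(0, -1.52),
               origin_tag = "WARHEAD"),
    data.frame(i = 1, j = 2))
  # wall of carbon atoms occluding all lateral directions except +x
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  keep <- ang > pi / 6 & ang < 2 * pi - pi / 6   # leave the +x corridor open
  wall <- mol_structure(
    data.frame(element = "C", x = 3.4 * cos(ang[keep]),
               y = 3.4 * sin(ang[keep]), z = 2.2, origin_tag = "POI"))
  half0 <- combine_structures(wall, moiety)
  lk <- mol_structure(data.frame(element = c("C", "C", "C"),
                                 x = c(0, 0.9, 1.8), y = c(0, 1.2, 2.4) * 0.4,
                                 z = c(0, 0.9, 1.5)),
                      data.frame(i = 1:2, j = 2:3))
  lk3 <- build_linker_3d(lk, seed = 1, junction_atoms = 1)
  half <- attach_linker(half0, lk3, c(moiety = n_atoms(wall) + 1, linker = 1),
                        side = "POI_SIDE")
  # the far linker atoms must emerge on the open (+x) side
  tip <- coords(half$structure)[utils::tail(half$linker_atoms[
    half$structure$atoms$element[half$linker_atoms] != "H"], 1), ]
  expect_gt(tip[1], 0)                       # +x corridor
  expect_lt(abs(atan2(tip[2], tip[1])), pi / 5)
})

test_that("superpose_and_merge of congruent linkers is exact and conservative", {
  fx <- fx_clean(seed = 6, perturbation = 9)
  tc <- superpose_and_merge(fx$poi_half, fx$e3_half)
  expect_lt(tc$assembly_rmsd, 1e-6)          # congruent up to a rigid motion
  # conservation: |TC| = |poi| + |e3| - |linker|
  expect_equal(n_atoms(tc$structure),
               n_atoms(fx$poi_half$structure) + n_atoms(fx$e3_half$structure) -
                 length(fx$e3_half$linker_atoms))
  # POI frame bitwise invariant
  np <- n_atoms(fx$poi_half$structure)
  expect_identical(coords(tc$structure)[seq_len(np), ],
                   coords(fx$poi_half$structure))
  # exactly two junction bonds cross PROTAC fragment boundaries
  pa <- sort(c(tc$warhead_atoms, tc$linker_atoms, tc$le3_atoms))
  b <- tc$structure$bonds
  b <- b[b$i %in% pa & b$j %in% pa, ]
  tags <- tc$structure$atoms$origin_tag
  expect_equal(sum(tags[b$i] != tags[b$j]), 2)
  # junction geometry ideal after an exact merge
  xyz <- coords(tc$structure)
  jb <- b[tags[b$i] != tags[b$j], ]
  d <- sqrt(rowSums((xyz[jb$i, ] - xyz[jb$j, ])^2))
  expect_true(all(abs(d - 1.52) < 0.1))
})

test_that("symmetric linkers try both anchored mappings and keep the best", {
  fx <- make_toy_tc(fixture_spec(seed = 8, flavor = "SYMMETRIC_LINKER",
                                 perturbation = 3))
  expect_message(tc <- superpose_and_merge(fx$poi_half, fx$e3_half),
                 "symmetric linker")
  # the kept mapping is at least as good as the reversal: brute-force both
  lp <- subset_structure(fx$poi_half$structure, fx$poi_half$linker_atoms)
  le <- subset_structure(fx$e3_half$structure, fx$e3_half$linker_atoms)
  nl <- n_atoms(lp)
  r_fwd <- kabsch_fit(coords(le), coords(lp))$fit_rmsd
  r_rev <- kabsch_fit(coords(le), coords(lp)[nl:1, ])$fit_rmsd
  expect_equal(tc$assembly_rmsd, min(r_fwd, r_rev), tolerance = 1e-9)
})

test_that("non-isomorphic linkers are rejected", {
  fx1 <- fx_clean(seed = 2)
  fx2 <- make_toy_tc(fixture_spec(seed = 2, flavor = "SYMMETRIC_LINKER"))
  expect_error(superpose_and_merge(fx1$poi_half, fx2$e3_half),
               "identical linkers")
})

test_that("assembly rmsd grows with non-rigid perturbation of one linker copy", {
  fx <- fx_clean(seed = 9)
  rmsds <- vapply(c(0, 0.05, 0.15, 0.3), function(s) {
    eh <- fx$e3_half
    xyz <- coords(eh$structure)
    withr::with_seed(77, {
      idx <- eh$linker_atoms
      xyz[idx, ] <- xyz[idx, ] + matrix(rnorm(3 * length(idx), sd = s),
                                        ncol = 3)
    })
    coords(eh$structure) <- xyz
    suppressMessages(superpose_and_merge(fx$poi_half, eh))$assembly_rmsd
  }, numeric(1))
  expect_true(all(diff(rmsds) > 0))
})

test_that("the merged model is bitwise deterministic", {
  fx <- fx_clean(seed = 10, perturbation = 6)
  t1 <- superpose_and_merge(fx$poi_half, fx$e3_half)
  t2 <- superpose_and_merge(fx$poi_half, fx$e3_half)
  expect_identical(coords(t1$structure), coords(t2$structure))
})
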