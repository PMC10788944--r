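# Minimization engine contracts and the staged refinement of merged models.

test_that("analytic gradients match numerical differentiation", {
  withr::with_seed(12, {
    n <- 7
    m <- mol_structure(
      data.frame(element = sample(c("C", "N", "O"), n, replace = TRUE),
                 x = cumsum(runif(n, 1.2, 1.5)), y = rnorm(n, 0, 0.7),
                 z = rnorm(n, 0, 0.7),
                 partial_charge = round(runif(n, -0.3, 0.3), 2)),
      data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1))
    terms <- tcforge:::.ff_terms(m, 10)
    xyz <- coords(m)
    g <- tcforge:::.ff_eval(xyz, terms)$grad
    h <- 1e-6
    num <- matrix(0, n, 3)
    for (a in seq_len(n)) for (d in 1:3) {
      xp <- xyz; xp[a, d] <- xp[a, d] + h
      xm <- xyz; xm[a, d] <- xm[a, d] - h
      num[a, d] <- (tcforge:::.ff_eval(xp, terms, want_grad = FALSE)$energy -
                      tcforge:::.ff_eval(xm, terms, want_grad = FALSE)$energy) /
        (2 * h)
    }
    expect_lt(max(abs(g - num)), 1e-5)
  })
})

test_that("minimize_half keeps poses restrained and lowers the energy", {
  for (seed in c(2, 6, 9)) {
    fx <- fx_clean(seed = seed)
    res <- minimize_half(fx$poi_half)
    expect_lte(attr(res, "e_end"), attr(res, "e_start") + 1e-9)
    expect_lte(attr(res, "max_restrained_moved"), 0.3)
  }
  # a half already at its restrained minimum is a fixed point
  fx <- fx_clean(seed = 2)
  h1 <- minimize_half(fx$poi_half)
  h2 <- minimize_half(h1)
  expect_lt(rmsd(coords(h2$structure), coords(h1$structure)), 5e-3)
})

test_that("minimization resolves a linker built through a protein atom", {
  fx <- fx_clean(seed = 5)
  half <- fx$poi_half
  xyz <- coords(half$structure)
  # drag one mid-linker atom onto a cage atom (forced clash)
  mid <- half$linker_atoms[3]
  xyz[mid, ] <- coords(half$structure)[half$protein_atoms[8], ] + c(0.6, 0, 0)
  coords(half$structure) <- xyz
  res <- minimize_half(half, min_config(max_iter = 4000))
  xyz2 <- coords(res$structure)
  dmin <- min(as.matrix(stats::dist(
    rbind(xyz2[res$linker_atoms, ], xyz2[res$protein_atoms, ])
  ))[seq_along(res$linker_atoms),
     length(res$linker_atoms) + seq_along(res$protein_atoms)])
  expect_gt(dmin, 2.0)
  expect_lte(attr(res, "e_end"), attr(res, "e_start"))
})

test_that("detect_clashes applies the 0.7 vdW-sum rule with exclusions", {
  # two carbons 5 A apart: nothing
  far <- mol_structure(data.frame(element = c("C", "C"), x = c(0, 5), y = 0, z = 0))
  expect_equal(nrow(detect_clashes(far)), 0)
  # two non-bonded carbons at 1.0 A: threshold 0.7 * 3.4 = 2.38
  near <- mol_structure(data.frame(element = c("C", "C"), x = c(0, 1), y = 0, z = 0))
  cl <- detect_clashes(near)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$threshold, 0.7 * 2 * element_param("C", "rvdw"))
  expect_equal(cl$distance, 1)
  # the same pair bonded: excluded
  bonded <- mol_structure(near$atoms, data.frame(i = 1, j = 2))
  expect_equal(nrow(detect_clashes(bonded)), 0)
  # 1-3 pairs excluded, hydrogens ignored
  angled <- mol_structure(
    data.frame(element = c("C", "C", "C", "H"),
               x = c(0, 1.5, 2.2, 0.6), y = c(0, 0, 1.2, 0.9), z = 0),
    data.frame(i = c(1, 2), j = c(2, 3)))
  expect_equal(nrow(detect_clashes(angled)), 0)
})

test_that("refine_stage_local fixes an injected clash and nothing else", {
  fx <- make_toy_tc(fixture_spec(seed = 4, flavor = "CLASHED"))
  tc <- suppressMessages(superpose_and_merge(fx$poi_half, fx$e3_half))
  cl <- detect_clashes(tc)
  expect_gte(nrow(cl), 1)
  xyz0 <- coords(tc$structure)
  tc2 <- refine_stage_local(tc, cl, config = min_config(max_iter = 4000))
  # the clash neighbourhood is clean afterwards
  seeds <- unique(c(cl$atom_i, cl$atom_j))
  cl2 <- detect_clashes(tc2)
  expect_equal(nrow(cl2[cl2$atom_i %in% seeds | cl2$atom_j %in% seeds, ]), 0)
  # atoms > 6 A from every clash atom are bitwise unchanged
  d2seed <- vapply(seq_len(nrow(xyz0)), function(a) {
    min(sqrt(rowSums(sweep(xyz0[seeds, , drop = FALSE], 2, xyz0[a, ])^2)))
  }, numeric(1))
  untouched <- which(d2seed > 6)
  expect_identical(coords(tc2$structure)[untouched, ], xyz0[untouched, ])
  # per-round energies never increase
  log <- attr(tc2, "stage_log")
  expect_true(all(log$e_end <= log$e_start + 1e-9))
  # clash-free input is a no-op
  fxc <- fx_clean(seed = 4)
  tc_clean <- suppressMessages(superpose_and_merge(fxc$poi_half, fxc$e3_half))
  tc3 <- refine_stage_local(tc_clean, detect_clashes(tc_clean))
  expect_identical(coords(tc3$structure), coords(tc_clean$structure))
})

test_that("refine_stage_protac moves no protein atom and relaxes the degrader", {
  fx <- make_toy_tc(fixture_spec(seed = 6, flavor = "STRAINED_JUNCTION"))
  tc <- suppressMessages(superpose_and_merge(fx$poi_half, fx$e3_half))
  # the strained L^E3 junction bond starts stretched
  tags <- tc$structure$atoms$origin_tag
  b <- tc$structure$bonds
  jb <- b[(tags[b$i] == "LINKER" & tags[b$j] == "LE3") |
            (tags[b$j] == "LINKER" & tags[b$i] == "LE3"), ]
  xyz0 <- coords(tc$structure)
  d0 <- sqrt(sum((xyz0[jb$i, ] - xyz0[jb$j, ])^2))
  expect_gt(d0, 2.1)
  tc2 <- refine_stage_protac(tc, min_config(max_iter = 4000))
  xyz <- coords(tc2$structure)
  d1 <- sqrt(sum((xyz[jb$i, ] - xyz[jb$j, ])^2))
  expect_gte(d1, 1.45); expect_lte(d1, 1.60)
  prot <- sort(c(tc$poi_atoms, tc$e3l_atoms))
  expect_identical(xyz[prot, ], xyz0[prot, ])
  expect_lte(attr(tc2, "e_end"), attr(tc2, "e_start"))
})

test_that("refine_stage_free reports QC and a fixed point stays put", {
  fx <- fx_clean(seed = 7)
  tc <- fx$truth_tc                   # already refined = a fixed point
  out <- refine_stage_free(tc, pose_reference = tc)
  expect_true(out$report$qc_pass)
  expect_equal(out$report$clashes_after, 0)
  expect_lt(out$report$protein_displacement, 0.05)
  expect_lt(out$report$pose_rmsd_warhead, 0.05)
  expect_true(out$tc$refined)
})

test_that("the full staged pipeline ends clash-free with monotone stages", {
  for (seed in c(1, 8)) {
    fx <- fx_clean(seed = seed, perturbation = 4)
    out <- suppressMessages(suppressWarnings(
      model_ternary_complex(fx$poi_half, fx$e3_half)))
    expect_true(out$report$qc_pass)
    expect_equal(out$report$clashes_after, 0)
    se <- out$report$stage_energies
    expect_true(all(se$e_end <= se$e_start + 1e-9))
    # QC re-checked independently of the minimizer
    expect_equal(nrow(detect_clashes(out$tc)), 0)
  }
})
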