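# Interaction typing, the per-interaction energy model, the degrader score,
# and the protein-protein interface summary.

# toy complex: an N-H donor ("ligand") facing a carbonyl acceptor
# ("receptor"), collinear N-H...O at a chosen N...O distance
hb_pair <- function(d_no, tag = TRUE) {
  atoms <- data.frame(
    element = c("N", "H", "O", "C"),
    x = c(0, 1.01, d_no, d_no + 1.3),
    y = 0, z = 0,
    partial_charge = c(-0.6, 0.4, -0.5, 0.5))
  if (tag) atoms$origin_tag <- c("WARHEAD", "WARHEAD", "POI", "POI")
  mol_structure(atoms, data.frame(i = c(1, 3), j = c(2, 4),
                                  order = c(1, 2)))
}

test_that("interaction typing follows the geometric criteria", {
  m <- hb_pair(2.9)
  out <- enumerate_interactions(m, c(1, 2), c(3, 4))
  expect_equal(out$kind[out$ligand_atom == 1 & out$protein_atom == 3], "HBOND")
  # same geometry at 4.5 A: nothing
  expect_equal(nrow(enumerate_interactions(hb_pair(4.5), c(1, 2), c(3, 4))), 0)
  # donor-acceptor at 3.4 A but H pointing away: demoted to NONBONDED
  bent <- hb_pair(3.4)
  xyz <- coords(bent); xyz[2, ] <- c(-1.01, 0, 0)   # H on the far side
  coords(bent) <- xyz
  out2 <- enumerate_interactions(bent, c(1, 2), c(3, 4))
  expect_equal(out2$kind[out2$ligand_atom == 1 & out2$protein_atom == 3],
               "NONBONDED")
  # carboxylate O- to ammonium N+ at 3.5 A: SALT_BRIDGE, counted once
  sb <- mol_structure(
    data.frame(element = c("N", "H", "O"),
               x = c(0, 1.01, 3.5), y = 0, z = 0,
               formal_charge = c(1L, 0L, -1L),
               partial_charge = c(0.3, 0.3, -0.8)),
    data.frame(i = 1, j = 2))
  out3 <- enumerate_interactions(sb, c(1, 2), 3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$kind, "SALT_BRIDGE")
  # overlap between groups is an error
  expect_error(enumerate_interactions(m, c(1, 2), c(2, 3)), "overlap")
})

test_that("enumeration equals the brute-force all-pairs classifier", {
  for (seed in c(3, 9)) {
    fx <- fx_clean(seed = seed)
    tc <- fx$truth_tc
    got <- enumerate_interactions(tc, tc$warhead_atoms,
                                  sort(c(tc$poi_atoms, tc$e3l_atoms)),
                                  warn_unrefined = FALSE)
    want <- oracle_classify_pairs(tc$structure, tc$warhead_atoms,
                                  sort(c(tc$poi_atoms, tc$e3l_atoms)))
    key <- function(df) {
      df <- df[order(df$ligand_atom, df$protein_atom), ]
      paste(df$kind, df$ligand_atom, df$protein_atom, round(df$distance, 6))
    }
    expect_equal(key(as.data.frame(got)), key(want))
  }
})

test_that("the Coulomb term matches its closed form (eps = 4r)", {
  # +1/-1 unit charges at 3.0 A with LJ switched off via distant vdW pairing
  m <- mol_structure(
    data.frame(element = c("N", "O"), x = c(0, 3), y = 0, z = 0,
               formal_charge = c(1L, -1L),
               partial_charge = c(1, -1)))
  inter <- list(kind = "NONBONDED", ligand_atom = 1, protein_atom = 2)
  e <- interaction_energy(inter, m)
  e_coul <- 332.0636 / (4 * 3^2) * (-1)
  e_lj <- {
    rmin <- sum(element_param(c("N", "O"), "rvdw"))
    eps <- sqrt(prod(element_param(c("N", "O"), "lj_eps")))
    eps * ((rmin / 3)^12 - 2 * (rmin / 3)^6)
  }
  expect_equal(e, e_coul + e_lj, tolerance = 1e-9)
  expect_lt(e, 0)
  # at the LJ minimum distance with zero charges, the LJ term is -eps
  m2 <- mol_structure(
    data.frame(element = c("C", "C"), x = c(0, 2 * element_param("C", "rvdw")),
               y = 0, z = 0))
  e2 <- interaction_energy(list(kind = "NONBONDED", ligand_atom = 1,
                                protein_atom = 2), m2)
  expect_equal(e2, -element_param("C", "lj_eps"), tolerance = 1e-12)
})

test_that("polar-group hydrogens enter HBOND/SALT_BRIDGE energies", {
  m <- hb_pair(2.9)
  e_hb <- interaction_energy(list(kind = "HBOND", ligand_atom = 1,
                                  protein_atom = 3), m)
  e_nb <- interaction_energy(list(kind = "NONBONDED", ligand_atom = 1,
                                  protein_atom = 3), m)
  # the H(+0.4)...O(-0.5) pair adds attraction
  expect_lt(e_hb, e_nb)
})

test_that("degrader score is additive, excludes the linker, and ranks poses", {
  fx <- fx_clean(seed = 2)
  tc <- fx$truth_tc
  sc <- degrader_score(tc)
  expect_identical(sc$total, sc$e_warhead + sc$e_le3)   # exact additivity
  expect_equal(glance(sc)$total, sc$total)
  expect_equal(nrow(tidy(sc)), nrow(sc$warhead_interactions) +
                 nrow(sc$le3_interactions))

  # moiety with no protein atom within 4 A contributes exactly zero:
  # pull the L^E3 guest far away
  tc_far <- tc
  xyz <- coords(tc_far$structure)
  xyz[tc_far$le3_atoms, ] <- xyz[tc_far$le3_atoms, ] + 60
  coords(tc_far$structure) <- xyz
  sc_far <- degrader_score(tc_far)
  expect_identical(sc_far$e_le3, 0)

  # perturbing only linker atoms (no new moiety contacts) leaves the score
  # unchanged
  tc_lk <- tc
  xyz <- coords(tc_lk$structure)
  withr::with_seed(123, {
    xyz[tc_lk$linker_atoms, ] <- xyz[tc_lk$linker_atoms, ] +
      matrix(rnorm(3 * length(tc_lk$linker_atoms), sd = 0.2), ncol = 3)
  })
  coords(tc_lk$structure) <- xyz
  expect_identical(degrader_score(tc_lk)$total, sc$total)

  # displacing the warhead 2 A out of the pocket makes the score worse
  # (less negative): score(A) < score(B)
  tc_out <- tc
  xyz <- coords(tc_out$structure)
  xyz[tc_out$warhead_atoms, ] <- xyz[tc_out$warhead_atoms, ] +
    matrix(rep(c(0, 0, 2) %o% 1, each = length(tc_out$warhead_atoms)),
           ncol = 3)
  coords(tc_out$structure) <- xyz
  expect_lt(sc$total, degrader_score(tc_out)$total)

  # empty moiety errors
  tc_bad <- tc; tc_bad$warhead_atoms <- integer()
  expect_error(degrader_score(tc_bad), "non-empty")
})

test_that("an approaching favourable H-bond pair lowers its energy", {
  e_far <- interaction_energy(list(kind = "HBOND", ligand_atom = 1,
                                   protein_atom = 3), hb_pair(4.4))
  e_near <- interaction_energy(list(kind = "HBOND", ligand_atom = 1,
                                    protein_atom = 3), hb_pair(2.9))
  expect_lt(e_near, e_far)
})

test_that("ppi_summary counts designed contacts and measures buried area", {
  # two parallel five-carbon strands, three pairs designed within 4 A
  strand <- function(x0, z0, chain, tag) {
    mol_structure(
      data.frame(element = "C", x = x0, y = seq(0, 16, by = 4), z = z0,
                 name = "CA", residue_name = "ALA",
                 residue_number = seq_len(5) + ifelse(chain == "A", 0, 100),
                 chain_id = chain, origin_tag = tag))
  }
  a <- strand(0, 0, "A", "POI")
  b <- strand(3.8, 0, "B", "E3L")
  xyz <- coords(b)
  xyz[4:5, 1] <- 10                  # two residues pulled out of range
  coords(b) <- xyz
  tcs <- combine_structures(a, b)
  # a distant dummy degrader so the container is a full ternary complex
  deg <- mol_structure(
    data.frame(element = rep("C", 3), x = 50 + c(0, 1.5, 3), y = 0, z = 0,
               origin_tag = c("WARHEAD", "LINKER", "LE3")),
    data.frame(i = 1:2, j = 2:3))
  tc <- new_ternary_complex(combine_structures(tcs, deg))
  pp <- ppi_summary(tc)
  expect_equal(pp$nonbonded_contacts, 3)
  expect_equal(pp$hbonds, 0)
  expect_equal(pp$salt_bridges, 0)
  expect_equal(nrow(pp$interface_residues), 6)    # 3 residues on each side
  expect_gt(pp$contact_area, 0)

  # far-apart proteins: empty summary
  b_far <- b
  coords(b_far) <- coords(b) + 50
  tc_far <- new_ternary_complex(
    combine_structures(combine_structures(a, b_far), deg))
  pp_far <- ppi_summary(tc_far)
  expect_equal(pp_far$nonbonded_contacts + pp_far$hbonds + pp_far$salt_bridges, 0)
  expect_lt(pp_far$contact_area, 1e-6)
})

test_that("buried surface agrees with an independent grid-quadrature SASA", {
  fx <- fx_clean(seed = 2)
  tc <- fx$truth_tc
  poi <- subset_structure(tc$structure, tc$poi_atoms)
  war <- subset_structure(tc$structure, tc$warhead_atoms)
  both <- subset_structure(tc$structure,
                           sort(c(tc$poi_atoms, tc$warhead_atoms)))
  buried <- (sum(sasa(poi)) + sum(sasa(war)) - sum(sasa(both))) / 2
  buried_oracle <- (oracle_grid_sasa(poi) + oracle_grid_sasa(war) -
                      oracle_grid_sasa(both)) / 2
  expect_gt(buried, 0)
  expect_lt(abs(buried - buried_oracle) / buried_oracle, 0.05)
})
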