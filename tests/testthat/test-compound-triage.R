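test_that("heavy_atom_count handles organic-subset, aromatic and bracket atoms", {
  cases <- list(
    list("CCO", 3L),                        # ethanol
    list("c1ccccc1", 6L),                   # benzene, aromatic
    list("C#N", 2L),                        # triple bond skipped
    list("CC(=O)[O-]", 4L),                 # bracket anion counts once
    list("[2H]OC", 2L),                     # isotopic hydrogen excluded
    list("[NH4+]", 1L),                     # H-count inside bracket ignored
    list("ClCCl", 3L),                      # two-letter element
    list("C1CC%12CC1CC%12", 7L)             # %nn ring closures
  )
  for (cs in cases) expect_identical(heavy_atom_count(cs[[1]]), cs[[2]])
  expect_identical(heavy_atom_count(c("CCO", "c1ccccc1")), c(3L, 6L))
})

test_that("heavy_atom_count rejects malformed SMILES with a parse error", {
  for (bad in c("", "C[", "C%1C", "CxC")) {
    expect_error(heavy_atom_count(bad), class = "npcquant_parse_error")
  }
})

test_that("heavy_atom_count reproduces formula-derived counts for the worked example", {
  tab <- npc_docking_table()
  counted <- heavy_atom_count(tab$smiles)
  # sums of non-H atoms in the standard molecular formulas, in table order
  expected <- c(23L, 22L, 27L, 33L, 30L, 26L, 33L, 22L, 25L, 26L, 28L, 29L)
  expect_identical(counted, expected)
})

test_that("ligand_efficiency is E_b / N_heavy with sign and linearity", {
  expect_equal(ligand_efficiency(-11.3, 28), -11.3 / 28)
  expect_equal(round(ligand_efficiency(-11.3, 28), 3), -0.404)
  expect_equal(round(ligand_efficiency(-12.6, 23), 3), -0.548)
  expect_identical(ligand_efficiency(0, 17), 0)
  # linearity in the energy for arbitrary scalars
  for (c in c(-2, 0.5, 3)) {
    expect_equal(ligand_efficiency(c * -7.7, 19),
                 c * ligand_efficiency(-7.7, 19))
  }
  expect_error(ligand_efficiency(-10, 0), class = "npcquant_domain_error")
})

test_that("verify_efficiency_table passes all 12 packaged rows at printed precision", {
  tab <- npc_docking_table()
  expect_true(all(verify_efficiency_table(tab)))
  # quinestrol is printed at 2 decimals and passes at that precision
  quin <- tab[tab$name == "Quinestrol", ]
  expect_identical(npcquant:::printed_decimals(quin$be_printed), 2L)
  expect_true(verify_efficiency_table(quin))
  # a value mistyped by 0.01 at 3 decimals fails
  bad <- tab[1, ]
  bad$be_printed <- sprintf("%.3f", as.numeric(bad$be_printed) + 0.01)
  expect_false(verify_efficiency_table(bad))
  # missing printed efficiency is a validation error naming the row
  none <- tab[2, ]; none$be_printed <- NA_character_
  expect_error(verify_efficiency_table(none),
               regexp = none$compound_id, class = "npcquant_validation_error")
})

test_that("select_hits applies the inclusive reference criterion with tie order", {
  tab <- npc_docking_table()
  cand <- tab[tab$role == "candidate", ]
  hits <- select_hits(cand, hit_criterion(-11.3))
  expect_identical(nrow(hits), 10L)
  # the boundary ties at exactly -11.3 are retained
  expect_true(all(c("DB00977", "DB01420", "DB12598") %in% hits$compound_id))
  # ordering: energy ascending, then efficiency, then id
  expect_identical(hits$compound_id[1:2], c("DB00378", "DB09280"))
  expect_true(!is.unsorted(hits$binding_energy))
  # a lone weak binder yields an empty hit list, not an error
  weak <- cand[1, ]; weak$binding_energy <- -10.0
  expect_identical(nrow(select_hits(weak, hit_criterion(-11.3))), 0L)
  expect_identical(nrow(select_hits(cand[0, ], hit_criterion(-11.3))), 0L)
})

test_that("select_hits is idempotent, a subset, and monotone in the reference", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    tab <- data.frame(
      compound_id = sprintf("C%03d", seq_len(n)),
      name = sprintf("cmp%d", seq_len(n)),
      binding_energy = round(runif(n, -13, -8), 1),
      heavy_atoms = sample(15:40, n, replace = TRUE))
    ref <- runif(1, -12.5, -9)
    crit <- hit_criterion(ref)
    hits <- select_hits(tab, crit)
    expect_true(all(hits$compound_id %in% tab$compound_id))
    expect_identical(select_hits(hits, crit)$compound_id, hits$compound_id)
    looser <- select_hits(tab, hit_criterion(ref + 0.5))
    expect_true(all(hits$compound_id %in% looser$compound_id))
  }
})

test_that("rank_compounds orders by energy then efficiency with ranks", {
  tab <- npc_docking_table()
  ranked <- rank_compounds(tab[tab$role == "candidate", ],
                           hit_criterion(-11.3))
  expect_identical(ranked$rank, 1:10)
  expect_identical(ranked$name[1:2], c("Dydrogesterone", "Lumacaftor"))
  expect_equal(ranked$binding_energy[1:2], c(-12.6, -12.1))
  expect_true(all(ranked$is_hit))
  # one-record input gets rank 1
  expect_identical(rank_compounds(tab[5, ])$rank, 1L)
  # equal energies are ordered by efficiency
  two <- data.frame(compound_id = c("A", "B"), name = c("a", "b"),
                    binding_energy = c(-11.5, -11.5),
                    heavy_atoms = c(20L, 30L))
  r <- rank_compounds(two)
  expect_identical(r$compound_id, c("A", "B"))  # -0.575 before -0.383
  r2 <- rank_compounds(two[2:1, ])
  expect_identical(r2$compound_id, c("A", "B"))  # order-independent
})

test_that("parse_vina_result reads both dialects and round-trips exactly", {
  aff <- c(-11.4, -10.9, -10.2)
  pd <- parse_vina_result(vina_pdbqt_fixture(aff), "pdbqt")
  expect_equal(pd$modes$affinity, aff)
  expect_equal(pd$best_affinity, -11.4)
  lg <- parse_vina_result(vina_log_fixture(-7.0), "log")
  expect_equal(lg$best_affinity, -7.0)
  expect_identical(nrow(lg$modes), 1L)
  # parse -> serialize -> parse preserves affinities exactly, both dialects
  for (dialect in c("pdbqt", "log")) {
    again <- parse_vina_result(serialize_vina_modes(pd, dialect), dialect)
    expect_identical(again$modes$affinity, pd$modes$affinity)
  }
  # file input path
  tf <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(vina_pdbqt_fixture(aff), tf)
  expect_equal(parse_vina_result(tf, "pdbqt")$best_affinity, -11.4)
})

test_that("parse_vina_result rejects degenerate or corrupt input", {
  expect_error(parse_vina_result("", "pdbqt"), class = "npcquant_parse_error")
  expect_error(parse_vina_result("ATOM 1", "log"),
               class = "npcquant_parse_error")
  expect_error(
    parse_vina_result("REMARK VINA RESULT:    abc   0 0", "pdbqt"),
    regexp = "line 1", class = "npcquant_parse_error")
  # affinities out of order are refused
  expect_error(parse_vina_result(vina_pdbqt_fixture(c(-9, -11)), "pdbqt"),
               class = "npcquant_parse_error")
})

test_that("read_compound_table accepts heavy_atoms in place of smiles", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,name,heavy_atoms,binding_energy",
               "X1,alpha,20,-11.5", "X2,beta,30,-10.0"), tf)
  tab <- read_compound_table(tf)
  expect_identical(tab$heavy_atoms, c(20L, 30L))
  expect_equal(tab$binding_efficiency, c(-11.5 / 20, -10 / 30))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tname\tsmiles\tbinding_energy",
               "X1\talpha\tCCO\t-5.0"), tf2)
  expect_identical(read_compound_table(tf2)$heavy_atoms, 3L)
  expect_error(read_compound_table(withr::local_tempfile()),
               class = "npcquant_validation_error")
})
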