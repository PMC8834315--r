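test_that("every generator is a pure function of its spec (bit-identical reruns)", {
  f1 <- gen_filipin_field(filipin_field_spec(seed = 7))
  f2 <- gen_filipin_field(filipin_field_spec(seed = 7))
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(f1$truth$cells, f2$truth$cells)
  p1 <- gen_coloc_pair(coloc_spec(0.5, 400, seed = 7))
  p2 <- gen_coloc_pair(coloc_spec(0.5, 400, seed = 7))
  expect_identical(p1$ch1, p2$ch1)
  b1 <- gen_blot_dataset(blot_spec(seed = 7))
  b2 <- gen_blot_dataset(blot_spec(seed = 7))
  expect_identical(b1$levels, b2$levels)
  s1 <- gen_screen_table(screen_spec(n_compounds = 100, seed = 7))
  s2 <- gen_screen_table(screen_spec(n_compounds = 100, seed = 7))
  expect_identical(s1, s2)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_filipin_field(filipin_field_spec(seed = 9)))
  expect_identical(runif(1), before)
})

test_that("filipin ground truth predicts the noise-free LSO ratio in closed form", {
  spec <- filipin_field_spec(noise_sd = 0, n_cells = 1, accumulation = 1,
                             max_puncta_per_cell = 1, seed = 3)
  fld <- gen_filipin_field(spec)
  tr <- fld$truth
  expect_identical(tr$n_puncta, 1L)
  got <- lso_compartment_ratio(fld$pixels, tr$t_low, tr$t_high)
  # numerator: planted punctum intensity sum; denominator: cell area
  expect_equal(got$sum_high, tr$sum_punctum_intensity)
  expect_identical(got$n_low, as.integer(tr$n_cell_pixels))
  expect_equal(got$ratio, tr$sum_punctum_intensity / tr$n_cell_pixels)
})

test_that("a = 0 fields are control-like: ratio near zero at recommended thresholds", {
  fld <- gen_filipin_field(filipin_field_spec(accumulation = 0, seed = 5))
  expect_identical(fld$truth$n_puncta, 0L)
  got <- lso_compartment_ratio(fld$pixels, fld$truth$t_low,
                               fld$truth$t_high)
  # numerator can only come from the additive-noise tail
  expect_lt(got$ratio, 1)
})

test_that("infeasible cell packing raises a generation error", {
  spec <- filipin_field_spec(width = 64L, height = 64L, n_cells = 40L,
                             cell_radius_range = c(15, 20), seed = 1)
  expect_error(gen_filipin_field(spec), class = "npcquant_generation_error")
})

test_that("gen_coloc_pair plants the requested correlation", {
  # rho = 1: affinely identical channels
  p <- gen_coloc_pair(coloc_spec(1, 2500, seed = 2))
  expect_equal(pearson_colocalization(p$ch1, p$ch2)$r, 1)
  # rho = 0 at n = 1e4: |r| small across seeds
  r0 <- vapply(1:20, function(s)
    with(gen_coloc_pair(coloc_spec(0, 10000, seed = s)),
         pearson_colocalization(ch1, ch2)$r), numeric(1))
  expect_gte(mean(abs(r0) < 0.03), 0.95)
  # rho = 0.8: Fisher-z interval
  r8 <- with(gen_coloc_pair(coloc_spec(0.8, 10000, seed = 4)),
             pearson_colocalization(ch1, ch2)$r)
  expect_gt(r8, 0.77); expect_lt(r8, 0.83)
  # negative correlation comes out negative
  rn <- with(gen_coloc_pair(coloc_spec(-0.6, 10000, seed = 4)),
             pearson_colocalization(ch1, ch2)$r)
  expect_lt(rn, -0.55)
  expect_error(coloc_spec(0.5, 1), class = "npcquant_generation_error")
  expect_error(coloc_spec(1.5), class = "npcquant_validation_error")
})

test_that("gen_blot_dataset recovers planted folds and fractions", {
  # CV = 0: folds and fractions are exact
  exact <- gen_blot_dataset(blot_spec(conditions = c("DMSO", "t1", "t2"),
                                      fold_changes = c(1, 2.5, 0.5),
                                      f_R = c(0.9, 0.25, 0.5),
                                      cv = 0, seed = 1))
  summ <- summarize_blot(exact$levels, "DMSO")
  expect_equal(summ$conditions$fold_change[
    match(c("t1", "t2"), summ$conditions$condition)], c(2.5, 0.5))
  fr <- glycoform_fractions(exact$glycoforms$endoH_R,
                            exact$glycoforms$endoH_S)
  expect_equal(fr$f_R[exact$glycoforms$condition == "t1"], rep(0.25, 4))
  # planted f_R = 0.25 at n = 6, CV 15%: mean within 0.05
  noisy <- gen_blot_dataset(blot_spec(conditions = c("DMSO", "t"),
                                      fold_changes = c(1, 1),
                                      f_R = c(0.9, 0.25),
                                      n_lanes = 6L, cv = 0.15, seed = 2))
  fr2 <- glycoform_fractions(noisy$glycoforms$endoH_R,
                             noisy$glycoforms$endoH_S)
  expect_lt(abs(mean(fr2$f_R[noisy$glycoforms$condition == "t"]) - 0.25),
            0.05)
})

test_that("gen_screen_table plants an exact hit count including boundary ties", {
  spec <- screen_spec(n_compounds = 300, n_hits = 10,
                      reference_energy = -11.3, seed = 6)
  tab <- gen_screen_table(spec)
  hits <- select_hits(tab, hit_criterion(-11.3))
  expect_identical(nrow(hits), 10L)
  expect_setequal(hits$compound_id, tab$compound_id[tab$is_planted_hit])
  # zero hits planted
  none <- gen_screen_table(screen_spec(n_compounds = 50, n_hits = 0, seed = 1))
  expect_identical(nrow(select_hits(none, hit_criterion(-11.3))), 0L)
  # all hits exactly at the reference: the inclusive rule keeps them
  ties <- gen_screen_table(screen_spec(n_compounds = 50, n_hits = 5,
                                       n_boundary = 5, seed = 1))
  kept <- select_hits(ties, hit_criterion(-11.3))
  expect_identical(nrow(kept), 5L)
  expect_true(all(kept$binding_energy == -11.3))
  expect_error(screen_spec(n_compounds = 5, n_hits = 6),
               class = "npcquant_validation_error")
})
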