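test_that("halogen templates carry the Br spacing and abundances", {
  t1 <- halogen_template(1L)
  expect_equal(t1$spacings, c(0, 1.99795), tolerance = 1e-5)
  expect_equal(t1$abundances, c(0.5069, 0.4931))
  t2 <- halogen_template(2L)
  expect_equal(t2$spacings, c(0, 1.99795, 3.99590), tolerance = 1e-5)
  expect_equal(t2$abundances, brute_force_br_pattern(2L)$abundance,
               tolerance = 1e-12)
  expect_error(halogen_template(3L), "1 or 2")
})

test_that("cosine score has the closed-form values and invariances", {
  t1 <- halogen_template(1L)$abundances
  expect_identical(score_isotope_match(t1, t1), 1)
  # observed (1, 0): cosine = 0.5069 / |template|
  expect_equal(score_isotope_match(c(1, 0), t1),
               0.5069 / sqrt(0.5069^2 + 0.4931^2), tolerance = 1e-12)
  expect_identical(score_isotope_match(7 * t1, t1), 1)
  expect_identical(score_isotope_match(c(0, 0), t1), 0)
  # score 1 iff proportional
  expect_lt(score_isotope_match(c(0.5069, 0.4932), t1) , 1)
  expect_equal(score_isotope_match(c(0.5069, 0.4932), t1), 1,
               tolerance = 1e-7)
})

test_that("noiseless doublets and triplets are classified with Br2 priority", {
  pk <- peak_list_for_test(c(223.9342, 225.9322), c(0.5069, 0.4931))
  cand <- find_halogen_signatures(pk)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_br, 1L)
  expect_gte(cand$score, 0.99)
  expect_equal(cand$mono_mz, 223.9342, tolerance = 1e-9)

  # di-Br triplet: one Br2 candidate, no Br1 sub-pairs
  br2 <- halogen_template(2L)
  pk2 <- peak_list_for_test(417.895 + br2$spacings, br2$abundances)
  cand2 <- find_halogen_signatures(pk2)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$n_br, 2L)
  expect_equal(sum(cand2$n_br == 1L), 0L)

  # M/M+1 carbon spacing with 1:1 ratio is not a Br signature
  pk3 <- peak_list_for_test(c(400, 401.003), c(1, 1))
  expect_equal(nrow(find_halogen_signatures(pk3)), 0L)
})

test_that("reported candidates respect the spacing invariant and scale invariance", {
  set.seed(9)
  tpl1 <- halogen_template(1L)
  tpl2 <- halogen_template(2L)
  planted <- c(300 + tpl1$spacings, 500 + tpl2$spacings)
  mz <- sort(c(runif(50, 100, 1000), planted))
  int <- runif(length(mz))
  int[match(planted, mz)] <- c(10 * tpl1$abundances, 20 * tpl2$abundances)
  pk <- peak_list_for_test(mz, int)
  cand <- find_halogen_signatures(pk)
  for (i in seq_len(nrow(cand))) {
    mzs <- c(cand$mz1[i], cand$mz2[i], cand$mz3[i])
    d <- diff(mzs[!is.na(mzs)])
    expect_true(all(abs(d - 1.99795) <= 0.05))
  }
  scaled <- find_halogen_signatures(peak_list_for_test(mz, 1e4 * int))
  expect_equal(scaled$mono_mz, cand$mono_mz)
  expect_equal(scaled$score, cand$score, tolerance = 1e-12)
})

test_that("de-replication removes decoys and lipid-explained envelopes, keeps true spikes", {
  lip <- default_lipid_background()
  decoy <- lip[lip$decoy & lip$decoy_pair == 1L, ]
  br_mz <- c(223.9342, 225.9322)
  pk <- peak_list_for_test(c(br_mz, decoy$mz),
                           c(0.5069 * 50, 0.4931 * 50, 30, 30))
  cand <- find_halogen_signatures(pk)
  expect_equal(nrow(cand), 2L)
  out <- dereplicate_lipids(cand, lip)
  expect_equal(out$removed[abs(out$mono_mz - decoy$mz[1L]) < 0.01], "lipid")
  expect_true(is.na(out$removed[abs(out$mono_mz - br_mz[1L]) < 0.01]))
  expect_equal(nrow(retained_candidates(out)), 1L)
  # empty lipid list leaves candidates unchanged
  expect_identical(dereplicate_lipids(cand, NULL)$removed, cand$removed)
  expect_identical(dereplicate_lipids(cand, numeric(0))$removed, cand$removed)
  # a lipid whose own envelope fits better than the Br template is flagged
  pc <- lip[lip$name == "PC(40)", ]
  env <- isotope_distribution(pc$formula, pc$adduct, prune = 1e-3)
  pk2 <- peak_list_for_test(env$mz[c(1, 3)], env$abundance[c(1, 3)])
  cand2 <- find_halogen_signatures(pk2, score_min = 0)
  out2 <- dereplicate_lipids(cand2, lip)
  expect_true(all(out2$removed == "lipid"))
})
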