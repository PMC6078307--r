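test_that("cohort spec rejects impossible settings", {
  expect_error(cohort_spec(n_subjects = 3), "at least 4")
  expect_error(cohort_spec(yfas_completion = 0), "positive")
  expect_error(cohort_spec(t_points = 4), "t_points")
  expect_error(cohort_spec(bmi_sd = -1), "positive")
  expect_error(cohort_spec(loadings = c(BMI = 1)), "strictly less than 1")
  expect_error(cohort_spec(effects = list(list(a = "BMI", b = "Indole",
                                               rho = 1.2))), "\\(-1, 1\\)")
  expect_error(cohort_spec(effects = list(
    list(a = "BMI", b = "Indole", rho = 0.5),
    list(a = "BMI", b = "YFAS", rho = 0.2))), "conflicting")
})

test_that("subject table reproduces the study margins", {
  subj <- generate_subjects(cohort_spec(seed = 1))
  expect_equal(nrow(subj), 63)
  expect_equal(sum(subj$sex == "M"), 29)
  expect_equal(sum(is.na(subj$YFAS)), 21)
  # missingness is assigned to the last subject ids
  expect_true(all(is.na(subj$YFAS[43:63])))
  expect_true(all(!is.na(subj$YFAS[1:42])))
  expect_true(all(subj$age >= 18 & subj$age <= 60))
  expect_true(all(subj$YFAS[!is.na(subj$YFAS)] %in% 0:7))
  expect_true(all(subj$HAD_anxiety %in% 0:21))
  expect_true(all(subj$Indole > 0 & subj$Skatole > 0 & subj$IAA > 0))

  big <- generate_subjects(cohort_spec(n_subjects = 1000, n_male = 460,
                                       yfas_completion = 1000, seed = 8))
  expect_lt(abs(mean(big$BMI) - 25.82) / 25.82, 0.1)
  expect_lt(abs(sd(big$BMI) - 4.93) / 4.93, 0.1)
  expect_lt(abs(mean(big$YFAS) - 1.24) / 1.24, 0.1)
  expect_lt(abs(sd(big$YFAS) - 1.25) / 1.25, 0.1)
  expect_lt(abs(mean(big$HAD_anxiety) - 4.25) / 4.25, 0.1)
  expect_lt(abs(sd(big$HAD_anxiety) - 3.41) / 3.41, 0.1)
})

test_that("generation is deterministic given (spec, seed)", {
  sp <- tiny_spec(seed = 11)
  expect_identical(generate_subjects(sp), generate_subjects(sp))
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$fibers, c2$fibers)
  c3 <- simulate_cohort(tiny_spec(seed = 12))
  expect_false(identical(c1$subjects$BMI, c3$subjects$BMI))
})

test_that("planted latent loadings are realized at large n", {
  sp <- cohort_spec(n_subjects = 1000, n_male = 500, yfas_completion = 1000,
                    seed = 7, loadings = c(BMI = 0.6))
  subj <- generate_subjects(sp)
  expect_lt(abs(cor(subj$latent, subj$BMI) - 0.6), 0.05)

  # pairwise plant: correlation between the two transformed variables
  sp2 <- cohort_spec(n_subjects = 1000, n_male = 500, yfas_completion = 1000,
                     seed = 9,
                     effects = list(list(a = "Indole", b = "BMI", rho = 0.5)))
  s2 <- generate_subjects(sp2)
  expect_lt(abs(cor(log(s2$Indole), s2$BMI) - 0.5), 0.05)
})

test_that("without planted effects the latent factor is inert", {
  rs <- vapply(1:200, function(i) {
    s <- generate_subjects(cohort_spec(seed = 100 + i))
    cor(s$latent, s$BMI)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)

  big <- generate_subjects(cohort_spec(n_subjects = 2000, n_male = 1000,
                                       yfas_completion = 2000, seed = 5))
  for (v in c("BMI", "HAD_anxiety", "Indole", "Skatole", "IAA")) {
    expect_lt(abs(cor(big$latent, big[[v]])), 0.05)
  }
})

test_that("time series honour the baseline correlation structure", {
  # flat baseline 0.1, no subject jitter: the designated pair's mean sample
  # correlation over the cohort recovers the baseline
  sp <- cohort_spec(n_subjects = 200, n_male = 100, yfas_completion = 200,
                    n_regions = 13, t_points = 120, seed = 21,
                    baseline_cor_range = c(0.1, 0.1), subject_cor_sd = 0,
                    fc_shifts = list(list(pair = c("L_NAcc", "R_NAcc"),
                                          beta = 0)))
  coh <- simulate_cohort(sp)
  i <- match("L_NAcc", coh$regions$label)
  j <- match("R_NAcc", coh$regions$label)
  rs <- vapply(coh$timeseries, function(ts) cor(ts[, i], ts[, j]), numeric(1))
  expect_lt(abs(mean(rs) - 0.1), 0.03)

  # identity baseline: off-diagonal correlations centred at zero
  sp0 <- cohort_spec(n_subjects = 50, n_male = 25, yfas_completion = 50,
                     n_regions = 13, t_points = 120, seed = 22,
                     baseline_cor_range = c(0, 0), subject_cor_sd = 0)
  coh0 <- simulate_cohort(sp0)
  offdiag <- vapply(coh0$timeseries, function(ts) {
    r <- cor(ts)
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(offdiag)), 0.02)

  # a planted shift couples the pair correlation to the latent factor
  sp1 <- cohort_spec(n_subjects = 300, n_male = 150, yfas_completion = 300,
                     n_regions = 13, t_points = 120, seed = 23,
                     baseline_cor_range = c(0.1, 0.1), subject_cor_sd = 0,
                     fc_shifts = list(list(pair = c("L_NAcc", "R_NAcc"),
                                           beta = 0.25)))
  coh1 <- simulate_cohort(sp1)
  rs1 <- vapply(coh1$timeseries, function(ts) cor(ts[, i], ts[, j]), numeric(1))
  expect_gt(cor(coh1$subjects$latent, rs1, method = "spearman"), 0.5)
})

test_that("fiber counts follow the Poisson intensity model", {
  # zero intensity everywhere -> all-zero matrices
  sp0 <- tiny_spec(seed = 31, fiber_lambda = 0, fiber_subject_sd = 0,
                   anat_exclude = 0)
  f0 <- simulate_cohort(sp0)$fibers
  expect_true(all(vapply(f0$counts, function(M) all(M == 0), logical(1))))

  # flat intensity 50, no jitter: each edge's cohort-mean count is ~50
  sp50 <- cohort_spec(n_subjects = 500, n_male = 250, yfas_completion = 500,
                      n_regions = 13, t_points = 40, seed = 32,
                      fiber_lambda = 50, fiber_subject_sd = 0,
                      anat_exclude = 0)
  regions <- build_parcellation(13)
  f50 <- generate_fiber_counts(generate_subjects(sp50), regions, sp50)
  edge_means <- Reduce(`+`, f50$counts) / length(f50$counts)
  expect_lt(abs(mean(edge_means[upper.tri(edge_means)]) - 50), 2)

  # symmetry and zero diagonal always hold
  for (M in f50$counts[1:5]) {
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
  }

  # planted multiplicative effect: counts track the latent factor
  spg <- cohort_spec(n_subjects = 400, n_male = 200, yfas_completion = 400,
                     n_regions = 13, t_points = 40, seed = 33,
                     fiber_lambda = 50, fiber_subject_sd = 0, anat_exclude = 0,
                     fiber_effects = list(list(pair = c("L_Amg", "L_NAcc"),
                                               gamma = 0.3)))
  subj <- generate_subjects(spg)
  fg <- generate_fiber_counts(subj, regions, spg)
  i <- match("L_Amg", regions$label)
  j <- match("L_NAcc", regions$label)
  cnt <- vapply(fg$counts, function(M) M[i, j], numeric(1))
  expect_gt(cor(subj$latent, cnt, method = "spearman"), 0.5)

  expect_error(generate_fiber_counts(subj, regions,
                                     tiny_spec(fiber_lambda = -5)),
               "nonnegative")
})

test_that("marginal moment calibration hits discretized targets", {
  par <- bgmnet:::calibrate_discrete(1.24, 1.25, 0, 7)
  mm <- bgmnet:::discretized_moments(par[1], par[2], 0, 7)
  expect_lt(abs(mm[1] - 1.24), 0.02)
  expect_lt(abs(mm[2] - 1.25), 0.02)
})

test_that("block-level simulation plants brain-metric correlations", {
  sp <- cohort_spec(seed = 41, n_subjects = 1000, n_male = 500,
                    yfas_completion = 1000, anat_exclude = 0,
                    effects = list(list(a = "Indole", b = "S_R_NAcc.func",
                                        rho = 0.6)))
  blk <- simulate_blocks(sp)
  expect_s3_class(blk, "bgm_blocks")
  expect_equal(nrow(blk$brain_meta), 48)
  r <- cor(log(blk$metabolite$Indole), log(blk$brain[["S_R_NAcc.func"]]))
  expect_lt(abs(r - 0.6), 0.05)
  # untouched brain variables stay null
  expect_lt(abs(cor(blk$metabolite$Skatole, blk$brain[["S_L_Amg.func"]])), 0.1)
})
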