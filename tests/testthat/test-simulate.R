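test_that("reference genotypes respect sex and panel structure", {
  set.seed(31)
  f <- sample_reference_profile("F1", "female")
  expect_equal(f$sex, "female")
  expect_length(profile_alleles(f, "DYS391"), 0)
  expect_equal(profile_alleles(f, "Amelogenin"), "X")

  m <- sample_reference_profile("M1", "male")
  expect_setequal(profile_alleles(m, "Amelogenin"), c("X", "Y"))
  for (loc in panel_loci(fusion6c_panel(), "y_str"))
    expect_length(profile_alleles(m, loc), 1)

  counts <- vapply(1:50, function(i)
    expected_allele_count(sample_reference_profile("S", "female")),
    numeric(1))
  expect_true(all(counts >= 23 & counts <= 46))
})

test_that("mean expected count matches the distinct-draw expectation", {
  # with 8 equifrequent alleles, E(distinct of 2 draws) = 2 - 1/8 per locus
  set.seed(101)
  counts <- vapply(1:2000, function(i)
    expected_allele_count(sample_reference_profile("S", "male")),
    numeric(1))
  expect_equal(mean(counts), 23 * (2 - 1 / 8), tolerance = 0.2 / 43.125)
})

test_that("identity and null detection limits are exact", {
  set.seed(7)
  ref <- sample_reference_profile("M1", "male")

  all_on <- simulate_evidence(ref, sim_params(1, dropin_rate = 0))
  rec1 <- compare_profiles(all_on, ref)
  expect_equal(rec1$recovery_pct, 100)
  expect_equal(rec1$drop_in, 0)
  expect_equal(rec1$detected, rec1$expected)

  all_off <- simulate_evidence(ref, sim_params(0, dropin_rate = 0))
  rec0 <- compare_profiles(all_off, ref)
  expect_equal(rec0$recovery_pct, 0)
  expect_equal(nrow(all_off$calls), 0)
})

test_that("mean recovery tracks the detection probability", {
  set.seed(55)
  ref <- sample_reference_profile("M1", "male")
  params <- sim_params(0.8, dropin_rate = 0)
  recov <- vapply(1:500, function(i) {
    compare_profiles(simulate_evidence(ref, params), ref)$recovery_pct
  }, numeric(1))
  expect_equal(mean(recov), 80, tolerance = 2 / 80)
})

test_that("drop-in counts are Poisson with the configured mean", {
  set.seed(66)
  ref <- sample_reference_profile("M1", "male")
  params <- sim_params(1, dropin_rate = 2)
  din <- vapply(1:2000, function(i)
    compare_profiles(simulate_evidence(ref, params), ref)$drop_in,
    numeric(1))
  expect_equal(mean(din), 2, tolerance = 0.1)
  # drop-ins are never reference alleles, so detection stays complete
  expect_true(all(din >= 0))

  none <- vapply(1:50, function(i)
    compare_profiles(simulate_evidence(
      ref, sim_params(0.5, dropin_rate = 0)), ref)$drop_in, numeric(1))
  expect_true(all(none == 0))
})

test_that("shedder multipliers scale the effective detection probability", {
  set.seed(88)
  ref <- sample_reference_profile("M1", "male")
  params <- sim_params(0.5, dropin_rate = 0,
                       shedder_multipliers = c(high = 1.5,
                                               intermediate = 1,
                                               low = 0.5))
  mean_rec <- function(shedder) mean(vapply(1:300, function(i)
    compare_profiles(simulate_evidence(ref, params, shedder),
                     ref)$recovery_pct, numeric(1)))
  expect_equal(mean_rec("high"), 75, tolerance = 0.05)
  expect_equal(mean_rec("low"), 25, tolerance = 0.08)
  # multipliers above 1/p clamp at certain detection
  clamped <- sim_params(0.9, dropin_rate = 0,
                        shedder_multipliers = c(high = 5, intermediate = 1,
                                                low = 0.5))
  rec <- compare_profiles(simulate_evidence(ref, clamped, "high"), ref)
  expect_equal(rec$recovery_pct, 100)
})

test_that("a simulated study carries the expected structure", {
  records <- simulate_study(n_subjects = 2, seed = 12)
  expect_equal(nrow(records), 4)
  expect_setequal(records$condition, c("HSWW", "HSWA"))
  expect_setequal(records$sex, c("male", "female"))

  # identical seed reproduces the study exactly
  again <- simulate_study(n_subjects = 2, seed = 12)
  attr(records, "profiles") <- NULL
  attr(again, "profiles") <- NULL
  expect_identical(records, again)

  # post-wash drop-in is structurally absent when its rate is zero
  big <- simulate_study(n_subjects = 12, seed = 3)
  expect_equal(sum(big$drop_in[big$condition == "HSWA"]), 0)
})

test_that("study-scenario parameters separate the two conditions", {
  for (seed in 1:5) {
    records <- simulate_study(n_subjects = 12, seed = seed)
    pre <- truncated_median(recovery_percentages(records, "HSWW"))
    post <- truncated_median(recovery_percentages(records, "HSWA"))
    expect_gt(pre, post)
    expect_gt(pre - post, 50)
  }
})

test_that("the pooled estimator recovers the detection probability", {
  p_true <- 0.6
  for (seed in 1:20) {
    records <- simulate_study(
      n_subjects = 100,
      params_pre = sim_params(p_true, dropin_rate = 0),
      params_post = sim_params(0.04, dropin_rate = 0),
      shedder_assignment = rep("intermediate", 100),
      seed = seed)
    p_hat <- estimate_detection_probability(
      records[records$condition == "HSWW", ])
    expect_lte(abs(p_hat - p_true), 0.05)
  }
})

test_that("all generated profiles satisfy the domain invariants", {
  set.seed(14)
  for (i in 1:25) {
    sex <- sample(c("male", "female"), 1)
    ref <- sample_reference_profile("S", sex)
    ev <- simulate_evidence(ref, sim_params(0.7, dropin_rate = 1))
    for (p in list(ref, ev)) {
      # re-running the validating constructor must succeed unchanged
      expect_true(profiles_equal(p, str_profile("S", p$calls, sex = p$sex)))
      aut <- panel_loci(fusion6c_panel(), "autosomal")
      per_locus <- table(p$calls$locus[p$calls$locus %in% aut])
      if (identical(p, ref)) expect_true(all(per_locus <= 2))
      if (sex == "female")
        expect_false(any(p$calls$locus %in%
                           panel_loci(fusion6c_panel(), "y_str")))
    }
    expect_true(all(is.na(ref$calls$height)))
    expect_true(all(ev$calls$height >= 0))
  }
})

test_that("mixtures sum contributor weights into peak heights", {
  set.seed(19)
  a <- sample_reference_profile("A", "male")
  b <- sample_reference_profile("B", "female")
  quiet <- sim_params(1, height_mean = 1000, height_cv = 0)

  mix <- make_mixture(list(a, b), c(10, 1), quiet)
  shared <- intersect(paste(a$calls$locus, a$calls$allele),
                      paste(b$calls$locus, b$calls$allele))
  key <- paste(mix$calls$locus, mix$calls$allele)
  a_only <- key %in% setdiff(paste(a$calls$locus, a$calls$allele), shared)
  b_only <- key %in% setdiff(paste(b$calls$locus, b$calls$allele), shared)
  expect_true(all(mix$calls$height[a_only] == 10000))
  expect_true(all(mix$calls$height[b_only] == 1000))
  expect_true(all(mix$calls$height[key %in% shared] == 11000))

  twin <- make_mixture(list(a, a), c(3, 2), quiet, sample_id = "T")
  expect_equal(nrow(twin$calls), nrow(a$calls))
  expect_true(all(twin$calls$height == 5000))

  expect_error(make_mixture(list(a), 1, quiet), "two contributors")
  expect_error(make_mixture(list(a, b), c(1, 2, 3), quiet), "ratios")
})

test_that("10:1 mixtures yield the major's genotype in nearly all seeds", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    major <- sample_reference_profile("A", "male")
    minor <- sample_reference_profile("B", "male")
    mix <- make_mixture(list(major, minor), c(10, 1), sim_params(1))
    got <- extract_major_contributor(mix)
    if (is.null(got)) next
    aut <- panel_loci(fusion6c_panel(), "autosomal")
    want <- major$calls[major$calls$locus %in% aut, c("locus", "allele")]
    if (identical(paste(got$calls$locus, got$calls$allele),
                  paste(want$locus, want$allele)))
      hits <- hits + 1L
  }
  expect_gte(hits, 95)
})
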