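# reference with 19 heterozygous + 4 homozygous autosomal loci -> E = 42
full_reference <- function(sample_id = "R1", sex = "male") {
  panel <- fusion6c_panel()
  aut <- panel_loci(panel, "autosomal")
  loci <- c(
    lapply(seq_along(aut), function(i)
      if (i <= 19) c("10", "12") else "11"),
    list(DYS391 = "11", DYS576 = "17", DYS570 = "19",
         Amelogenin = c("X", "Y"))
  )
  names(loci)[seq_along(aut)] <- aut
  quick_profile(sample_id, loci, sex = sex)
}

test_that("expected allele count follows zygosity and excludes sex markers", {
  ref <- full_reference()
  expect_equal(expected_allele_count(ref), 2 * 19 + 4)

  het <- quick_profile("H", stats::setNames(
    rep(list(c("10", "12")), 23), panel_loci(fusion6c_panel(), "autosomal")))
  expect_equal(expected_allele_count(het), 46)

  hom <- quick_profile("H", stats::setNames(
    rep(list("10"), 23), panel_loci(fusion6c_panel(), "autosomal")))
  expect_equal(expected_allele_count(hom), 23)

  y_only <- quick_profile("Y", list(DYS391 = "11"), sex = "male")
  expect_error(expected_allele_count(y_only), "no autosomal calls")
})

test_that("comparison handles identity, empty and drop-in cases", {
  ref <- full_reference()

  same <- compare_profiles(ref, ref)
  expect_equal(same$detected, same$expected)
  expect_equal(same$drop_in, 0)
  expect_equal(same$drop_out, 0)
  expect_equal(same$recovery_pct, 100)

  none <- compare_profiles(quick_profile("R1", list()), ref)
  expect_equal(none$detected, 0)
  expect_equal(none$drop_out, none$expected)
  expect_equal(none$recovery_pct, 0)

  ev <- str_profile("R1", rbind(ref$calls,
                                data.frame(locus = "vWA", allele = "99",
                                           height = NA_real_)),
                    sex = "male")
  extra <- compare_profiles(ev, ref)
  expect_equal(extra$drop_in, 1)
  expect_equal(extra$drop_out, 0)

  # evidence at a locus the reference lacks counts as drop-in
  ref2 <- quick_profile("R2", list(vWA = c("14", "16")))
  ev2 <- quick_profile("R2", list(vWA = "14", TH01 = "7"))
  rec2 <- compare_profiles(ev2, ref2)
  expect_equal(rec2$drop_in, 1)
  expect_equal(rec2$detected, 1)

  # Y-STR and amelogenin calls never enter the counts
  detail <- attr(same, "detail")
  expect_false(any(detail$counted[detail$kind != "autosomal"]))
  expect_equal(sum(detail$expected[detail$counted]), same$expected)
})

test_that("locus scores follow the 1 / 0.5 / 0 detection rule", {
  ref <- quick_profile("R", list(vWA = c("12", "14"), TH01 = "11"))
  ev_half <- quick_profile("R", list(vWA = "12"))
  ev_hom <- quick_profile("R", list(TH01 = "11"))
  ev_none <- quick_profile("R", list())

  expect_equal(locus_score(ev_half, ref, "vWA"), 0.5)
  expect_equal(locus_score(ev_hom, ref, "TH01"), 1)
  expect_equal(locus_score(ev_none, ref, "vWA"), 0)
  expect_equal(locus_score(quick_profile("R", list(vWA = c("12", "14"))),
                           ref, "vWA"), 1)
  expect_error(locus_score(ev_half, ref, "D3S1358"), "no genotype")
  expect_error(locus_score(ev_half, ref, "Amelogenin"), "not an STR")
})

test_that("score matrices cover all STR loci and blank female Y cells", {
  ref_m <- full_reference("M1", "male")
  ref_f <- quick_profile("F1", list(vWA = c("12", "14"), TH01 = "9"),
                         sex = "female")
  m <- score_matrix(list(
    list(evidence = ref_m, reference = ref_m),
    list(evidence = quick_profile("F1", list()), reference = ref_f)
  ))
  expect_equal(dim(m), c(26, 2))
  expect_true(all(m[panel_loci(fusion6c_panel(), "autosomal"), "M1"] == 1))
  expect_true(all(is.na(m[c("DYS391", "DYS576", "DYS570"), "F1"])))
  expect_true(all(m[c("vWA", "TH01"), "F1"] == 0))

  # one heterozygote losing one allele yields exactly one 0.5 cell
  ev <- str_profile("M1", ref_m$calls[!(ref_m$calls$locus == "vWA" &
                                          ref_m$calls$allele == "12"), ],
                    sex = "male")
  m2 <- score_matrix(list(list(evidence = ev, reference = ref_m)))
  expect_equal(sum(m2 == 0.5, na.rm = TRUE), 1)
  expect_equal(m2["vWA", 1], 0.5)
})

test_that("comparison agrees with a brute-force oracle on random profiles", {
  set.seed(2041)
  for (i in 1:1000) {
    pair <- random_small_pair()
    got <- compare_profiles(pair$evidence, pair$reference)
    want <- oracle_compare(pair$evidence, pair$reference)
    expect_equal(got$expected, want$expected)
    expect_equal(got$detected, want$detected)
    expect_equal(got$drop_in, want$drop_in)
    expect_equal(got$drop_out, want$drop_out)
  }
})

test_that("removing an evidence allele never increases detected or drop-in", {
  set.seed(77)
  for (i in 1:50) {
    pair <- random_small_pair()
    if (!nrow(pair$evidence$calls)) next
    full <- compare_profiles(pair$evidence, pair$reference)
    drop <- sample.int(nrow(pair$evidence$calls), 1L)
    smaller <- str_profile("R1", pair$evidence$calls[-drop, ])
    less <- compare_profiles(smaller, pair$reference)
    expect_lte(less$detected, full$detected)
    expect_lte(less$drop_in, full$drop_in)
  }
})

test_that("detected counts respect the score-derived bounds on random pairs", {
  set.seed(90)
  for (i in 1:50) {
    pair <- random_small_pair()
    m <- score_matrix(list(pair))
    aut <- panel_loci(fusion6c_panel(), "autosomal")
    sc <- m[aut, 1]
    n05 <- sum(sc == 0.5, na.rm = TRUE)
    n1 <- sum(sc == 1, na.rm = TRUE)
    d <- compare_profiles(pair$evidence, pair$reference)$detected
    expect_gte(d, n05 + n1)
    expect_lte(d, n05 + 2 * n1)
  }
})
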