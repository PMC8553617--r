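ex <- atm_study_dataset()
fit <- atm_burden(ex$cohort, ex$reference, classified = ex$classified)

test_that("grouped analyses rebuild the study's 2x2 allele tables", {
  df <- as.data.frame(fit)
  lof_all <- df[df$label == "LOF, all cases", ]
  expect_equal(unlist(lof_all[c("a", "b", "c", "d")], use.names = FALSE),
               c(20, 4188, 237, 128969))
  vus_fam <- df[df$label == "VUS, fam+MPM", ]
  expect_equal(unlist(vus_fam[c("a", "b", "c", "d")], use.names = FALSE),
               c(135, 2441, 4268, 124938))
  # allele conservation: totals are exactly 2 x individuals
  expect_equal(lof_all$a + lof_all$b, 2 * sum(ex$cohort$n_individuals))
  expect_equal(vus_fam$a + vus_fam$b,
               2 * sum(ex$cohort$n_individuals[c("familial", "MPM")]))
})

test_that("subset and domain decompositions are consistent", {
  df <- as.data.frame(fit)
  a_of <- function(lab) df$a[df$label == lab]
  # fam+MPM + sporadic = all
  obs <- ex$cohort$observations
  lof_ids <- ex$classified$variant_id[ex$classified$category == "LOF"]
  spor_lof <- sum(obs$variant_id %in% lof_ids & obs$stratum == "sporadic")
  expect_equal(a_of("LOF, all cases"), a_of("LOF, fam+MPM") + spor_lof)
  # VUS in-domain + out-domain = VUS total, in both subsets
  expect_equal(a_of("VUS in-domain, all cases") +
                 a_of("VUS out-domain, all cases"), a_of("VUS, all cases"))
  expect_equal(a_of("VUS in-domain, fam+MPM") +
                 a_of("VUS out-domain, fam+MPM"), a_of("VUS, fam+MPM"))
})

test_that("plan validation mirrors the study design", {
  expect_error(analysis_plan("LOF", domain = "in_domain"), "VUS")
  expect_error(analysis_plan("VUS", min_cases_individual = 0), ">= 1")
  # a cohort with zero carriers still tests cleanly (p = 1)
  empty <- cohort_dataset(
    data.frame(individual_id = character(), center = character(),
               stratum = character(), variant_id = character(),
               zygosity = character()),
    ex$cohort$variants, c(familial = 10L, MPM = 5L, sporadic = 5L))
  r <- atm_burden(empty, reference_counts(
    data.frame(variant_id = "x", cdna_hgvs = "c.1A>G", consequence = "nonsense",
               allele_count = 0, allele_number = 1000, homozygote_count = 0)),
    plans = list(analysis_plan("LOF")))
  expect_equal(r$results[[1]]$p_value, 1)
})

test_that("recurrent-variant selection counts distinct individuals", {
  vus <- select_recurrent_variants(ex$cohort, ex$classified, 3, "VUS")
  expect_length(vus, 13)
  expect_true("c.5750G>C" %in% vus)
  # variants in exactly 2 cases are not selected at min 3
  two_case <- select_recurrent_variants(ex$cohort, ex$classified, 2, "VUS")
  expect_gt(length(two_case), length(vus))
  expect_false(any(setdiff(two_case, vus) %in% vus))
  # c.3576G>A is carried by 3 cases in the LOF universe
  lof3 <- select_recurrent_variants(ex$cohort, ex$classified, 3, "LOF")
  expect_equal(lof3, "c.3576G>A")
})

test_that("per-variant tables respect margins and reference fallbacks", {
  r <- per_variant_test("c.3576G>A", ex$cohort, ex$reference)
  expect_equal(unname(r$table["a"]), 3)
  expect_equal(round(r$case_af, 4), 7e-04)
  expect_lte(unname(r$table["a"]), sum(allele_totals(ex$cohort)))

  # absent from the reference: AC 0 against the aggregate AN, no correction
  # needed for the exact p
  r2 <- per_variant_test("c.1368A>C", ex$cohort, ex$reference)
  expect_equal(unname(r2$table["c"]), 0)
  expect_equal(unname(r2$table["c"] + r2$table["d"]), 129206)
  expect_lte(r2$p_value, 1)
  expect_error(per_variant_test("c.999999A>G", ex$cohort, ex$reference),
               "not carried")
})

test_that("the two-center internal comparison reproduces published odds", {
  tc <- atm_two_center_dataset()
  r <- internal_case_control(tc$cases, tc$controls, tc$classified, "LOF")
  expect_equal(unname(r$table), c(12, 2272, 6, 2886))
  expect_equal(round(r$odds_ratio, 2), 2.54)
  rf <- internal_case_control(tc$cases, tc$controls, tc$classified, "LOF",
                              "fam_mpm")
  expect_equal(round(rf$odds_ratio, 2), 3.67)
  expect_lt(rf$p_value, 0.05)

  # identical carriage gives OR 1, p 1
  same <- internal_case_control(tc$cases, cohort_dataset(
    data.frame(individual_id = paste0("X_", tc$cases$observations$individual_id),
               center = "B", stratum = "sporadic",
               variant_id = tc$cases$observations$variant_id,
               zygosity = "het"),
    tc$cases$variants, c(sporadic = 1142L)), tc$classified, "LOF")
  expect_equal(as.numeric(same$odds_ratio), 1)
  expect_equal(same$p_value, 1)

  # overlapping individual ids across cohorts are rejected
  expect_error(internal_case_control(tc$cases, tc$cases, tc$classified),
               "both cohorts")
})

test_that("lollipop export orders placed variants and sidelines the rest", {
  lp <- export_lollipop(ex$cohort, ex$classified)
  expect_true(all(diff(lp$placed$protein_position) >= 0))
  expect_true(all(lp$placed$category %in% c("LOF", "VUS")))
  # one row per variant, carriers aggregated over duplicates
  expect_equal(anyDuplicated(lp$placed$variant_id), 0L)
  expect_equal(lp$placed$case_count[lp$placed$variant_id == "c.3576G>A"], 3L)
  # splice variants without a protein change still get a cDNA anchor;
  # the aggregate totals add up across both tables
  # per-variant distinct carriers sum to the 20 LOF + 192 VUS alleles
  # (every carrier is het, and no individual carries one variant twice)
  expect_equal(sum(lp$placed$case_count) + sum(lp$unplaced$case_count),
               20L + 192L)
})
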