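test_that("consequence derivation follows HGVS structure", {
  expect_equal(derive_consequence("c.7928-2A>T"), "splice_acceptor")
  expect_equal(derive_consequence("c.7629 + 2T>C"), "splice_donor")
  expect_equal(derive_consequence("c.8850+2dup"), "splice_donor")
  expect_equal(derive_consequence("c.1368A>C", "p.(Leu456Phe)"), "missense")
  expect_equal(derive_consequence("c.3275C>A", "p.Ser1092*"), "nonsense")
  expect_equal(derive_consequence("c.4451delT", "p.(Met1484Argfs*15)"),
               "frameshift")
  expect_equal(derive_consequence("c.3576G>A", "p.(Lys1192=)"), "synonymous")
  # in-frame deletion falls through to "other"
  expect_equal(derive_consequence("c.3x", "p.(Ser1135_Lys1195del58)"),
               "other")
  expect_error(derive_consequence("3576G>A"), "c\\.")
})

test_that("LOF assignment and curated overrides behave as specified", {
  expect_equal(classify_consequence(c("nonsense", "frameshift",
                                      "splice_acceptor", "splice_donor")),
               rep("LOF", 4))
  expect_equal(classify_consequence("missense"), "missense_candidate")
  expect_equal(classify_consequence(c("synonymous", "other")),
               rep("excluded_other_class", 2))

  # c.3576G>A: nominally synonymous, curated override makes it LOF
  v <- mk_variants("c.3576G>A", "synonymous", "p.(Lys1192=)")
  out <- classify_variants(v)
  expect_equal(out$category, "LOF")
  expect_equal(out$consequence, "splice_donor")
  # without the override it is excluded
  expect_equal(classify_variants(v, overrides = NULL)$category,
               "excluded_other_class")
})

test_that("missense frequency and homozygote filters use strict thresholds", {
  # AF 0.006 > 0.005 -> common; hom 3 > 2 -> homozygous excess;
  # AF exactly 0.005 with 2 homozygotes passes both
  expect_equal(apply_missense_filters(600, 100000, 0), "excluded_common")
  expect_equal(apply_missense_filters(100, 100000, 3), "excluded_homozygous")
  expect_equal(apply_missense_filters(500, 100000, 2), "VUS")
  # absent from the reference: AF treated as 0, retained
  expect_equal(apply_missense_filters(NA, NA, NA), "VUS")
  expect_error(apply_missense_filters(0, 0, 0), "allele_number")

  ref <- reference_counts(data.frame(variant_id = "c.5750G>C",
                                     allele_count = 6, allele_number = 129206,
                                     homozygote_count = 0))
  out <- classify_variants(mk_variants("c.5750G>C", "missense",
                                       "p.(Arg1917Thr)"), ref)
  expect_equal(out$category, "VUS")
})

test_that("provenance partition is exact set arithmetic", {
  expect_equal(partition_provenance(c("A", "B"), c("B", "C"))[1:3],
               list(study_only = 1L, reference_only = 1L, both = 1L))
  expect_equal(partition_provenance(c("A", "B"), character())[1:3],
               list(study_only = 2L, reference_only = 0L, both = 0L))
  # study universe: 18 case-seen and 144 reference-seen LOF keys sharing 6
  cs <- sprintf("V%03d", 1:18)
  rf <- c(sprintf("V%03d", 1:6), sprintf("R%03d", 1:138))
  pv <- partition_provenance(cs, rf)
  expect_equal(pv, list(study_only = 12L, reference_only = 138L, both = 6L,
                        total = 156L))
})

test_that("classification partitions any universe, matching a naive oracle", {
  set.seed(11)
  n <- 200
  cons <- sample(CONSEQUENCES, n, replace = TRUE)
  ids <- sprintf("c.%dG>A", seq_len(n) * 7L)
  variants <- data.frame(variant_id = ids, cdna_hgvs = ids,
                         protein_hgvs = NA, consequence = cons,
                         stringsAsFactors = FALSE)
  in_ref <- runif(n) < 0.6
  ref <- reference_counts(data.frame(
    variant_id = ids[in_ref],
    allele_count = rbinom(sum(in_ref), 2000, 0.2),
    allele_number = 200000L,
    homozygote_count = sample(0:4, sum(in_ref), replace = TRUE)))
  ref$homozygote_count <- pmin(ref$homozygote_count,
                               ref$allele_count %/% 2L)
  ref <- reference_counts(ref)

  out <- classify_variants(variants, ref, overrides = NULL)
  # partition completeness: every variant in exactly one category
  expect_equal(nrow(out), n)
  expect_true(all(out$category %in% c("LOF", "VUS", "excluded_common",
                                      "excluded_homozygous",
                                      "excluded_other_class")))
  expect_equal(sum(table(out$category)), n)

  # naive sequential re-implementation of the rules, one variant at a time
  naive <- vapply(seq_len(n), function(i) {
    cq <- cons[i]
    if (cq %in% c("nonsense", "frameshift", "splice_acceptor",
                  "splice_donor")) return("LOF")
    if (cq != "missense") return("excluded_other_class")
    j <- match(ids[i], ref$variant_id)
    af <- if (is.na(j)) 0 else ref$allele_count[j] / ref$allele_number[j]
    hm <- if (is.na(j)) 0 else ref$homozygote_count[j]
    if (af > 0.005) "excluded_common"
    else if (hm > 2) "excluded_homozygous"
    else "VUS"
  }, "")
  expect_equal(out$category, naive)
})

test_that("raising the AF cutoff never reclassifies VUS as common", {
  set.seed(12)
  ids <- sprintf("c.%dG>A", 1:50 * 3L)
  variants <- mk_variants(ids, "missense")
  ref <- reference_counts(data.frame(
    variant_id = ids, allele_count = rbinom(50, 10000, 0.05),
    allele_number = 1000000L, homozygote_count = 0L))
  lo <- classify_variants(variants, ref, overrides = NULL, af_cutoff = 0.0004)
  hi <- classify_variants(variants, ref, overrides = NULL, af_cutoff = 0.0006)
  was_vus <- lo$category == "VUS"
  expect_true(all(hi$category[was_vus] == "VUS"))
})

test_that("curated overrides are idempotent", {
  ex <- atm_study_dataset()
  once <- classify_variants(ex$cohort$variants)
  # applying the override table to the already-overridden consequences
  v2 <- ex$cohort$variants
  v2$consequence <- once$consequence
  twice <- classify_variants(v2)
  expect_equal(twice$category, once$category)
  expect_equal(twice$consequence, once$consequence)
})
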