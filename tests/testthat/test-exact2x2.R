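test_that("allele and carrier frequencies are exact quotients", {
  expect_equal(allele_frequency(20, 4208), 20 / 4208)
  expect_equal(round(allele_frequency(20, 4208), 3), 0.005)
  expect_equal(round(allele_frequency(192, 4208), 3), 0.046)
  expect_equal(allele_frequency(0, 100), 0)
  expect_error(allele_frequency(1, 0), "positive")

  expect_equal(round(carrier_frequency(20, 2104), 2), 0.95)
  expect_equal(carrier_frequency(14, 1288), 100 * 14 / 1288)
  expect_equal(carrier_frequency(0, 50), 0)
  expect_error(carrier_frequency(1, 0), "positive")
})

test_that("sample odds ratio reproduces the study estimates", {
  expect_equal(round(sample_odds_ratio(20, 4188, 237, 128969), 2), 2.6,
               ignore_attr = TRUE)
  expect_equal(round(sample_odds_ratio(12, 2272, 6, 2886), 2), 2.54,
               ignore_attr = TRUE)
  # equal row proportions give OR 1
  expect_equal(sample_odds_ratio(5, 10, 50, 100), 1, ignore_attr = TRUE)
  # zero-cell policy: Haldane +0.5 applied and flagged
  or0 <- sample_odds_ratio(0, 10, 5, 10)
  expect_true(attr(or0, "haldane"))
  expect_equal(as.numeric(or0), (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(sample_odds_ratio(0, 10, 5, 10, haldane = FALSE), "Haldane")
  expect_error(sample_odds_ratio(0, 0, 0, 0), "all-zero")
})

test_that("two-sided exact p matches enumeration and fisher.test", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(3, 7, 7, 3), brute_fisher_p(3, 7, 7, 3),
               tolerance = 1e-12)
  p <- fisher_exact_two_sided(20, 4188, 237, 128969)
  expect_equal(format(p, digits = 2, scientific = TRUE), "2.2e-04")
  expect_equal(p, stats::fisher.test(matrix(c(20, 4188, 237, 128969), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-10)

  # sweep of small tables against the independent enumeration oracle and
  # the stats::fisher.test cross-check
  set.seed(3)
  for (i in 1:60) {
    tb <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(tb[c(1, 3)]) == 0 || sum(tb[c(2, 4)]) == 0 ||
        sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next
    p1 <- fisher_exact_two_sided(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p1, brute_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    expect_equal(p1, stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact p is symmetric under transposition; OR inverts on row swap", {
  set.seed(4)
  for (i in 1:25) {
    tb <- as.integer(sample(1:15, 4, replace = TRUE))
    expect_equal(fisher_exact_two_sided(tb[1], tb[2], tb[3], tb[4]),
                 fisher_exact_two_sided(tb[1], tb[3], tb[2], tb[4]),
                 tolerance = 1e-12)
    expect_equal(as.numeric(sample_odds_ratio(tb[3], tb[4], tb[1], tb[2])),
                 1 / as.numeric(sample_odds_ratio(tb[1], tb[2], tb[3], tb[4])),
                 tolerance = 1e-12)
  }
})

test_that("conditional MLE and conditional-exact CI match fisher.test", {
  f <- stats::fisher.test(matrix(c(20, 4188, 237, 128969), 2, byrow = TRUE))
  expect_equal(conditional_mle_odds_ratio(20, 4188, 237, 128969),
               unname(f$estimate), tolerance = 1e-4)
  ci <- odds_ratio_ci(20, 4188, 237, 128969)
  # fisher.test's own root-finder carries ~1e-4 tolerance
  expect_equal(ci, as.numeric(f$conf.int), tolerance = 1e-3)
  expect_equal(round(ci, 2), c(1.56, 4.11))
})

test_that("conditional bounds satisfy the noncentral tail equations", {
  # independent oracle: noncentral hypergeometric masses built from choose()
  dnch_direct <- function(n1, n2, k, psi) {
    xs <- max(0, k - n2):min(n1, k)
    w <- choose(n1, xs) * choose(n2, k - xs) * psi^xs
    list(x = xs, p = w / sum(w))
  }
  set.seed(5)
  for (i in 1:15) {
    tb <- as.integer(sample(1:25, 4, replace = TRUE))
    a <- tb[1]; n1 <- tb[1] + tb[2]; n2 <- tb[3] + tb[4]; k <- tb[1] + tb[3]
    ci <- odds_ratio_ci(tb[1], tb[2], tb[3], tb[4])
    if (is.finite(ci[1]) && ci[1] > 0) {
      d <- dnch_direct(n1, n2, k, ci[1])
      expect_equal(sum(d$p[d$x >= a]), 0.025, tolerance = 1e-6)
    }
    if (is.finite(ci[2])) {
      d <- dnch_direct(n1, n2, k, ci[2])
      expect_equal(sum(d$p[d$x <= a]), 0.025, tolerance = 1e-6)
    }
    # the conditional MLE solves the mean equation E[X | psi] = a
    psi_hat <- conditional_mle_odds_ratio(tb[1], tb[2], tb[3], tb[4])
    if (is.finite(psi_hat) && psi_hat > 0) {
      d <- dnch_direct(n1, n2, k, psi_hat)
      expect_equal(sum(d$x * d$p), a, tolerance = 1e-6)
    }
  }
})

test_that("degenerate tables yield open conditional bounds", {
  # a equals the entire variant margin: upper bound infinite
  ci <- odds_ratio_ci(4, 6, 0, 10)
  expect_equal(ci[2], Inf)
  expect_gt(ci[1], 0)
  expect_equal(conditional_mle_odds_ratio(4, 6, 0, 10), Inf)
  ci0 <- odds_ratio_ci(0, 10, 4, 6)
  expect_equal(ci0[1], 0)
  expect_equal(conditional_mle_odds_ratio(0, 10, 4, 6), 0)
})

test_that("Wald interval matches the closed form and converges to exact", {
  w <- odds_ratio_ci(20, 4188, 237, 128969, method = "wald")
  se <- sqrt(1 / 20 + 1 / 4188 + 1 / 237 + 1 / 128969)
  expect_equal(w, exp(log((20 * 128969) / (4188 * 237)) +
                        c(-1, 1) * qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(round(w, 2), c(1.64, 4.11))
  expect_error(odds_ratio_ci(0, 5, 3, 7, method = "wald", haldane = FALSE),
               "zero cell")

  # scaling all cells by 100x brings Wald and conditional-exact together
  small <- c(6, 40, 4, 60)
  big <- small * 100L
  we <- odds_ratio_ci(big[1], big[2], big[3], big[4], method = "wald")
  ce <- odds_ratio_ci(big[1], big[2], big[3], big[4])
  expect_lt(max(abs(we - ce) / ce), 0.02)
})

test_that("burden_test composes the pieces into one result", {
  r <- burden_test(20, 4208, 237, 129206, label = "LOF, all cases")
  expect_s3_class(r, "burden_result")
  expect_equal(unname(r$table), c(20, 4188, 237, 128969))
  expect_equal(round(r$odds_ratio, 2), 2.6)
  expect_equal(round(r$case_af, 3), 0.005)
  expect_equal(round(r$ref_af, 3), 0.002)
  expect_output(print(r), "OR 2.60")

  r2 <- burden_test(14, 2576, 237, 129206)
  expect_equal(round(r2$odds_ratio, 2), 2.97)

  # no signal: empty variant margin, p = 1, odds ratio undefined
  r0 <- burden_test(0, 100, 0, 1000)
  expect_equal(r0$p_value, 1)
  expect_true(is.na(r0$odds_ratio))

  df <- as.data.frame(r)
  expect_equal(df$a, 20)
  expect_equal(df$ci_method, "conditional_exact")
})

test_that("exact p-values are valid (conservative) under the null", {
  # equal carriage probability in both groups; the exact test's rejection
  # rate must not exceed nominal beyond Monte-Carlo error
  set.seed(6)
  n_rep <- 400
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rbinom(1, 400, 0.02); c_ <- rbinom(1, 4000, 0.02)
    p[i] <- fisher_exact_two_sided(a, 400 - a, c_, 4000 - c_)
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(p < 0.05), 0.05 + 3 * mc_se)
})
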