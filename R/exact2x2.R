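# Exact 2x2 inference on allele-count tables: two-sided Fisher p under the
# point-probability rule, sample and conditional-MLE odds ratios, and
# conditional-exact / Wald confidence intervals. The table layout is
#   a = case variant alleles      b = case non-variant alleles
#   c = reference variant alleles d = reference non-variant alleles

check_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (anyNA(v) || any(v < 0) || any(v != floor(v)))
    stop("2x2 table entries must be non-negative integers", call. = FALSE)
  invisible(v)
}

#' Allele frequency
#'
#' Exact quotient of variant alleles over total alleles assayed (2 per
#' diploid individual); any rounding happens in the reporting layer.
#' @param variant_alleles,total_alleles non-negative counts,
#'   `total_alleles > 0`.
#' @export
allele_frequency <- function(variant_alleles, total_alleles) {
  if (any(total_alleles <= 0))
    stop("total_alleles must be positive", call. = FALSE)
  if (any(variant_alleles < 0) || any(variant_alleles > total_alleles))
    stop("variant_alleles must lie in [0, total_alleles]", call. = FALSE)
  variant_alleles / total_alleles
}

#' Carrier frequency in percent
#'
#' Fraction of individuals (not alleles) carrying at least one qualifying
#' variant, times 100.
#' @param carriers,individuals non-negative counts, `individuals > 0`.
#' @export
carrier_frequency <- function(carriers, individuals) {
  if (any(individuals <= 0))
    stop("individuals must be positive", call. = FALSE)
  if (any(carriers < 0) || any(carriers > individuals))
    stop("carriers must lie in [0, individuals]", call. = FALSE)
  100 * carriers / individuals
}

#' Sample (cross-product) odds ratio
#'
#' `(a*d)/(b*c)`. When any cell is zero and `haldane = TRUE`, the
#' Haldane-Anscombe correction adds 0.5 to every cell first; the result then
#' carries attribute `haldane = TRUE`.
#' @param a,b,c,d table cells.
#' @param haldane apply the +0.5 correction when a zero cell is present.
#' @export
sample_odds_ratio <- function(a, b, c, d, haldane = TRUE) {
  check_table(a, b, c, d)
  if (a + b + c + d == 0)
    stop("odds ratio undefined for the all-zero table", call. = FALSE)
  corrected <- FALSE
  if (any(c(a, b, c, d) == 0)) {
    if (!haldane)
      stop("zero cell present and Haldane correction disabled", call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  structure((a * d) / (b * c), haldane = corrected)
}

# Hypergeometric support and log point masses for fixed margins.
hyper_support <- function(a, b, c, d) {
  k <- a + c                       # variant-allele margin
  lo <- max(0L, k - (c + d))
  hi <- min(a + b, k)
  x <- lo:hi
  list(x = x, logdc = stats::dhyper(x, a + b, c + d, k, log = TRUE))
}

#' Two-sided Fisher exact p-value (point-probability rule)
#'
#' Sums, over the hypergeometric support with all margins fixed, the
#' probabilities of every table no more likely than the observed one (the
#' convention of `stats::fisher.test`; a relative tolerance of 1e-7 guards
#' the comparison against floating-point ties).
#' @param a,b,c,d table cells.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  check_table(a, b, c, d)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(1)                      # degenerate margin: only one table
  sup <- hyper_support(a, b, c, d)
  d0 <- stats::dhyper(a, a + b, c + d, a + c, log = FALSE)
  p <- sum(exp(sup$logdc)[exp(sup$logdc) <= d0 * (1 + 1e-7)])
  min(p, 1)
}

# Noncentral hypergeometric point masses at odds ratio psi (normalized).
dnchyper <- function(sup, psi) {
  w <- sup$logdc + sup$x * log(psi)
  w <- exp(w - max(w))
  w / sum(w)
}

mean_nchyper <- function(sup, psi) sum(sup$x * dnchyper(sup, psi))

# P(X >= a | psi) and P(X <= a | psi) under the noncentral hypergeometric.
pnchyper_geq <- function(sup, a, psi) sum(dnchyper(sup, psi)[sup$x >= a])
pnchyper_leq <- function(sup, a, psi) sum(dnchyper(sup, psi)[sup$x <= a])

solve_increasing <- function(f, target) {
  # f is monotone increasing in log(psi); find f = target by bracketing
  lo <- -1; hi <- 1
  while (f(exp(lo)) > target && lo > -745) lo <- lo * 2
  while (f(exp(hi)) < target && hi < 709) hi <- hi * 2
  r <- stats::uniroot(function(lp) f(exp(lp)) - target, c(lo, hi),
                      tol = .Machine$double.eps^0.5)
  exp(r$root)
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of the
#' observed table conditional on both margins (the estimate reported by
#' `stats::fisher.test`). Degenerate tables at the support boundary return 0
#' or `Inf`.
#' @param a,b,c,d table cells.
#' @export
conditional_mle_odds_ratio <- function(a, b, c, d) {
  check_table(a, b, c, d)
  sup <- hyper_support(a, b, c, d)
  if (length(sup$x) == 1L) return(NA_real_) # margins admit a single table
  if (a == min(sup$x)) return(0)
  if (a == max(sup$x)) return(Inf)
  solve_increasing(function(psi) mean_nchyper(sup, psi), a)
}

#' Confidence interval for the odds ratio of a 2x2 table
#'
#' `conditional_exact` inverts the noncentral hypergeometric tail
#' probabilities at `(1 - level)/2` per side (the `fisher.test` interval);
#' boundary tables yield open bounds (0 or `Inf`). `wald` is
#' `exp(log(sample OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, with the
#' Haldane-Anscombe correction when a zero cell is present (error if
#' `haldane` is disabled).
#' @param a,b,c,d table cells.
#' @param method `"conditional_exact"` (default) or `"wald"`.
#' @param level confidence level in (0, 1), default 0.95.
#' @param haldane zero-cell policy for the Wald interval.
#' @return numeric vector `c(low, high)`.
#' @export
odds_ratio_ci <- function(a, b, c, d,
                          method = c("conditional_exact", "wald"),
                          level = 0.95, haldane = TRUE) {
  method <- match.arg(method)
  check_table(a, b, c, d)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  alpha <- (1 - level) / 2
  if (method == "wald") {
    if (any(c(a, b, c, d) == 0)) {
      if (!haldane)
        stop("Wald interval undefined with a zero cell and Haldane disabled",
             call. = FALSE)
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    or <- (a * d) / (b * c)
    return(exp(log(or) + c(-1, 1) * stats::qnorm(1 - alpha) * se))
  }
  sup <- hyper_support(a, b, c, d)
  if (length(sup$x) == 1L) return(c(0, Inf))
  # lower bound: P(X >= a | psi) is increasing in psi
  low <- if (a == min(sup$x)) 0 else
    solve_increasing(function(psi) pnchyper_geq(sup, a, psi), alpha)
  # upper bound: P(X <= a | psi) is decreasing in psi
  high <- if (a == max(sup$x)) Inf else
    solve_increasing(function(psi) -pnchyper_leq(sup, a, psi), -alpha)
  c(low, high)
}

#' Exact burden test on a 2x2 allele-count table
#'
#' Composes allele frequencies, the sample cross-product odds ratio, the
#' conditional-MLE odds ratio, the two-sided exact p-value and a confidence
#' interval into one result. The reported `odds_ratio` is the sample
#' cross-product estimate; the conditional MLE is stored alongside.
#'
#' @param case_alleles,case_total variant and total allele counts in cases.
#' @param ref_alleles,ref_total variant and total allele counts in the
#'   comparison population.
#' @param label free-text analysis identifier.
#' @param ci_method `"conditional_exact"` (default) or `"wald"`.
#' @param level confidence level, default 0.95.
#' @return object of class `burden_result`: a list with elements `table`
#'   (named vector a,b,c,d), `case_af`, `ref_af`, `odds_ratio`,
#'   `odds_ratio_cmle`, `ci_low`, `ci_high`, `ci_method`, `p_value`,
#'   `haldane`, `label`.
#' @examples
#' burden_test(20, 4208, 237, 129206, label = "LOF, all cases")
#' @export
burden_test <- function(case_alleles, case_total, ref_alleles, ref_total,
                        label = "", ci_method = c("conditional_exact", "wald"),
                        level = 0.95) {
  ci_method <- match.arg(ci_method)
  a <- case_alleles; b <- case_total - case_alleles
  c <- ref_alleles;  d <- ref_total - ref_alleles
  check_table(a, b, c, d)
  # an empty margin carries no signal: no odds ratio is defined
  or <- if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0)
    NA_real_ else sample_odds_ratio(a, b, c, d)
  ci <- odds_ratio_ci(a, b, c, d, method = ci_method, level = level)
  structure(list(
    table = c(a = a, b = b, c = c, d = d),
    case_af = allele_frequency(a, case_total),
    ref_af = allele_frequency(c, ref_total),
    odds_ratio = as.numeric(or),
    odds_ratio_cmle = conditional_mle_odds_ratio(a, b, c, d),
    ci_low = ci[1], ci_high = ci[2], ci_method = ci_method, level = level,
    p_value = fisher_exact_two_sided(a, b, c, d),
    haldane = isTRUE(attr(or, "haldane")),
    label = label), class = "burden_result")
}

# Reporting-layer formatters: OR to 2 decimals (3 significant figures below
# 1), p in scientific notation with 2 significant digits.
format_or <- function(x) {
  ifelse(is.finite(x) & x < 1, formatC(signif(x, 3), format = "fg"),
         formatC(x, format = "f", digits = 2))
}
format_p <- function(p) formatC(p, format = "e", digits = 1)

#' @export
print.burden_result <- function(x, af_digits = 4, ...) {
  cat("Exact 2x2 burden test", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  cases:     %d / %d variant alleles (AF %s)\n",
              x$table["a"], x$table["a"] + x$table["b"],
              formatC(x$case_af, format = "f", digits = af_digits)))
  cat(sprintf("  reference: %d / %d variant alleles (AF %s)\n",
              x$table["c"], x$table["c"] + x$table["d"],
              formatC(x$ref_af, format = "f", digits = af_digits)))
  cat(sprintf("  OR %s (%d%% CI %s-%s, %s)%s, p = %s\n",
              format_or(x$odds_ratio), round(100 * x$level),
              format_or(x$ci_low), format_or(x$ci_high),
              x$ci_method, if (x$haldane) " [Haldane +0.5]" else "",
              format_p(x$p_value)))
  invisible(x)
}

#' @export
as.data.frame.burden_result <- function(x, ...) {
  data.frame(label = x$label,
             a = x$table[["a"]], b = x$table[["b"]],
             c = x$table[["c"]], d = x$table[["d"]],
             case_af = x$case_af, ref_af = x$ref_af,
             or = x$odds_ratio, or_cmle = x$odds_ratio_cmle,
             ci_low = x$ci_low, ci_high = x$ci_high,
             ci_method = x$ci_method, p = x$p_value,
             haldane = x$haldane, stringsAsFactors = FALSE)
}
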