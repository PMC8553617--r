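# Full-study orchestration: analysis plans, grouped burden tests against the
# reference population, per-variant tests, the internal two-center
# case-control comparison, and the lollipop export table.

#' Define one grouped burden analysis
#'
#' A plan names a variant class (`LOF` or `VUS`), a case subset (`all`
#' strata, or the genetically enriched `fam_mpm` subset of familial probands
#' plus MPM cases), and for VUS an optional restriction to variants inside or
#' outside the configured ATM functional domains. The domain restriction is
#' only valid for VUS.
#'
#' @param class `"LOF"` or `"VUS"`.
#' @param subset `"all"` or `"fam_mpm"`.
#' @param domain `"none"`, `"in_domain"` or `"out_domain"`.
#' @param min_cases_individual recurrence threshold for per-variant follow-up
#'   (default 3 distinct cases).
#' @param label optional label; a descriptive one is built by default.
#' @return list of class `analysis_plan`.
#' @export
analysis_plan <- function(class = c("LOF", "VUS"),
                          subset = c("all", "fam_mpm"),
                          domain = c("none", "in_domain", "out_domain"),
                          min_cases_individual = 3L, label = NULL) {
  class <- match.arg(class)
  subset <- match.arg(subset)
  domain <- match.arg(domain)
  if (domain != "none" && class != "VUS")
    stop("domain restriction is only defined for the VUS class", call. = FALSE)
  if (min_cases_individual < 1)
    stop("min_cases_individual must be >= 1", call. = FALSE)
  if (is.null(label))
    label <- paste0(class,
                    if (domain == "in_domain") " in-domain" else
                      if (domain == "out_domain") " out-domain" else "",
                    ", ", if (subset == "all") "all cases" else "fam+MPM")
  structure(list(class = class, subset = subset, domain = domain,
                 min_cases_individual = as.integer(min_cases_individual),
                 label = label),
            class = "analysis_plan")
}

#' The default full plan set
#'
#' Grouped LOF and VUS tests for all cases and the genetically enriched
#' subset, plus the VUS in-domain / out-domain splits: eight plans in all.
#' @export
default_plans <- function() {
  plans <- list()
  for (cl in c("LOF", "VUS")) for (ss in c("all", "fam_mpm"))
    plans[[length(plans) + 1L]] <- analysis_plan(cl, ss)
  for (dm in c("in_domain", "out_domain")) for (ss in c("all", "fam_mpm"))
    plans[[length(plans) + 1L]] <- analysis_plan("VUS", ss, dm)
  plans
}

plan_strata <- function(subset)
  if (subset == "fam_mpm") c("familial", "MPM") else STRATA

# variant ids matching a plan's class and domain restriction
plan_variant_ids <- function(variant_ids, categories, anchors, plan,
                             domains) {
  keep <- categories == plan$class
  if (plan$domain != "none") {
    m <- match(variant_ids, anchors$variant_id)
    pos <- anchors$position[m]
    # only residues parsed from a protein change can place a variant inside
    # a domain; cDNA-derived plotting anchors never qualify
    pos[anchors$source[m] != "protein"] <- NA_integer_
    in_dom <- annotate_domain(pos, domains) != "outside"
    keep <- keep & (if (plan$domain == "in_domain") in_dom else !in_dom)
  }
  variant_ids[keep]
}

# allele count contributed by each observation (het = 1, hom = 2)
obs_alleles <- function(obs) ifelse(obs$zygosity == "hom", 2L, 1L)

case_allele_count <- function(cohort, variant_ids, strata = STRATA) {
  obs <- cohort$observations
  sel <- obs$variant_id %in% variant_ids & obs$stratum %in% strata
  sum(obs_alleles(obs[sel, , drop = FALSE]))
}

#' Run the grouped burden analyses
#'
#' The orchestrator of the full study: classifies the union of the cohort's
#' and the reference's variant universes (unless pre-classified outcomes are
#' supplied), then for each plan builds the 2x2 allele table -- case variant
#' alleles out of `2 * N` case alleles for the plan's strata, against the
#' summed reference allele counts of the same variant class over the
#' aggregate reference allele number -- and runs the exact test.
#'
#' @param cohort a [cohort_dataset].
#' @param reference a `reference_counts` table ([read_reference_table()]).
#' @param plans list of [analysis_plan()] objects (default [default_plans()]).
#' @param classified optional precomputed [classify_variants()] outcomes
#'   covering every variant in cohort and reference; computed when `NULL`.
#' @param overrides curated override table used when classifying.
#' @param ref_allele_number single aggregate reference allele number used as
#'   the grouped-test denominator (default 129206, i.e. 2 x 64,603
#'   reference individuals).
#' @param domains domain intervals for domain-restricted plans.
#' @param ci_method,level forwarded to [burden_test()].
#' @return object of class `atm_burden`: list with `results` (one
#'   `burden_result` per plan), `plans`, `classified`, `provenance`, and the
#'   inputs' summary. Methods: `print`, `summary`, `as.data.frame`.
#' @export
atm_burden <- function(cohort, reference, plans = default_plans(),
                       classified = NULL, overrides = default_overrides(),
                       ref_allele_number = 129206L, domains = atm_domains(),
                       ci_method = "conditional_exact", level = 0.95) {
  if (!inherits(cohort, "cohort_dataset"))
    stop("cohort must be a cohort_dataset", call. = FALSE)
  if (inherits(plans, "analysis_plan")) plans <- list(plans)
  reference <- if (inherits(reference, "reference_counts")) reference else
    reference_counts(reference)

  if (is.null(classified)) {
    universe <- merge_universe(cohort$variants, reference)
    classified <- classify_variants(universe, reference, overrides)
  }
  need <- unique(c(cohort$variants$variant_id, reference$variant_id))
  missing <- setdiff(need, classified$variant_id)
  if (length(missing))
    stop("classification missing for variant(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  anchors <- rbind(anchor_table(cohort$variants),
                   anchor_table(reference[!reference$variant_id %in%
                                            cohort$variants$variant_id, ,
                                          drop = FALSE]))
  cat_of <- stats::setNames(classified$category, classified$variant_id)

  results <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    strata <- intersect(plan_strata(plan$subset), names(cohort$n_individuals))
    n_cases <- sum(cohort$n_individuals[strata])
    if (n_cases == 0)
      stop("plan '", plan$label, "' selects an empty case subset",
           call. = FALSE)
    ids <- plan_variant_ids(names(cat_of), unname(cat_of), anchors, plan,
                            domains)
    a <- case_allele_count(cohort, ids, strata)
    ref_ids <- intersect(ids, reference$variant_id)
    c_ <- sum(reference$allele_count[match(ref_ids, reference$variant_id)])
    results[[i]] <- burden_test(a, 2L * n_cases, c_, ref_allele_number,
                                label = plan$label, ci_method = ci_method,
                                level = level)
  }

  structure(list(
    results = results, plans = plans, classified = classified,
    provenance = list(
      LOF = partition_provenance(
        intersect(cohort$variants$variant_id,
                  classified$variant_id[classified$category == "LOF"]),
        intersect(reference$variant_id,
                  classified$variant_id[classified$category == "LOF"])),
      VUS = partition_provenance(
        intersect(cohort$variants$variant_id,
                  classified$variant_id[classified$category == "VUS"]),
        intersect(reference$variant_id,
                  classified$variant_id[classified$category == "VUS"]))),
    n_individuals = cohort$n_individuals,
    ref_allele_number = as.integer(ref_allele_number)),
    class = "atm_burden")
}

# union of a cohort variant table and the reference's annotation columns
merge_universe <- function(variants, reference) {
  extra <- reference[!reference$variant_id %in% variants$variant_id,
                     c("variant_id", "cdna_hgvs", "protein_hgvs",
                       "consequence"), drop = FALSE]
  out <- rbind(variants[c("variant_id", "cdna_hgvs", "protein_hgvs",
                          "consequence")],
               as.data.frame(extra, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' @export
print.atm_burden <- function(x, ...) {
  cat("Grouped rare-variant burden analysis:",
      sum(x$n_individuals), "cases vs", x$ref_allele_number,
      "reference alleles\n\n")
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.atm_burden <- function(x, ...) {
  do.call(rbind, lapply(x$results, as.data.frame))
}

#' @export
summary.atm_burden <- function(object, ...) {
  cat("Variant classification (unique variants):\n")
  print(table(factor(object$classified$category, CLASS_CATEGORIES)))
  for (cl in c("LOF", "VUS")) {
    pv <- object$provenance[[cl]]
    cat(sprintf("%s provenance: %d study-only, %d reference-only, %d shared (%d total)\n",
                cl, pv$study_only, pv$reference_only, pv$both, pv$total))
  }
  cat("\n")
  print(object)
  invisible(object)
}

#' Variants recurrent in the case cohort
#'
#' Variants of the requested categories observed in at least `min_cases`
#' distinct case individuals; the study design examines these individually.
#' @param cohort a [cohort_dataset].
#' @param classified [classify_variants()] outcomes.
#' @param min_cases distinct-individual threshold (default 3).
#' @param categories classes eligible for selection (default VUS and LOF).
#' @return character vector of variant keys.
#' @export
select_recurrent_variants <- function(cohort, classified, min_cases = 3L,
                                      categories = c("VUS", "LOF")) {
  if (min_cases < 1) stop("min_cases must be >= 1", call. = FALSE)
  keep <- classified$variant_id[classified$category %in% categories]
  obs <- cohort$observations[cohort$observations$variant_id %in% keep, ,
                             drop = FALSE]
  n <- tapply(obs$individual_id, obs$variant_id,
              function(z) length(unique(z)))
  names(n)[n >= min_cases]
}

#' Per-variant exact test against the reference population
#'
#' Builds the 2x2 table for one variant: case carrier alleles over the whole
#' case cohort against the variant's reference allele count. A variant
#' absent from the reference contributes AC = 0 over the aggregate allele
#' number.
#' @param variant_id variant key (must be carried in the cohort).
#' @param cohort a [cohort_dataset].
#' @param reference a `reference_counts` table.
#' @param ref_allele_number fallback aggregate AN used when the variant has
#'   no reference row (default 129206); a variant's own AN is used when
#'   present.
#' @param ... forwarded to [burden_test()].
#' @return a `burden_result`.
#' @export
per_variant_test <- function(variant_id, cohort, reference,
                             ref_allele_number = 129206L, ...) {
  variant_id <- normalize_variant_id(variant_id)
  a <- case_allele_count(cohort, variant_id)
  if (a == 0)
    stop("variant ", variant_id, " not carried in the cohort", call. = FALSE)
  m <- match(variant_id, reference$variant_id)
  ac <- if (is.na(m)) 0L else reference$allele_count[m]
  an <- if (is.na(m)) as.integer(ref_allele_number) else
    reference$allele_number[m]
  burden_test(a, sum(allele_totals(cohort)), ac, an, label = variant_id, ...)
}

#' Internal case-control burden comparison
#'
#' Compares case allele counts of one variant class against an internal
#' control cohort genotyped by the same centers (instead of the reference
#' population). The subset restriction applies to cases only; controls
#' always contribute all their alleles.
#' @param cases,controls [cohort_dataset] objects; individual ids must not
#'   overlap.
#' @param classified [classify_variants()] outcomes covering both cohorts'
#'   variants (classified under the same rules).
#' @param class `"LOF"` or `"VUS"`.
#' @param subset `"all"` or `"fam_mpm"` (cases only).
#' @param ... forwarded to [burden_test()].
#' @return a `burden_result`.
#' @export
internal_case_control <- function(cases, controls, classified,
                                  class = c("LOF", "VUS"),
                                  subset = c("all", "fam_mpm"), ...) {
  class <- match.arg(class)
  subset <- match.arg(subset)
  shared <- intersect(unique(cases$observations$individual_id),
                      unique(controls$observations$individual_id))
  if (length(shared))
    stop("individual id(s) present in both cohorts: ",
         paste(utils::head(shared, 5), collapse = ", "), call. = FALSE)
  ids <- classified$variant_id[classified$category == class]
  strata <- intersect(plan_strata(subset), names(cases$n_individuals))
  a <- case_allele_count(cases, ids, strata)
  n_case_alleles <- 2L * sum(cases$n_individuals[strata])
  c_ <- case_allele_count(controls, ids)
  n_ctrl_alleles <- sum(allele_totals(controls))
  burden_test(a, n_case_alleles, c_, n_ctrl_alleles,
              label = paste0(class, " cases vs internal controls (",
                             subset, ")"), ...)
}

#' Export the lollipop-plot table
#'
#' One row per unique LOF/VUS variant with a resolvable residue anchor,
#' sorted by position, with the distinct-case carrier count; variants with
#' no anchor are listed in a side table.
#' @param cohort a [cohort_dataset].
#' @param classified [classify_variants()] outcomes.
#' @return list with data.frames `placed` (variant_id, protein_position,
#'   category, case_count) and `unplaced` (variant_id, category,
#'   case_count).
#' @export
export_lollipop <- function(cohort, classified) {
  obs <- cohort$observations
  counts <- tapply(obs$individual_id, obs$variant_id,
                   function(z) length(unique(z)))
  v <- cohort$variants
  m <- match(v$variant_id, classified$variant_id)
  cat_ <- classified$category[m]
  keep <- !is.na(cat_) & cat_ %in% c("LOF", "VUS")
  v <- v[keep, , drop = FALSE]; cat_ <- cat_[keep]
  anch <- anchor_table(v)
  out <- data.frame(variant_id = v$variant_id,
                    protein_position = anch$position,
                    category = cat_,
                    case_count = as.integer(counts[v$variant_id]),
                    stringsAsFactors = FALSE)
  placed <- out[!is.na(out$protein_position), , drop = FALSE]
  placed <- placed[order(placed$protein_position, placed$variant_id), ,
                   drop = FALSE]
  rownames(placed) <- NULL
  unplaced <- out[is.na(out$protein_position),
                  c("variant_id", "category", "case_count"), drop = FALSE]
  rownames(unplaced) <- NULL
  list(placed = placed, unplaced = unplaced)
}
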