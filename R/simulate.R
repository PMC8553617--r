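# Synthetic cohort, reference and family generators with the statistical
# structure the analysis assumes: per-individual Bernoulli carriage of rare
# variants at reference AF times an enrichment multiplier (odds ~ probability
# at AF < 0.01), and binomial reference allele counts.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old))
    rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Define a simulation scenario
#'
#' @param stratum_sizes named integer vector of case counts per stratum
#'   (names from [STRATA]).
#' @param n_controls internal-control cohort size.
#' @param ref_individuals diploid reference-population size (AN is twice
#'   this).
#' @param blueprint data.frame with one row per variant: `variant_id`,
#'   `cdna_hgvs`, `protein_hgvs`, `consequence`, `protein_position`,
#'   `ref_af` (in [0, 0.5]), `multiplier` (case carrier-odds multiplier,
#'   > 0) and `hom_rate`.
#' @param seed integer seed (mandatory; every generator call is
#'   deterministic given the config).
#' @return list of class `scenario_config`.
#' @export
scenario <- function(stratum_sizes, n_controls, ref_individuals, blueprint,
                     seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("scenario seed is mandatory", call. = FALSE)
  stopifnot(all(names(stratum_sizes) %in% STRATA),
            all(stratum_sizes > 0), n_controls > 0, ref_individuals > 0)
  blueprint <- as.data.frame(blueprint, stringsAsFactors = FALSE)
  require_columns(blueprint, c("variant_id", "consequence", "ref_af",
                               "multiplier"), "blueprint")
  if (any(blueprint$ref_af < 0 | blueprint$ref_af > 0.5))
    stop("blueprint ref_af must lie in [0, 0.5]", call. = FALSE)
  if (any(blueprint$multiplier < 0))
    stop("blueprint multiplier must be >= 0", call. = FALSE)
  if (is.null(blueprint$hom_rate)) blueprint$hom_rate <- 0
  if (is.null(blueprint$cdna_hgvs)) blueprint$cdna_hgvs <- blueprint$variant_id
  if (is.null(blueprint$protein_hgvs)) blueprint$protein_hgvs <- NA_character_
  structure(list(stratum_sizes = stratum_sizes,
                 n_controls = as.integer(n_controls),
                 ref_individuals = as.integer(ref_individuals),
                 blueprint = blueprint, seed = as.integer(seed)),
            class = "scenario_config")
}

# HGVS strings for a synthetic variant at residue r
synth_hgvs <- function(consequence, r) {
  cdna_pos <- 3L * r - 1L
  switch(consequence,
         nonsense = list(cdna = sprintf("c.%dC>A", cdna_pos),
                         prot = sprintf("p.(Ser%d*)", r)),
         frameshift = list(cdna = sprintf("c.%ddelT", cdna_pos),
                           prot = sprintf("p.(Leu%dProfs*7)", r)),
         splice_donor = list(cdna = sprintf("c.%d+1G>A", 3L * r),
                             prot = NA_character_),
         splice_acceptor = list(cdna = sprintf("c.%d-2A>G", 3L * r - 2L),
                                prot = NA_character_),
         missense = list(cdna = sprintf("c.%dG>A", cdna_pos),
                         prot = sprintf("p.(Ala%dThr)", r)),
         list(cdna = sprintf("c.%dG>A", cdna_pos), prot = NA_character_))
}

#' The default study-scale scenario
#'
#' Mirrors the study cohort structure: 878 familial probands, 410 MPM and
#' 816 sporadic cases (2,104 in all), 1,446 internal controls, and a
#' reference population of 64,603 diploid individuals (AN 129,206). The
#' blueprint carries 16 LOF-like variants with reference AFs summing to
#' 0.002 and carrier-odds multiplier 2.6, and 100 VUS-like missense variants
#' with AFs summing to 0.033 and multiplier 1.41 -- the aggregate
#' frequencies and effect sizes the analysis is designed to detect. Variant
#' residues are spread over the 3,056-residue protein so that some VUS fall
#' inside the functional domains.
#'
#' @param seed integer seed.
#' @return a `scenario_config`.
#' @export
scenario_study_scale <- function(seed) {
  lof_cons <- rep(c("nonsense", "frameshift", "splice_donor",
                    "splice_acceptor"), 4)
  lof_pos <- as.integer(round(seq(120, 3000, length.out = 16)))
  vus_pos <- as.integer(round(seq(25, 3050, length.out = 100)))
  rows <- function(cons, pos, af, mult) {
    h <- lapply(seq_along(pos), function(i) synth_hgvs(cons[i], pos[i]))
    data.frame(variant_id = vapply(h, `[[`, "", "cdna"),
               cdna_hgvs = vapply(h, `[[`, "", "cdna"),
               protein_hgvs = vapply(h, `[[`, "", "prot"),
               consequence = cons, protein_position = pos,
               ref_af = af, multiplier = mult, hom_rate = 0,
               stringsAsFactors = FALSE)
  }
  blueprint <- rbind(
    rows(lof_cons, lof_pos, 0.002 / 16, 2.6),
    rows(rep("missense", 100), vus_pos, 0.033 / 100, 1.41))
  scenario(c(familial = 878L, MPM = 410L, sporadic = 816L),
           n_controls = 1446L, ref_individuals = 64603L,
           blueprint = blueprint, seed = seed)
}

#' Simulate a reference-population count table
#'
#' For each blueprint variant the allele count is binomial at the variant's
#' reference AF over AN = 2 x `ref_individuals` trials; the homozygote count
#' is binomial over `floor(AC / 2)` at `hom_rate`, so `2 * hom <= AC` always
#' holds. Deterministic given the scenario seed.
#' @param config a [scenario()] config.
#' @return a `reference_counts` table.
#' @export
simulate_reference <- function(config) {
  bp <- config$blueprint
  an <- 2L * config$ref_individuals
  with_seed(config$seed, {
    ac <- stats::rbinom(nrow(bp), an, bp$ref_af)
    hom <- stats::rbinom(nrow(bp), ac %/% 2L, bp$hom_rate)
    reference_counts(data.frame(
      variant_id = bp$variant_id, cdna_hgvs = bp$cdna_hgvs,
      protein_hgvs = bp$protein_hgvs, consequence = bp$consequence,
      allele_count = ac, allele_number = an, homozygote_count = hom,
      stringsAsFactors = FALSE))
  })
}

simulate_carriage <- function(blueprint, sizes, id_prefixes, center, seed,
                              multiplier = blueprint$multiplier) {
  # carriage is sampled per allele (2 per diploid individual), so a unit
  # multiplier leaves the case allele frequency exactly at the reference AF;
  # an individual drawing both alleles is a (rare) homozygote
  p <- blueprint$ref_af * multiplier
  if (any(p > 1)) {
    warning("allele carriage probability clipped to 1 for ",
            sum(p > 1), " variant(s)", call. = FALSE)
    p <- pmin(p, 1)
  }
  obs <- list()
  with_seed(seed, {
    for (s in seq_along(sizes)) {
      n <- sizes[[s]]
      for (j in seq_len(nrow(blueprint))) {
        k <- stats::rbinom(1L, 2L * n, p[j])
        if (k > 0) {
          slots <- sample.int(2L * n, k)
          idx <- table(ceiling(slots / 2))
          obs[[length(obs) + 1L]] <- data.frame(
            individual_id = sprintf("%s%05d", id_prefixes[s],
                                    as.integer(names(idx))),
            center = center, stratum = names(sizes)[s],
            variant_id = blueprint$variant_id[j],
            zygosity = ifelse(idx == 2L, "hom", "het"),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  if (length(obs)) do.call(rbind, obs) else
    data.frame(individual_id = character(), center = character(),
               stratum = character(), variant_id = character(),
               zygosity = character(), stringsAsFactors = FALSE)
}

#' Simulate a case cohort
#'
#' Each of a case's two alleles independently carries each blueprint variant
#' with probability `ref_af * multiplier` (odds-scale enrichment, a close
#' approximation at AF < 0.01; clipped to 1 with a warning otherwise), so a
#' unit multiplier reproduces the reference allele frequency exactly and
#' carriers are heterozygous unless both alleles draw the variant.
#' Observations are emitted for carriers only. Deterministic given the
#' scenario seed.
#' @param config a [scenario()] config.
#' @return a [cohort_dataset].
#' @export
simulate_cohort <- function(config) {
  sizes <- config$stratum_sizes
  prefixes <- stats::setNames(paste0(toupper(substr(names(sizes), 1, 1)), "_"),
                              names(sizes))
  obs <- simulate_carriage(config$blueprint, as.list(sizes), prefixes,
                           center = "SIM", seed = config$seed + 1L)
  cohort_dataset(obs,
                 config$blueprint[c("variant_id", "cdna_hgvs",
                                    "protein_hgvs", "consequence")],
                 sizes)
}

#' Simulate an internal control cohort
#'
#' Controls carry variants at the unenriched reference AF (multiplier 1).
#' @param config a [scenario()] config.
#' @return a [cohort_dataset] with a single `sporadic` stratum.
#' @export
simulate_controls <- function(config) {
  sizes <- c(sporadic = config$n_controls)
  obs <- simulate_carriage(config$blueprint, as.list(sizes), c(sporadic = "CTRL_"),
                           center = "SIM_CTRL", seed = config$seed + 2L,
                           multiplier = 1)
  cohort_dataset(obs,
                 config$blueprint[c("variant_id", "cdna_hgvs",
                                    "protein_hgvs", "consequence")],
                 sizes)
}

#' Simulate family cosegregation records
#'
#' Sequenced-affected counts are drawn uniformly from 2-6 (3-6 under the
#' partial regime, which needs room between one carrier and all); carrier
#' counts follow the regime: `full` (all sequenced carry), `none` (only the
#' proband carries), `partial` (two or more but not all).
#' @param n_families number of records.
#' @param regime `"full"`, `"partial"` or `"none"`; recycled over families.
#' @param seed integer seed.
#' @param variant_id key recorded for every family (default "c.synthetic").
#' @return data.frame of family records.
#' @export
simulate_families <- function(n_families, regime = "full", seed,
                              variant_id = "c.synthetic") {
  stopifnot(n_families >= 1)
  if (!all(regime %in% c("full", "partial", "none")))
    stop("regime must be 'full', 'partial' or 'none'", call. = FALSE)
  regime <- rep_len(regime, n_families)
  with_seed(seed, {
    s <- ifelse(regime == "partial",
                sample(3:6, n_families, replace = TRUE),
                sample(2:6, n_families, replace = TRUE))
    k <- integer(n_families)
    for (i in seq_len(n_families)) {
      k[i] <- switch(regime[i],
                     full = s[i],
                     none = 1L,
                     partial = if (s[i] == 3L) 2L else
                       sample(2:(s[i] - 1L), 1L))
    }
    data.frame(family_id = sprintf("FAM_%04d", seq_len(n_families)),
               variant_id = variant_id,
               n_sequenced_affected = s,
               n_carriers_among_sequenced = k,
               stringsAsFactors = FALSE)
  })
}

#' Write every table of a simulated scenario
#'
#' Emits `cases.tsv`, `cohort_sizes.tsv`, `reference_counts.tsv`,
#' `controls.tsv`, `control_sizes.tsv` and `families.tsv` into `out_dir`.
#' @param config a [scenario()] config.
#' @param out_dir output directory (created if needed).
#' @param n_families families to simulate (default 20, regime recycled from
#'   `regimes`).
#' @param regimes cosegregation regimes for [simulate_families()].
#' @return `out_dir`, invisibly.
#' @export
write_scenario_tables <- function(config, out_dir, n_families = 20L,
                                  regimes = c("full", "partial", "none")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  write_case_table(cohort, file.path(out_dir, "cases.tsv"),
                   file.path(out_dir, "cohort_sizes.tsv"))
  ref <- simulate_reference(config)
  utils::write.table(as.data.frame(ref), file.path(out_dir, "reference_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  controls <- simulate_controls(config)
  write_case_table(controls, file.path(out_dir, "controls.tsv"),
                   file.path(out_dir, "control_sizes.tsv"))
  fam <- simulate_families(n_families, rep_len(regimes, n_families),
                           seed = config$seed + 3L)
  utils::write.table(fam, file.path(out_dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
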