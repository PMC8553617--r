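# Core containers and tab-separated table dialects shared by every stage of
# the pipeline. All tables are UTF-8 TSV with one header row; lines starting
# with "#" are comments.

#' Case strata recognised throughout the package
#'
#' Cases are one of: probands of melanoma-prone families (`familial`),
#' multiple-primary-melanoma cases (`MPM`), or sporadic single-primary cases
#' from case-control/cohort studies (`sporadic`).
#' @export
STRATA <- c("familial", "MPM", "sporadic")

#' Variant consequence classes
#'
#' The four loss-of-function classes are nonsense, frameshift, and canonical
#' splice acceptor/donor changes; `missense` variants are candidate VUS;
#' everything else (`synonymous`, `other`) is excluded from burden testing
#' unless a curated override applies.
#' @export
CONSEQUENCES <- c("nonsense", "frameshift", "splice_acceptor", "splice_donor",
                  "missense", "synonymous", "other")

#' @rdname CONSEQUENCES
#' @export
LOF_CONSEQUENCES <- CONSEQUENCES[1:4]

# Normalize a cDNA HGVS key: strip all whitespace, keep case.
normalize_variant_id <- function(x) gsub("[[:space:]]+", "", as.character(x))

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

as_count <- function(x, what, min = 0) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) || any(v != floor(v)) || any(v < min))
    stop(what, ": must be integer counts >= ", min, call. = FALSE)
  as.integer(v)
}

#' Construct a case-cohort dataset
#'
#' Bundles per-individual variant observations, the unique-variant table and
#' the per-stratum cohort sizes (which cover non-carriers) into a validated
#' container. Allele totals per stratum are always `2 * n_individuals`
#' (diploid autosomal locus).
#'
#' @param observations data.frame with columns `individual_id`, `center`,
#'   `stratum`, `variant_id`, `zygosity` (`"het"` or `"hom"`, default het).
#' @param variants data.frame with columns `variant_id`, `cdna_hgvs`,
#'   `protein_hgvs`, `consequence` (optional columns may be `NA`).
#' @param n_individuals named integer vector of cohort sizes per stratum,
#'   names drawn from [STRATA].
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(observations, variants, n_individuals) {
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  require_columns(observations,
                  c("individual_id", "center", "stratum", "variant_id"),
                  "observations")
  if (is.null(observations$zygosity)) observations$zygosity <- "het"
  observations$zygosity[is.na(observations$zygosity)] <- "het"
  require_columns(variants, c("variant_id", "cdna_hgvs"), "variants")
  if (is.null(variants$protein_hgvs)) variants$protein_hgvs <- NA_character_
  if (is.null(variants$consequence)) variants$consequence <- NA_character_

  observations$variant_id <- normalize_variant_id(observations$variant_id)
  variants$variant_id <- normalize_variant_id(variants$variant_id)

  bad <- setdiff(unique(observations$stratum), STRATA)
  if (length(bad))
    stop("unknown stratum label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(STRATA, collapse = "/"), call. = FALSE)
  if (!all(observations$zygosity %in% c("het", "hom")))
    stop("zygosity must be 'het' or 'hom'", call. = FALSE)

  key <- paste(observations$individual_id, observations$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (individual, variant) observation(s): ",
         paste(gsub("\r", " x ", utils::head(dup, 5)), collapse = "; "),
         call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id))
    stop("variant_id not unique in variant table", call. = FALSE)
  if (any(!nzchar(variants$variant_id)) || anyNA(variants$variant_id))
    stop("empty variant_id in variant table", call. = FALSE)

  unresolved <- setdiff(observations$variant_id, variants$variant_id)
  if (length(unresolved))
    stop("observation variant_id(s) not in variant table: ",
         paste(utils::head(unresolved, 5), collapse = ", "), call. = FALSE)

  n_individuals <- n_individuals[STRATA[STRATA %in% names(n_individuals)]]
  if (!all(observations$stratum %in% names(n_individuals)))
    stop("n_individuals lacks an entry for a stratum present in observations",
         call. = FALSE)
  storage.mode(n_individuals) <- "integer"
  if (anyNA(n_individuals) || any(n_individuals < 0))
    stop("n_individuals must be non-negative integers", call. = FALSE)
  ind <- unique(observations[c("individual_id", "stratum")])
  carriers <- table(factor(ind$stratum, names(n_individuals)))
  if (any(carriers > n_individuals))
    stop("more carriers than individuals in a stratum", call. = FALSE)

  structure(list(observations = observations, variants = variants,
                 n_individuals = n_individuals),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Case cohort:", sum(x$n_individuals), "individuals (",
      paste(sprintf("%s=%d", names(x$n_individuals), x$n_individuals),
            collapse = ", "), ")\n")
  cat("  ", nrow(x$observations), "carriage observations of",
      nrow(x$variants), "unique variants\n")
  invisible(x)
}

#' Total alleles per stratum (2 per diploid individual)
#' @param cohort a [cohort_dataset]
#' @export
allele_totals <- function(cohort) 2L * cohort$n_individuals

#' Read a case-cohort variant table
#'
#' `cases.tsv` has columns `individual_id`, `center`, `stratum`,
#' `variant_id`, `cdna_hgvs`, `protein_hgvs`, `consequence`, `zygosity`;
#' `cohort_sizes` is either a path to a two-column TSV (`stratum`,
#' `n_individuals`) or a named vector.
#'
#' @param path path to the cases TSV.
#' @param cohort_sizes path to the cohort-sizes TSV, or a named integer
#'   vector of individuals per stratum.
#' @return a [cohort_dataset]
#' @export
read_case_table <- function(path, cohort_sizes) {
  df <- read_tsv_file(path)
  require_columns(df, c("individual_id", "center", "stratum", "variant_id",
                        "cdna_hgvs"), basename(path))
  if (is.null(df$protein_hgvs)) df$protein_hgvs <- NA_character_
  if (is.null(df$consequence)) df$consequence <- NA_character_
  if (is.null(df$zygosity)) df$zygosity <- "het"
  df$variant_id <- normalize_variant_id(df$variant_id)
  df$cdna_hgvs <- normalize_variant_id(df$cdna_hgvs)

  if (is.character(cohort_sizes) && length(cohort_sizes) == 1L) {
    sz <- read_tsv_file(cohort_sizes)
    require_columns(sz, c("stratum", "n_individuals"), basename(cohort_sizes))
    cohort_sizes <- stats::setNames(
      as_count(sz$n_individuals, "n_individuals"), sz$stratum)
  }
  variants <- unique(df[c("variant_id", "cdna_hgvs", "protein_hgvs",
                          "consequence")])
  if (anyDuplicated(variants$variant_id))
    stop("inconsistent annotation for a variant_id across rows", call. = FALSE)
  cohort_dataset(df[c("individual_id", "center", "stratum", "variant_id",
                      "zygosity")],
                 variants, cohort_sizes)
}

#' Write a case-cohort dataset back to the TSV dialect
#' @param cohort a [cohort_dataset]
#' @param path output path for the cases table
#' @param sizes_path optional output path for the cohort-sizes table
#' @export
write_case_table <- function(cohort, path, sizes_path = NULL) {
  obs <- cohort$observations
  v <- cohort$variants
  m <- match(obs$variant_id, v$variant_id)
  out <- data.frame(individual_id = obs$individual_id, center = obs$center,
                    stratum = obs$stratum, variant_id = obs$variant_id,
                    cdna_hgvs = v$cdna_hgvs[m],
                    protein_hgvs = v$protein_hgvs[m],
                    consequence = v$consequence[m],
                    zygosity = obs$zygosity,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  if (!is.null(sizes_path)) {
    sz <- data.frame(stratum = names(cohort$n_individuals),
                     n_individuals = as.integer(cohort$n_individuals))
    utils::write.table(sz, sizes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Validate a reference-population count table
#'
#' Rows summarise one variant in the reference population: allele count
#' (`allele_count`, AC), total called alleles (`allele_number`, AN) and the
#' number of homozygous individuals. Enforces `AC <= AN`,
#' `2 * homozygote_count <= AC`, `AN > 0` and unique keys.
#'
#' @param df data.frame with columns `variant_id`, `allele_count`,
#'   `allele_number`, `homozygote_count` (plus optional `cdna_hgvs`,
#'   `protein_hgvs`, `consequence`).
#' @return the validated data.frame, class `reference_counts`.
#' @export
reference_counts <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  require_columns(df, c("variant_id", "allele_count", "allele_number",
                        "homozygote_count"), "reference counts")
  df$variant_id <- normalize_variant_id(df$variant_id)
  df$allele_count <- as_count(df$allele_count, "allele_count")
  df$allele_number <- as_count(df$allele_number, "allele_number", min = 1)
  df$homozygote_count <- as_count(df$homozygote_count, "homozygote_count")
  if (nrow(df)) {
    if (anyDuplicated(df$variant_id))
      stop("duplicate variant_id in reference table", call. = FALSE)
    bad <- df$allele_count > df$allele_number
    if (any(bad))
      stop("allele_count > allele_number for: ",
           paste(df$variant_id[bad], collapse = ", "), call. = FALSE)
    bad <- 2L * df$homozygote_count > df$allele_count
    if (any(bad))
      stop("2 * homozygote_count > allele_count for: ",
           paste(df$variant_id[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(df$cdna_hgvs)) df$cdna_hgvs <- df$variant_id
  if (is.null(df$protein_hgvs)) df$protein_hgvs <- rep(NA_character_, nrow(df))
  if (is.null(df$consequence)) df$consequence <- rep(NA_character_, nrow(df))
  class(df) <- c("reference_counts", "data.frame")
  df
}

#' Read a reference-population variant count table
#'
#' @param path TSV with columns `variant_id`, `allele_count`,
#'   `allele_number`, `homozygote_count` (and optionally `cdna_hgvs`,
#'   `protein_hgvs`, `consequence`). An empty table (header only) is valid.
#' @return a `reference_counts` data.frame
#' @export
read_reference_table <- function(path) {
  df <- read_tsv_file(path)
  reference_counts(df)
}

#' Read a family cosegregation table
#'
#' Columns: `family_id`, `variant_id`, `n_sequenced_affected`,
#' `n_carriers_among_sequenced`. Requires
#' `1 <= n_carriers_among_sequenced <= n_sequenced_affected`.
#' @param path TSV path
#' @return data.frame of family records
#' @export
read_family_table <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("family_id", "variant_id", "n_sequenced_affected",
                        "n_carriers_among_sequenced"), basename(path))
  df$variant_id <- normalize_variant_id(df$variant_id)
  df$n_sequenced_affected <-
    as_count(df$n_sequenced_affected, "n_sequenced_affected", min = 1)
  df$n_carriers_among_sequenced <-
    as_count(df$n_carriers_among_sequenced, "n_carriers_among_sequenced",
             min = 1)
  bad <- df$n_carriers_among_sequenced > df$n_sequenced_affected
  if (any(bad))
    stop("carriers exceed sequenced affecteds for family: ",
         paste(df$family_id[bad], collapse = ", "), call. = FALSE)
  df
}

#' Read a curated-override table
#' @param path TSV with columns `variant_id`, `override_consequence` and an
#'   optional free-text `note`.
#' @return data.frame usable as the `overrides` argument of
#'   [classify_variants()]
#' @export
read_override_table <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("variant_id", "override_consequence"), basename(path))
  df$variant_id <- normalize_variant_id(df$variant_id)
  if (!all(df$override_consequence %in% CONSEQUENCES))
    stop("override_consequence outside the consequence enumeration",
         call. = FALSE)
  df
}
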