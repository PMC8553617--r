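# Variant selection and classification: consequence-based LOF assignment,
# frequency/homozygote filters for missense variants, curated overrides, and
# provenance partitioning of the unique-variant universe.

CLASS_CATEGORIES <- c("LOF", "VUS", "excluded_common", "excluded_homozygous",
                      "excluded_other_class")

#' Derive a consequence class from HGVS strings
#'
#' Heuristic derivation used when no consequence annotation is supplied:
#' an intronic offset of -1/-2 in the cDNA string marks a canonical splice
#' acceptor, +1/+2 a splice donor; a protein change containing `fs` is a
#' frameshift; a stop at a substituted residue (`p.(Xxx123*)` or `Ter`) is
#' nonsense; `=` is synonymous; a plain single-residue substitution is
#' missense; any other parseable protein change (in-frame deletion,
#' extension, ...) is `other`.
#'
#' @param cdna_hgvs character vector of cDNA HGVS strings (`c.` prefix).
#' @param protein_hgvs optional character vector of protein HGVS strings
#'   (`NA` when there is none).
#' @return character vector of consequence classes (see [CONSEQUENCES]).
#' @export
derive_consequence <- function(cdna_hgvs, protein_hgvs = NA_character_) {
  cdna <- normalize_variant_id(cdna_hgvs)
  prot <- normalize_variant_id(protein_hgvs)
  prot[!nzchar(prot) | prot == "NA"] <- NA_character_
  if (length(prot) == 1L && length(cdna) > 1L) prot <- rep(prot, length(cdna))
  if (length(prot) != length(cdna))
    stop("cdna_hgvs and protein_hgvs lengths differ", call. = FALSE)
  if (any(!grepl("^c\\.", cdna)))
    stop("cDNA HGVS must carry the 'c.' prefix: ",
         paste(utils::head(cdna[!grepl("^c\\.", cdna)], 3), collapse = ", "),
         call. = FALSE)

  out <- character(length(cdna))
  for (i in seq_along(cdna)) {
    # intronic offsets: a signed integer immediately following an exonic base
    offs <- regmatches(cdna[i],
                       gregexpr("(?<=[0-9])[+-][0-9]+", cdna[i], perl = TRUE))[[1]]
    offn <- as.integer(offs)
    if (any(offn %in% c(-1L, -2L))) { out[i] <- "splice_acceptor"; next }
    if (any(offn %in% c(1L, 2L)))   { out[i] <- "splice_donor";    next }
    p <- prot[i]
    if (is.na(p)) { out[i] <- "other"; next }
    if (grepl("fs", p)) { out[i] <- "frameshift"; next }
    if (grepl("[A-Z][a-z]{2}[0-9]+(\\*|Ter)(\\))?$", p)) {
      out[i] <- "nonsense"; next
    }
    if (grepl("=", p, fixed = TRUE)) { out[i] <- "synonymous"; next }
    if (grepl("^p\\.\\(?[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}\\)?$", p)) {
      out[i] <- "missense"; next
    }
    if (!grepl("^p\\.", p))
      stop("unparseable protein HGVS: ", p, call. = FALSE)
    out[i] <- "other"
  }
  out
}

# Effective consequence: explicit annotation, else derived from HGVS, with
# any curated override taking precedence.
effective_consequence <- function(variants, overrides = default_overrides()) {
  cons <- variants$consequence
  need <- is.na(cons) | !nzchar(cons)
  if (any(need))
    cons[need] <- derive_consequence(variants$cdna_hgvs[need],
                                     variants$protein_hgvs[need])
  bad <- !cons %in% CONSEQUENCES
  if (any(bad))
    stop("consequence absent or underivable for variant(s): ",
         paste(variants$variant_id[bad], collapse = ", "), call. = FALSE)
  if (!is.null(overrides) && nrow(overrides)) {
    m <- match(variants$variant_id, normalize_variant_id(overrides$variant_id))
    hit <- !is.na(m)
    cons[hit] <- overrides$override_consequence[m[hit]]
  }
  cons
}

#' Map a consequence class to the LOF / missense-candidate split
#'
#' Nonsense, frameshift and canonical splice acceptor/donor changes are
#' loss-of-function; missense variants go on to the frequency filters; all
#' other classes are excluded, unless a curated override reassigns them.
#'
#' @param consequence character vector of consequence classes.
#' @return character vector over `{"LOF", "missense_candidate",
#'   "excluded_other_class"}`.
#' @export
classify_consequence <- function(consequence) {
  if (!all(consequence %in% CONSEQUENCES))
    stop("unknown consequence class: ",
         paste(setdiff(consequence, CONSEQUENCES), collapse = ", "),
         call. = FALSE)
  ifelse(consequence %in% LOF_CONSEQUENCES, "LOF",
         ifelse(consequence == "missense", "missense_candidate",
                "excluded_other_class"))
}

#' Frequency and homozygote filters for a candidate missense variant
#'
#' A missense variant is excluded as likely benign if its reference-population
#' allele frequency `AC/AN` exceeds `af_cutoff` (strict; the default 0.005 is
#' the upper estimate of the ataxia-telangiectasia heterozygote frequency),
#' or if more than `max_homozygotes` reference individuals are homozygous.
#' A variant absent from the reference table has AF treated as 0 and is
#' retained.
#'
#' @param ref_ac,ref_an,ref_hom reference allele count, allele number and
#'   homozygote count (`NA` when the variant is absent from the reference).
#' @param af_cutoff strict allele-frequency threshold (default 0.005).
#' @param max_homozygotes retained only if homozygote count is at most this
#'   (default 2, i.e. "more than two" excludes).
#' @return character vector over `{"VUS", "excluded_common",
#'   "excluded_homozygous"}`.
#' @export
apply_missense_filters <- function(ref_ac, ref_an, ref_hom,
                                   af_cutoff = 0.005, max_homozygotes = 2L) {
  n <- max(length(ref_ac), length(ref_an), length(ref_hom))
  ref_ac <- rep_len(ref_ac, n); ref_an <- rep_len(ref_an, n)
  ref_hom <- rep_len(ref_hom, n)
  if (any(!is.na(ref_an) & ref_an == 0))
    stop("reference allele_number of 0", call. = FALSE)
  af <- ifelse(is.na(ref_ac) | is.na(ref_an), 0, ref_ac / ref_an)
  hom <- ifelse(is.na(ref_hom), 0L, ref_hom)
  ifelse(af > af_cutoff, "excluded_common",
         ifelse(hom > max_homozygotes, "excluded_homozygous", "VUS"))
}

#' Default curated consequence overrides
#'
#' Ships the single established reclassification: ATM c.3576G>A, nominally
#' synonymous p.(Lys1192=), is functionally a splice variant causing skipping
#' of exon 26 (p.(Ser1135_Lys1195del58)) and is treated as LOF.
#' @return data.frame with columns `variant_id`, `override_consequence`,
#'   `note`.
#' @export
default_overrides <- function() {
  data.frame(
    variant_id = "c.3576G>A",
    override_consequence = "splice_donor",
    note = paste("functionally a splice variant (exon 26 skipping,",
                 "p.(Ser1135_Lys1195del58)) despite the nominal synonymous",
                 "annotation"),
    stringsAsFactors = FALSE)
}

#' Classify a variant universe into LOF / VUS / excluded categories
#'
#' Applies the full selection algorithm to each unique variant: curated
#' overrides first, then consequence-based LOF assignment, then the
#' allele-frequency and homozygote filters for missense candidates. Every
#' variant receives exactly one of `LOF`, `VUS`, `excluded_common`,
#' `excluded_homozygous`, `excluded_other_class`.
#'
#' @param variants data.frame with columns `variant_id`, `cdna_hgvs`,
#'   `protein_hgvs`, `consequence` (a `cohort_dataset$variants` table or a
#'   `reference_counts` table both qualify).
#' @param reference optional `reference_counts` table supplying AF and
#'   homozygote counts for the missense filters. When `variants` itself
#'   carries `allele_count`/`allele_number` columns (a reference table being
#'   classified) those are used for rows missing from `reference`.
#' @param overrides curated override table (default [default_overrides()]).
#' @param af_cutoff,max_homozygotes see [apply_missense_filters()].
#' @return data.frame with columns `variant_id`, `consequence` (effective),
#'   `category`, `reason`; class `classification_outcomes`.
#' @export
classify_variants <- function(variants, reference = NULL,
                              overrides = default_overrides(),
                              af_cutoff = 0.005, max_homozygotes = 2L) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (anyDuplicated(variants$variant_id))
    stop("variant universe contains duplicate variant_id", call. = FALSE)
  cons <- effective_consequence(variants, overrides)
  base <- classify_consequence(cons)

  ac <- rep(NA_real_, nrow(variants)); an <- ac; hom <- ac
  if (!is.null(reference) && nrow(reference)) {
    m <- match(variants$variant_id, reference$variant_id)
    ac <- reference$allele_count[m]
    an <- reference$allele_number[m]
    hom <- reference$homozygote_count[m]
  }
  if (!is.null(variants$allele_count)) {
    use <- is.na(ac) & !is.na(variants$allele_count)
    ac[use] <- variants$allele_count[use]
    an[use] <- variants$allele_number[use]
    hom[use] <- variants$homozygote_count[use]
  }

  category <- character(nrow(variants))
  reason <- character(nrow(variants))
  is_lof <- base == "LOF"
  category[is_lof] <- "LOF"
  reason[is_lof] <- paste0("consequence ", cons[is_lof])
  is_mis <- base == "missense_candidate"
  if (any(is_mis)) {
    category[is_mis] <- apply_missense_filters(
      ac[is_mis], an[is_mis], hom[is_mis], af_cutoff, max_homozygotes)
    af <- ifelse(is.na(ac) | is.na(an), 0, ac / an)
    reason[is_mis] <- sprintf("missense, reference AF %.3g, homozygotes %d",
                              af[is_mis],
                              as.integer(ifelse(is.na(hom[is_mis]), 0,
                                                hom[is_mis])))
  }
  is_other <- base == "excluded_other_class"
  category[is_other] <- "excluded_other_class"
  reason[is_other] <- paste0("consequence ", cons[is_other],
                             " not in the LOF or missense classes")

  out <- data.frame(variant_id = variants$variant_id, consequence = cons,
                    category = category, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("classification_outcomes", "data.frame")
  out
}

#' Partition a variant universe by provenance
#'
#' Splits the union of case-seen and reference-seen variant keys into
#' study-only, reference-only and shared counts.
#'
#' @param case_variant_ids,reference_variant_ids character vectors of variant
#'   keys (duplicates ignored).
#' @return list with integer components `study_only`, `reference_only`,
#'   `both`, `total`.
#' @export
partition_provenance <- function(case_variant_ids, reference_variant_ids) {
  cs <- unique(normalize_variant_id(case_variant_ids))
  rf <- unique(normalize_variant_id(reference_variant_ids))
  cs <- cs[nzchar(cs) & cs != "NA"]
  rf <- rf[nzchar(rf) & rf != "NA"]
  both <- length(intersect(cs, rf))
  out <- list(study_only = length(cs) - both,
              reference_only = length(rf) - both,
              both = both)
  out$total <- out$study_only + out$reference_only + out$both
  out
}
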