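# ATM functional-domain annotation and protein-residue anchoring.

#' Default ATM functional domain intervals
#'
#' The three functional domains of the 3,056-residue ATM protein, with
#' inclusive residue bounds: FAT (1940-2566), the PI3K/PI4K kinase domain
#' (2712-2962) and FATC (3024-3056).
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
atm_domains <- function() {
  data.frame(label = c("FAT", "PI3K/PI4K", "FATC"),
             start = c(1940L, 2712L, 3024L),
             end   = c(2566L, 2962L, 3056L),
             stringsAsFactors = FALSE)
}

validate_domains <- function(domains) {
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  require_columns(domains, c("label", "start", "end"), "domain config")
  domains$start <- as_count(domains$start, "domain start", min = 1)
  domains$end <- as_count(domains$end, "domain end", min = 1)
  if (any(domains$start > domains$end))
    stop("domain start exceeds end", call. = FALSE)
  o <- order(domains$start)
  s <- domains$start[o]; e <- domains$end[o]
  if (nrow(domains) > 1L && any(s[-1] <= e[-nrow(domains)]))
    stop("domain intervals overlap", call. = FALSE)
  domains
}

#' Read a domain-interval override table
#' @param path TSV with columns `label`, `start`, `end`.
#' @export
read_domain_table <- function(path) validate_domains(read_tsv_file(path))

#' Anchor a variant to a protein residue
#'
#' The anchor is the first residue number in the protein HGVS string when one
#' is present. Variants with only cDNA coordinates (splice changes) are
#' anchored at `ceiling(first exonic cDNA position / 3)` for plotting;
#' notation with no parsable exonic base yields `NA`.
#'
#' @param protein_hgvs,cdna_hgvs character vectors (either may be `NA`
#'   element-wise).
#' @return integer vector of residue indices (`NA` when no anchor exists).
#' @export
protein_position_of <- function(protein_hgvs, cdna_hgvs = NA_character_) {
  prot <- normalize_variant_id(protein_hgvs)
  cdna <- normalize_variant_id(cdna_hgvs)
  n <- max(length(prot), length(cdna))
  prot <- rep_len(prot, n); cdna <- rep_len(cdna, n)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- prot[i]
    if (!is.na(p) && nzchar(p) && p != "NA" && grepl("[0-9]", p)) {
      out[i] <- as.integer(regmatches(p, regexpr("[0-9]+", p)))
    } else {
      cd <- cdna[i]
      if (!is.na(cd) && grepl("^c\\.[0-9]", cd)) {
        pos <- as.integer(regmatches(cd, regexpr("(?<=c\\.)[0-9]+", cd,
                                                 perl = TRUE)))
        out[i] <- as.integer(ceiling(pos / 3))
      }
    }
  }
  out
}

# Residue anchors for a variant table, with their source: a residue parsed
# from the protein change ("protein"), a cDNA-derived plotting anchor
# ("cdna"), or none. Domain-restricted analyses only trust protein anchors;
# cDNA anchors exist for lollipop export only.
anchor_table <- function(variants) {
  prot <- normalize_variant_id(variants$protein_hgvs)
  has_prot <- !is.na(prot) & nzchar(prot) & prot != "NA" & grepl("[0-9]", prot)
  pos <- protein_position_of(variants$protein_hgvs, variants$cdna_hgvs)
  source <- ifelse(has_prot, "protein", ifelse(is.na(pos), "none", "cdna"))
  data.frame(variant_id = variants$variant_id, position = pos,
             source = source, stringsAsFactors = FALSE)
}

#' Assign residues to ATM functional domains
#'
#' Inclusive-bound interval membership; a residue in none of the configured
#' intervals maps to `"outside"`.
#'
#' @param position integer vector of residue indices (>= 1; `NA` allowed and
#'   maps to `"outside"`, since an unanchored variant cannot lie inside a
#'   protein domain).
#' @param domains domain config data.frame (default [atm_domains()]).
#' @return character vector of domain labels or `"outside"`.
#' @export
annotate_domain <- function(position, domains = atm_domains()) {
  domains <- validate_domains(domains)
  if (any(!is.na(position) & position < 1))
    stop("residue position below 1", call. = FALSE)
  out <- rep("outside", length(position))
  for (j in seq_len(nrow(domains))) {
    hit <- !is.na(position) & position >= domains$start[j] &
      position <= domains$end[j]
    out[hit] <- domains$label[j]
  }
  out
}
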