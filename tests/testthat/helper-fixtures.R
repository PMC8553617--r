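# Small in-code fixtures shared across test files.

mk_variants <- function(ids, consequence = "missense", protein = NA_character_) {
  data.frame(variant_id = ids, cdna_hgvs = ids,
             protein_hgvs = rep_len(protein, length(ids)),
             consequence = rep_len(consequence, length(ids)),
             stringsAsFactors = FALSE)
}

mk_cohort <- function(obs, variants = NULL,
                      sizes = c(familial = 100L, MPM = 50L, sporadic = 80L)) {
  if (is.null(variants)) mk_variants(unique(obs$variant_id)) -> variants
  if (is.null(obs$center)) obs$center <- "T"
  if (is.null(obs$zygosity)) obs$zygosity <- "het"
  cohort_dataset(obs, variants, sizes)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# independent brute-force two-sided Fisher p: enumerate the whole
# hypergeometric support with choose(), sum point masses <= observed
brute_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(n1, k)
  pm <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  p0 <- pm[xs == a]
  sum(pm[pm <= p0 * (1 + 1e-7)])
}
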