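# Within-family cosegregation of a variant with disease, summarized as
# carriers / sequenced affected relatives.

COSEG_STATUSES <- c("yes", "partial", "no", "not_determined")

#' Classify family cosegregation from carrier counts
#'
#' Status is a pure function of (carriers, sequenced affected relatives):
#' with a single sequenced case the proband carries by construction and
#' nothing can be determined (`not_determined`); all sequenced affecteds
#' carrying (>= 2 of them) is full cosegregation (`yes`); a single carrier
#' among several is `no`; two or more but not all is `partial`.
#'
#' @param n_carriers,n_sequenced integer vectors,
#'   `1 <= n_carriers <= n_sequenced`.
#' @return character vector over
#'   `{"yes", "partial", "no", "not_determined"}`.
#' @export
classify_cosegregation <- function(n_carriers, n_sequenced) {
  n <- max(length(n_carriers), length(n_sequenced))
  k <- rep_len(as.integer(n_carriers), n)
  s <- rep_len(as.integer(n_sequenced), n)
  if (anyNA(k) || anyNA(s) || any(s < 1) || any(k < 1))
    stop("carrier and sequenced counts must be integers >= 1", call. = FALSE)
  if (any(k > s))
    stop("carriers exceed sequenced affecteds", call. = FALSE)
  ifelse(s == 1L, "not_determined",
         ifelse(k == s, "yes",
                ifelse(k == 1L, "no", "partial")))
}

#' Cosegregation calls for a family table
#'
#' @param families data.frame of family records ([read_family_table()]
#'   dialect: `family_id`, `variant_id`, `n_sequenced_affected`,
#'   `n_carriers_among_sequenced`).
#' @return the input with added columns `status` and `ratio`
#'   (e.g. `"2/3"`).
#' @export
cosegregation_calls <- function(families) {
  require_columns(families, c("family_id", "n_sequenced_affected",
                              "n_carriers_among_sequenced"), "family table")
  families$status <- classify_cosegregation(
    families$n_carriers_among_sequenced, families$n_sequenced_affected)
  families$ratio <- paste0(families$n_carriers_among_sequenced, "/",
                           families$n_sequenced_affected)
  families
}

#' Summarize cosegregation statuses over families
#'
#' @param families data.frame of family records.
#' @return named integer vector with counts for `yes`, `partial`, `no`,
#'   `not_determined`; the counts sum to the number of records.
#' @export
summarize_cosegregation <- function(families) {
  if (is.null(families) || nrow(families) == 0)
    return(stats::setNames(integer(length(COSEG_STATUSES)), COSEG_STATUSES))
  calls <- cosegregation_calls(families)
  tab <- table(factor(calls$status, COSEG_STATUSES))
  stats::setNames(as.integer(tab), COSEG_STATUSES)
}
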