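# Transcribed reference tables from a published manual-vs-automatic CYP2
# substrate-classification comparison on a German emergency-department
# ADR cohort (ADRED). Shipped under inst/extdata/ as plain TSVs:
#
#   adred_agreement_marginals.tsv  per (resource, enzyme): jointly
#       assessed drug count and the two methods' substrate marginals
#   adred_disagreements.tsv        drugs the methods classified
#       differently, with tri-state codes (x substrate, - non-substrate,
#       NA not assessed) per resource and dataset entry counts; a
#       combined "(dex)ibuprofen" listing is transcribed as two rows
#
# Together these determine the full 2x2 agreement table for each
# comparison (see reconstruct_contingency()).

#' Load the transcribed reference agreement tables
#'
#' Reads the shipped marginal and disagreement transcriptions and
#' reconstructs the 2x2 agreement table for every (resource, enzyme)
#' comparison of the manual method against an automatic resource: the
#' manual-only disagreement count `b` is the number of listed drugs the
#' manual method called substrate while the resource, having assessed
#' them, did not; the remaining cells follow from the marginals.
#'
#' Comparisons whose reconstruction is infeasible (inconsistent
#' marginals) are returned with a `NULL` table rather than an error, so
#' callers can see which published rows are internally consistent.
#'
#' @param marginals_path,disagreements_path Paths to the two TSVs;
#'   default to the transcriptions shipped with the package.
#' @return Tibble with columns `comparison`, `enzyme`, `n_joint`,
#'   `manual_substrates`, `automatic_substrates`, `manual_only`, and a
#'   list-column `table` of [contingency_2x2()] objects (or `NULL`).
#' @export
#' @examples
#' ref <- reference_agreement_tables()
#' cohens_kappa(ref$table[[1]])
reference_agreement_tables <- function(
    marginals_path = system.file("extdata", "adred_agreement_marginals.tsv",
                                 package = "cypmatch"),
    disagreements_path = system.file("extdata", "adred_disagreements.tsv",
                                     package = "cypmatch")) {
  marg <- readr::read_tsv(marginals_path, col_types = "cciii",
                          progress = FALSE)
  dis <- readr::read_tsv(disagreements_path, col_types = readr::cols(
    .default = readr::col_character(), entries = readr::col_integer()
  ), na = character(), progress = FALSE)
  marg$manual_only <- NA_integer_
  marg$table <- vector("list", nrow(marg))
  for (i in seq_len(nrow(marg))) {
    col <- tolower(marg$comparison[i])
    stopifnot(col %in% names(dis))
    rows <- dis[dis$enzyme == marg$enzyme[i], , drop = FALSE]
    b <- sum(rows$manual == "x" & rows[[col]] == "-")
    marg$manual_only[i] <- b
    tab <- tryCatch(
      reconstruct_contingency(
        n = marg$n_joint[i],
        marginal_a = marg$manual_substrates[i],
        marginal_b = marg$automatic_substrates[i],
        a_only = b,
        method_a = "MANUAL", method_b = marg$comparison[i],
        enzyme = marg$enzyme[i]),
      error = function(e) NULL
    )
    marg$table[i] <- list(tab)
  }
  marg
}

#' Load the transcribed disagreement listing
#'
#' @param path Path to the disagreements TSV (default: shipped
#'   transcription).
#' @return Tibble with `enzyme`, `drug`, per-method tri-state code
#'   columns (`manual`, `drugbank`, `fda`, `flockhart`; codes `x`, `-`,
#'   `NA`), and `entries`.
#' @export
reference_disagreements <- function(
    path = system.file("extdata", "adred_disagreements.tsv",
                       package = "cypmatch")) {
  readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(), entries = readr::col_integer()
  ), na = character(), progress = FALSE)
}
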