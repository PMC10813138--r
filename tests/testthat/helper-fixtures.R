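# Shared helpers: fixture paths, an independent kappa oracle, and a
# builder turning transcribed tri-state codes into a classification
# matrix.

`%||%` <- function(x, y) if (is.null(x)) y else x

digest_file <- function(path) unname(tools::md5sum(path))

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cypmatch")
  if (path == "") stop("missing extdata fixture: ", file)
  path
}

# Independent Cohen's kappa oracle via the observed/expected-agreement
# route (the implementation uses the single integer-ratio form); exact
# rational bookkeeping through a common denominator of n^2.
oracle_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  po_num <- (a + d) * n               # p_o over denominator n^2
  pe_num <- (a + b) * (a + c) + (c + d) * (b + d)
  if (pe_num == n^2) return(NA_real_)
  (po_num - pe_num) / (n^2 - pe_num)
}

# Build a classification matrix from tri-state codes as used in the
# transcribed disagreement listing: "x" substrate, "-" non-substrate,
# "NA" not assessed. `codes` is a data.frame with columns drug, enzyme
# and one column per method id.
matrix_from_codes <- function(codes, methods) {
  decode <- c(x = "substrate", `-` = "non_substrate",
              `NA` = "not_assessed")
  slices <- lapply(methods, function(m) {
    tibble::tibble(
      drug = codes$drug, method = m, enzyme = codes$enzyme,
      state = unname(decode[codes[[m]]])
    )
  })
  classification_matrix(dplyr::bind_rows(slices))
}

mini_index <- function() {
  read_name_index(extdata("name_index_atc.tsv"),
                  extdata("name_index_names.tsv"))
}
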