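# Building the drug x method x enzyme tri-state classification matrix.

#' Classify drugs automatically against a substrate resource
#'
#' Produces one tri-state assessment per drug and enzyme by looking each
#' canonical name up in the resource. Unresolved drugs (`NA` names) are
#' classified `"not_assessed"` for every enzyme, with a warning.
#'
#' @param drugs Character vector of canonical drug names, or a drug-record
#'   tibble with a `canonical_name` column.
#' @param resource A [substrate_resource()].
#' @return A classification slice: tibble with columns `drug`, `method`
#'   (the resource id), `enzyme`, `state`.
#' @export
classify_automatic <- function(drugs, resource) {
  stopifnot(inherits(resource, "substrate_resource"))
  if (is.data.frame(drugs)) drugs <- drugs$canonical_name
  if (length(drugs) == 0L) {
    return(tibble::tibble(drug = character(), method = character(),
                          enzyme = character(), state = character()))
  }
  if (anyNA(drugs)) {
    warning(sum(is.na(drugs)),
            " unresolved drug name(s) classified not_assessed",
            call. = FALSE)
  }
  slices <- lapply(resource$enzymes, function(enz) {
    state <- rep("not_assessed", length(drugs))
    ok <- !is.na(drugs)
    state[ok] <- substrate_lookup(resource, drugs[ok], enz)
    tibble::tibble(drug = ifelse(is.na(drugs), "<unresolved>",
                                 tolower(drugs)),
                   method = resource$id, enzyme = enz, state = state)
  })
  dplyr::bind_rows(slices)
}

#' Read a manual-assessment table
#'
#' The manual method is a standardized, consensus-based literature review;
#' the package ingests its result as data: a TSV with a `name` column and
#' one 0/1 (or TRUE/FALSE) column per configured enzyme. Optional
#' provenance columns (e.g. `reviewer_1`, `reviewer_2`, `consensus`) are
#' carried through untouched.
#'
#' @param path TSV file path.
#' @param enzymes Configured enzyme set; a missing enzyme column is an
#'   error naming the column.
#' @return Tibble with `name` (lowercase, unique) and one logical column
#'   per enzyme.
#' @export
read_manual_assessments <- function(path, enzymes = cyp_enzymes()) {
  if (!file.exists(path)) {
    stop("manual assessment table not found: ", path, call. = FALSE)
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"name" %in% names(tab)) {
    stop("manual table: missing 'name' column", call. = FALSE)
  }
  missing_cols <- setdiff(enzymes, names(tab))
  if (length(missing_cols) > 0L) {
    stop("manual table: missing enzyme column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$name <- tolower(stringr::str_squish(tab$name))
  dup <- unique(tab$name[duplicated(tab$name)])
  if (length(dup) > 0L) {
    stop("manual table: duplicate drug row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (e in enzymes) {
    v <- toupper(stringr::str_squish(tab[[e]]))
    if (any(is.na(v) | !v %in% c("0", "1", "TRUE", "FALSE", "T", "F"))) {
      stop("manual table: non-boolean value in column ", e, call. = FALSE)
    }
    tab[[e]] <- v %in% c("1", "TRUE", "T")
  }
  tab
}

#' Classify drugs from a manual-assessment table
#'
#' Drugs present in the table get `"substrate"`/`"non_substrate"` per the
#' flags; drugs outside the table — typically those below the manual
#' selection frequency threshold — are `"not_assessed"`.
#'
#' @param drugs Character vector of canonical names (or drug-record
#'   tibble).
#' @param manual Table from [read_manual_assessments()].
#' @param method Method id recorded in the slice.
#' @param enzymes Enzyme set (defaults to the table's enzyme columns).
#' @return A classification slice tibble (`drug`, `method`, `enzyme`,
#'   `state`).
#' @export
classify_manual <- function(drugs, manual, method = "MANUAL",
                            enzymes = NULL) {
  if (is.data.frame(drugs)) drugs <- drugs$canonical_name
  drugs <- tolower(drugs)
  enzymes <- enzymes %||% intersect(cyp_enzymes(), names(manual))
  slices <- lapply(enzymes, function(enz) {
    idx <- match(drugs, manual$name)
    state <- ifelse(is.na(idx), "not_assessed",
                    ifelse(manual[[enz]][idx], "substrate",
                           "non_substrate"))
    tibble::tibble(drug = drugs, method = method, enzyme = enz,
                   state = state)
  })
  dplyr::bind_rows(slices)
}

#' Combine classification slices into one matrix
#'
#' @param ... Classification slices (tibbles with `drug`, `method`,
#'   `enzyme`, `state`), e.g. from [classify_automatic()] and
#'   [classify_manual()].
#' @return A single validated long-format tibble of class
#'   `classification_matrix`. Method order follows first appearance.
#' @export
classification_matrix <- function(...) {
  m <- dplyr::bind_rows(...)
  stopifnot(all(c("drug", "method", "enzyme", "state") %in% names(m)))
  assert_states(m$state)
  key <- paste(m$drug, m$method, m$enzyme, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (drug, method, enzyme) assessment(s)", call. = FALSE)
  }
  structure(m, class = c("classification_matrix", class(tibble::tibble())),
            methods = unique(m$method), enzymes = unique(m$enzyme))
}

matrix_methods <- function(matrix) {
  attr(matrix, "methods") %||% unique(matrix$method)
}

matrix_enzymes <- function(matrix) {
  attr(matrix, "enzymes") %||% unique(matrix$enzyme)
}

#' Per-method classification counts
#'
#' Summarizes, per method and enzyme, how many drugs were assessed (state
#' other than `"not_assessed"`) and how many were classified substrates —
#' the shape of a per-resource classification summary table.
#'
#' @param matrix A [classification_matrix()].
#' @return Tibble with `method`, `enzyme`, `n_assessed`, `n_substrate`,
#'   `pct_substrate` (of assessed, 1 decimal).
#' @export
classification_counts <- function(matrix) {
  matrix |>
    dplyr::group_by(method = .data$method, enzyme = .data$enzyme) |>
    dplyr::summarise(
      n_assessed = sum(.data$state != "not_assessed"),
      n_substrate = sum(.data$state == "substrate"),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_substrate = round(
      100 * .data$n_substrate / pmax(.data$n_assessed, 1L), 1))
}

#' Drugs classified substrate by exactly one method
#'
#' Reports drugs a single method calls a substrate of the given enzyme
#' while every other method calls them non-substrate or has not assessed
#' them — the classifications most worth manual re-examination.
#'
#' @param matrix A [classification_matrix()] with at least two methods.
#' @param enzyme Enzyme identifier.
#' @return Tibble with `drug` and `method` (the uniquely classifying
#'   method), sorted by drug.
#' @export
unique_classifications <- function(matrix, enzyme) {
  if (length(matrix_methods(matrix)) < 2L) {
    stop("unique_classifications needs at least two methods",
         call. = FALSE)
  }
  assert_enzyme(enzyme, matrix_enzymes(matrix))
  sl <- matrix[matrix$enzyme == enzyme, , drop = FALSE]
  sub <- sl[sl$state == "substrate", c("drug", "method")]
  counts <- table(sub$drug)
  uniq <- names(counts)[counts == 1L]
  out <- sub[sub$drug %in% uniq, , drop = FALSE]
  tibble::as_tibble(out[order(out$drug), , drop = FALSE])
}

#' Write / read a classification matrix as long-format CSV
#'
#' @param matrix A [classification_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a `classification_matrix` (reader).
#' @export
write_classification_matrix <- function(matrix, path) {
  readr::write_csv(tibble::as_tibble(matrix), path)
  invisible(path)
}

#' @rdname write_classification_matrix
#' @export
read_classification_matrix <- function(path) {
  tab <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  classification_matrix(tab)
}
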