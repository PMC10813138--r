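# Reading, splitting, excluding and aggregating medication-entry tables.

#' Read a medication-entry table
#'
#' Reads a delimited text file with one row per documented drug use. Rows
#' with an empty or missing substance name are not silently dropped: they
#' are returned separately so a pipeline can report them.
#'
#' @param path Path to a CSV or TSV file (UTF-8).
#' @param case_col,name_col,atc_col Column names holding the case
#'   identifier, the raw substance name as documented, and the (optional)
#'   ATC code. Set `atc_col = NULL` if the table has no ATC column.
#' @param delim Field delimiter; if `NULL` it is inferred from the header
#'   line (tab if present, comma otherwise).
#' @return A list with two tibbles: `entries` (columns `case_id`,
#'   `raw_name`, `atc_code`, `source_row`; `source_row` is the 1-based data
#'   row in the file) and `rejected` (columns `source_row`, `reason`).
#' @export
#' @examples
#' path <- system.file("extdata", "medication_mini.csv", package = "cypmatch")
#' read_medication_table(path)$entries
read_medication_table <- function(path, case_col = "case_id",
                                  name_col = "name", atc_col = "atc",
                                  delim = NULL) {
  if (!file.exists(path)) {
    stop("medication table not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    stop("malformed medication table at line(s) ",
         paste(unique(probs$row), collapse = ", "), ": ",
         probs$expected[1], call. = FALSE)
  }
  needed <- c(case_col, name_col)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_atc <- !is.null(atc_col) && atc_col %in% names(tab)
  entries <- tibble::tibble(
    case_id = as.character(tab[[case_col]]),
    raw_name = stringr::str_squish(as.character(tab[[name_col]])),
    atc_code = if (has_atc) as.character(tab[[atc_col]]) else NA_character_,
    source_row = seq_len(nrow(tab))
  )
  bad <- is.na(entries$raw_name) | entries$raw_name == ""
  rejected <- tibble::tibble(
    source_row = entries$source_row[bad],
    reason = rep("empty substance name", sum(bad))
  )
  list(entries = entries[!bad, , drop = FALSE], rejected = rejected)
}

#' Split combination products into single substances
#'
#' Combination products such as `"hydrochlorothiazide/ramipril"` are split
#' on the configured separators; each part inherits the case identifier.
#' A combination-level ATC code (which identifies the product, not the
#' single substances) is attached to every part and flagged ambiguous so
#' that downstream name resolution can prefer the name over the code.
#'
#' @param entries Tibble of medication entries as returned by
#'   [read_medication_table()].
#' @param separators Character vector of literal separator strings.
#' @return The entries tibble with one row per single substance and an
#'   added logical column `ambiguous_atc`.
#' @export
split_combinations <- function(entries, separators = c("/", "+")) {
  if (length(separators) == 0L) {
    return(dplyr::mutate(entries, ambiguous_atc = FALSE))
  }
  pattern <- paste0("\\s*(", paste(vapply(separators, function(s) {
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  }, character(1)), collapse = "|"), ")\\s*")
  parts <- stringr::str_split(entries$raw_name, pattern)
  parts <- lapply(parts, function(p) p[p != ""])
  n_parts <- lengths(parts)
  if (any(n_parts == 0L)) {
    bad <- entries$source_row[n_parts == 0L]
    stop("separator-only substance name at source row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- entries[rep(seq_len(nrow(entries)), n_parts), , drop = FALSE]
  out$raw_name <- unlist(parts, use.names = FALSE)
  out$ambiguous_atc <- rep(n_parts > 1L, n_parts) & !is.na(out$atc_code)
  tibble::as_tibble(out)
}

#' Rules excluding unspecific names and food supplements
#'
#' Cleaning of a real-world medication list removes rows that do not name
#' a single classifiable substance: unspecific free-text names and dietary
#' or food supplements. The rules are data, not code: a user-editable list
#' of (normalized) names plus ATC prefix rules (e.g. the vitamin and
#' mineral-supplement ATC groups `A11`/`A12`).
#'
#' @param names Character vector of normalized names to exclude.
#' @param atc_prefixes Character vector of ATC code prefixes to exclude.
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(names = character(), atc_prefixes = character()) {
  structure(
    list(names = tolower(stringr::str_squish(names)),
         atc_prefixes = toupper(atc_prefixes)),
    class = "exclusion_rules"
  )
}

#' @rdname exclusion_rules
#' @export
default_exclusion_rules <- function() {
  exclusion_rules(
    names = c("multivitamin", "vitamin preparation", "herbal preparation",
              "food supplement", "electrolyte solution", "homeopathic remedy",
              "unknown", "unspecified"),
    atc_prefixes = c("A11", "A12")
  )
}

#' Apply exclusion rules to medication entries
#'
#' @param entries Entries tibble (after splitting).
#' @param rules An [exclusion_rules()] object.
#' @return List with `kept` (entries tibble) and `excluded` (tibble of
#'   `raw_name`, `rule`, `source_row`).
#' @export
apply_exclusions <- function(entries, rules = default_exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  norm <- tolower(stringr::str_squish(entries$raw_name))
  by_name <- norm %in% rules$names
  by_atc <- rep(FALSE, nrow(entries))
  if (length(rules$atc_prefixes) > 0L) {
    atc <- toupper(entries$atc_code)
    for (p in rules$atc_prefixes) {
      by_atc <- by_atc | (!is.na(atc) & startsWith(atc, p))
    }
  }
  rule <- dplyr::case_when(
    by_name ~ "excluded name",
    by_atc ~ "excluded ATC prefix",
    .default = NA_character_
  )
  drop <- !is.na(rule)
  list(
    kept = entries[!drop, , drop = FALSE],
    excluded = tibble::tibble(
      raw_name = entries$raw_name[drop],
      rule = rule[drop],
      source_row = entries$source_row[drop]
    )
  )
}

#' Aggregate medication entries into per-drug records
#'
#' Groups entries by the canonical (resolved) drug name and computes the
#' entry count, the number of distinct cases documenting the drug, and the
#' fraction of all cases. A drug documented twice within one case counts
#' once toward `case_count` and twice toward `entry_count`. Entries whose
#' resolution failed are kept out of the drug records and reported in the
#' summary, preserving the conservation identity
#' `sum(entry_count) + n_entries_unresolved == nrow(entries)`.
#'
#' @param entries Entries tibble (after splitting/cleaning).
#' @param resolutions Resolution tibble from [resolve_names()], joined by
#'   `raw_name` (and `atc_code` where present).
#' @param n_cases Total number of distinct cases in the dataset; defaults
#'   to the number of distinct `case_id` values in `entries`.
#' @return List with `records` (tibble: `canonical_name`, `atc_codes`,
#'   `entry_count`, `case_count`, `case_fraction`, sorted by descending
#'   `entry_count`) and `summary` (list of dataset-level counts).
#' @export
aggregate_drugs <- function(entries, resolutions, n_cases = NULL) {
  if (is.null(n_cases)) {
    n_cases <- dplyr::n_distinct(entries$case_id)
  }
  if (!is.numeric(n_cases) || n_cases < 1L) {
    stop("total case count unknown or invalid", call. = FALSE)
  }
  res <- dplyr::distinct(resolutions, .data$raw_name, .keep_all = TRUE)
  joined <- dplyr::left_join(entries, res[, c("raw_name", "canonical_name")],
                             by = "raw_name")
  unresolved <- is.na(joined$canonical_name)
  resolved <- joined[!unresolved, , drop = FALSE]
  records <- resolved |>
    dplyr::group_by(canonical_name = .data$canonical_name) |>
    dplyr::summarise(
      atc_codes = paste(sort(unique(stats::na.omit(.data$atc_code))),
                        collapse = ";"),
      entry_count = dplyr::n(),
      case_count = dplyr::n_distinct(.data$case_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(case_fraction = .data$case_count / n_cases) |>
    dplyr::arrange(dplyr::desc(.data$entry_count), .data$canonical_name)
  summary <- list(
    n_cases = as.integer(n_cases),
    n_entries = nrow(entries),
    n_entries_counted = sum(records$entry_count),
    n_entries_unresolved = sum(unresolved),
    n_drugs = nrow(records)
  )
  stopifnot(summary$n_entries_counted + summary$n_entries_unresolved ==
              summary$n_entries)
  list(records = records, summary = summary)
}

#' Select drugs frequent enough for manual assessment
#'
#' Manual literature review is time-consuming, so only drugs documented in
#' at least a given fraction of all cases are assessed manually (the
#' published workflow used 3% of cases). The comparison is on the case
#' fraction, computed over distinct cases, with a closed lower bound
#' (`case_fraction >= threshold_fraction`).
#'
#' @param records Drug-record tibble from [aggregate_drugs()].
#' @param threshold_fraction Minimum case fraction, in `[0, 1]`.
#' @return The qualifying subset, ordered by descending `entry_count`.
#' @export
select_frequent_drugs <- function(records, threshold_fraction = 0.03) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      is.na(threshold_fraction) || threshold_fraction < 0 ||
      threshold_fraction > 1) {
    stop("threshold_fraction must be a single number in [0, 1]",
         call. = FALSE)
  }
  if (!"case_fraction" %in% names(records) ||
      anyNA(records$case_fraction)) {
    stop("case_fraction unavailable: total case count unknown",
         call. = FALSE)
  }
  out <- records[records$case_fraction >= threshold_fraction, , drop = FALSE]
  out[order(-out$entry_count, out$canonical_name), , drop = FALSE]
}
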