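# File-based pipeline runners behind the command-line front end:
# normalize -> classify -> compare, plus simulate. Each runner writes its
# machine-readable outputs (CSV/TSV/JSON) to an output directory and
# removes partial outputs on failure so a crashed run leaves no
# half-written files behind.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

with_output_dir <- function(output_dir, files, body) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(output_dir, files)
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  result <- body(paths)
  ok <- TRUE
  result
}

#' Run the normalization stage
#'
#' Reads a medication table, splits combination products, applies
#' exclusion rules, resolves names through the cascade, and aggregates
#' per-drug records. Writes `drug_records.csv`, `summary.json`,
#' `resolutions.csv` and `exclusions.tsv` into `output_dir`.
#'
#' @param input Path to the medication table (CSV/TSV).
#' @param index A [name_index()] or path to an ATC-to-name TSV.
#' @param output_dir Output directory (created if needed).
#' @param overrides Optional [override_map()] or TSV path.
#' @param names_path Optional canonical-name list TSV (when `index` is a
#'   path).
#' @param separators Combination separators.
#' @param exclusions An [exclusion_rules()] object.
#' @param case_col,name_col,atc_col Input column names.
#' @return Invisibly, a list with `records`, `summary`, `resolutions`,
#'   `excluded`.
#' @export
run_normalize <- function(input, index, output_dir,
                          overrides = NULL, names_path = NULL,
                          separators = c("/", "+"),
                          exclusions = default_exclusion_rules(),
                          case_col = "case_id", name_col = "name",
                          atc_col = "atc") {
  if (is.character(index)) {
    index <- read_name_index(index, names_path)
  }
  if (is.character(overrides)) {
    overrides <- read_override_map(overrides, index)
  }
  files <- c("drug_records.csv", "summary.json", "resolutions.csv",
             "exclusions.tsv")
  with_output_dir(output_dir, files, function(paths) {
    reading <- read_medication_table(input, case_col = case_col,
                                     name_col = name_col,
                                     atc_col = atc_col)
    n_raw <- nrow(reading$entries) + nrow(reading$rejected)
    split <- split_combinations(reading$entries, separators)
    cleaned <- apply_exclusions(split, exclusions)
    kept <- cleaned$kept
    res <- resolve_names(kept$raw_name,
                         ifelse(kept$ambiguous_atc, NA_character_,
                                kept$atc_code),
                         index, overrides)
    agg <- aggregate_drugs(kept, dplyr::distinct(res, .data$raw_name,
                                                 .keep_all = TRUE))
    summary <- c(
      list(n_rows_raw = n_raw,
           n_rows_rejected = nrow(reading$rejected),
           n_entries_after_split = nrow(split),
           n_entries_excluded = nrow(cleaned$excluded)),
      agg$summary
    )
    # conservation: every split part is counted, excluded, or unresolved
    stopifnot(summary$n_entries_after_split ==
                summary$n_entries_counted + summary$n_entries_unresolved +
                summary$n_entries_excluded)
    readr::write_csv(agg$records, paths[1])
    write_json_file(summary, paths[2])
    readr::write_csv(dplyr::distinct(res, .data$raw_name, .keep_all = TRUE),
                     paths[3])
    readr::write_tsv(cleaned$excluded, paths[4])
    invisible(list(records = agg$records, summary = summary,
                   resolutions = res, excluded = cleaned$excluded))
  })
}

#' Run the classification stage
#'
#' Classifies the drug records against every automatic resource and, for
#' the frequent subset, against the manual-assessment table. Writes the
#' long-format matrix (`classification_matrix.csv`) and the per-method
#' count summary (`classification_counts.json`).
#'
#' @param records Drug-record tibble or path to `drug_records.csv`.
#' @param resources Named list of [substrate_resource()] objects or
#'   snapshot file paths (names become method ids when paths lack an id
#'   pragma).
#' @param output_dir Output directory.
#' @param manual Optional manual table (from
#'   [read_manual_assessments()]) or TSV path.
#' @param threshold Case-fraction threshold for manual assessment
#'   eligibility.
#' @param enzymes Enzyme panel.
#' @return Invisibly, the [classification_matrix()].
#' @export
run_classify <- function(records, resources, output_dir, manual = NULL,
                         threshold = 0.03, enzymes = cyp_enzymes()) {
  if (is.character(records)) {
    records <- readr::read_csv(records, col_types = readr::cols(),
                               progress = FALSE)
  }
  resources <- lapply(seq_along(resources), function(i) {
    r <- resources[[i]]
    if (is.character(r)) {
      read_substrate_snapshot(r, enzymes = enzymes,
                              id = names(resources)[i] %||% NULL)
    } else r
  })
  files <- c("classification_matrix.csv", "classification_counts.json")
  with_output_dir(output_dir, files, function(paths) {
    slices <- lapply(resources, function(r) {
      classify_automatic(records, r)
    })
    if (!is.null(manual)) {
      if (is.character(manual)) {
        manual <- read_manual_assessments(manual, enzymes)
      }
      frequent <- select_frequent_drugs(records, threshold)
      manual_slice <- classify_manual(records$canonical_name, manual,
                                      enzymes = enzymes)
      # below-threshold drugs stay not_assessed for the manual method
      manual_slice$state[!manual_slice$drug %in%
                           frequent$canonical_name] <- "not_assessed"
      slices <- c(list(manual_slice), slices)
    }
    matrix <- classification_matrix(dplyr::bind_rows(slices))
    write_classification_matrix(matrix, paths[1])
    counts <- classification_counts(matrix)
    write_json_file(
      lapply(split(counts, counts$method), function(df) {
        lapply(split(df, df$enzyme), function(r) {
          list(n_assessed = r$n_assessed, n_substrate = r$n_substrate)
        })
      }),
      paths[2]
    )
    invisible(matrix)
  })
}

#' Run the agreement stage
#'
#' Compares a reference method (default `MANUAL`) against every other
#' method in the matrix, per enzyme: joint-assessment counts, substrate
#' marginals, Cohen's kappa with its band (the kappa column shows `"-"`
#' when undefined), plus a disagreement table weighted by entry
#' frequency and a Venn summary of assessed sets. Writes
#' `agreement.csv`, `disagreements.csv` and `venn.json`.
#'
#' @param matrix A [classification_matrix()] or path to its CSV.
#' @param output_dir Output directory.
#' @param records Optional drug-record tibble or CSV path (required for
#'   the disagreement table's entry counts).
#' @param reference_method Method id every other method is compared to.
#' @return Invisibly, a list with `agreement` (tibble), `disagreements`
#'   (tibble), `venn` (a [venn_summary()]).
#' @export
run_compare <- function(matrix, output_dir, records = NULL,
                        reference_method = "MANUAL") {
  if (is.character(matrix)) matrix <- read_classification_matrix(matrix)
  if (is.character(records)) {
    records <- readr::read_csv(records, col_types = readr::cols(),
                               progress = FALSE)
  }
  methods <- matrix_methods(matrix)
  if (length(methods) < 2L) {
    stop("comparison needs at least two methods", call. = FALSE)
  }
  if (!reference_method %in% methods) {
    stop("reference method not in matrix: ", reference_method,
         call. = FALSE)
  }
  others <- setdiff(methods, reference_method)
  files <- c("agreement.csv", "disagreements.csv", "venn.json")
  with_output_dir(output_dir, files, function(paths) {
    agreement_rows <- list()
    disagreement_rows <- list()
    for (m in others) {
      joint <- jointly_assessed(matrix, reference_method, m)
      for (enz in matrix_enzymes(matrix)) {
        if (length(joint) == 0L) {
          agreement_rows[[length(agreement_rows) + 1L]] <- tibble::tibble(
            method = m, enzyme = enz, n_joint = 0L,
            substrates_reference = NA_integer_,
            substrates_method = NA_integer_,
            kappa = "-", band = NA_character_)
          next
        }
        tab <- build_contingency(matrix, reference_method, m, enz)
        kr <- cohens_kappa(tab)
        agreement_rows[[length(agreement_rows) + 1L]] <- tibble::tibble(
          method = m, enzyme = enz, n_joint = tab$n,
          substrates_reference = tab$a + tab$b,
          substrates_method = tab$a + tab$c,
          kappa = if (kr$status == "undefined") "-"
                  else sprintf("%.2f", kr$kappa),
          band = kr$band)
        if (!is.null(records)) {
          dt <- disagreement_table(matrix, reference_method, m, enz,
                                   records)
          if (nrow(dt) > 0L) {
            names(dt)[names(dt) == reference_method] <- "state_reference"
            names(dt)[names(dt) == m] <- "state_method"
            dt$method <- m
            disagreement_rows[[length(disagreement_rows) + 1L]] <- dt
          }
        }
      }
    }
    agreement <- dplyr::bind_rows(agreement_rows)
    disagreements <- dplyr::bind_rows(disagreement_rows)
    venn <- venn_summary(matrix)
    readr::write_csv(agreement, paths[1])
    readr::write_csv(disagreements, paths[2])
    write_json_file(list(sizes = as.list(venn$sizes)), paths[3])
    invisible(list(agreement = agreement, disagreements = disagreements,
                   venn = venn))
  })
}

#' Generate and write a synthetic dataset bundle
#'
#' Writes `medication.csv`, the name-index TSVs (`atc_index.tsv`,
#' `name_list.tsv`), the override map (`overrides.tsv`), a snapshot
#' resource (`resource_synthdb.tsv`) and a ground-truth side file
#' (`ground_truth.json`) for a given seed.
#'
#' @param config A [fixture_config()] (or a seed, with defaults).
#' @param output_dir Output directory.
#' @return Invisibly, the generated dataset list.
#' @export
run_simulate <- function(config, output_dir) {
  if (is.numeric(config)) config <- fixture_config(seed = config)
  stopifnot(inherits(config, "fixture_config"))
  files <- c("medication.csv", "atc_index.tsv", "name_list.tsv",
             "overrides.tsv", "resource_synthdb.tsv", "ground_truth.json")
  with_output_dir(output_dir, files, function(paths) {
    ds <- generate_medication_dataset(config)
    snap <- generate_resource_snapshot(config, ds$truth)
    readr::write_csv(ds$table, paths[1])
    readr::write_tsv(tibble::tibble(
      atc = names(ds$truth$index$atc_to_name),
      name = unname(ds$truth$index$atc_to_name)), paths[2])
    readr::write_tsv(tibble::tibble(name = ds$truth$index$name_set),
                     paths[3])
    ov <- unclass(ds$truth$overrides)
    readr::write_tsv(tibble::tibble(raw = names(ov),
                                    canonical = unname(ov)), paths[4])
    write_substrate_snapshot(snap$resource, paths[5])
    write_json_file(list(
      n_cases = ds$truth$n_cases,
      n_entries = ds$truth$n_entries,
      frequent = as.list(ds$truth$frequent),
      recoverable_e = as.list(ds$truth$recoverable_e),
      unresolvable = as.list(ds$truth$unresolvable),
      resource_assessed = as.list(snap$truth$assessed)
    ), paths[6])
    invisible(ds)
  })
}
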