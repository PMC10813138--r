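# Seeded synthetic fixtures: medication tables with known ground truth,
# resource snapshots with planted coverage, and classification vectors
# with exact planted 2x2 agreement counts.
#
# The generator emulates the structure of an emergency-department ADR
# medication dataset: a few hundred cases each documenting several drugs,
# drug popularity following a Zipf-like law, occasional combination
# products joined with '/', and German-style spellings produced by
# dropping the trailing 'e' of the English INN (invertible by the
# 'e'-suffix rule) or by an unrelated alias (resolvable only by manual
# override). All randomness flows through one seed via withr::with_seed;
# no global RNG state is touched.

#' Configuration for the synthetic-dataset generator
#'
#' Defaults describe the emulated study conditions: 500 cases over a
#' 200-drug universe, Zipf exponent 1, a mean of about six entries per
#' case, 5% combination rows, a 20% chance that a trailing-'e' name is
#' documented in its German spelling, a 5% chance of an opaque alias, and
#' ATC codes present on 70% of single-substance rows. Combination rows
#' carry no ATC code (a combination product has no single substance-level
#' code).
#'
#' @param seed Mandatory integer seed; all generator randomness derives
#'   from it.
#' @param n_cases,n_drugs Number of cases and size of the drug universe.
#' @param zipf_exponent Exponent of the drug-frequency law
#'   (weight of rank r proportional to `1/r^zipf_exponent`).
#' @param mean_entries_per_case Mean number of drugs documented per case
#'   (at least one is always documented).
#' @param combo_rate Fraction of entry rows merged into a '/'-joined
#'   combination row with the preceding entry of the same case.
#' @param e_drop_rate Probability that a drug whose canonical name ends
#'   in 'e' is documented without it.
#' @param alias_rate Probability that a drug is documented under an
#'   opaque alias.
#' @param atc_rate Probability that a single-substance row carries the
#'   drug's ATC code.
#' @param resource_coverage Fraction of the drug universe a generated
#'   snapshot resource catalogs.
#' @param substrate_rate Per-enzyme probability that a cataloged drug is
#'   flagged substrate.
#' @param enzymes Enzyme panel for generated resources.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed, n_cases = 500L, n_drugs = 200L,
                           zipf_exponent = 1, mean_entries_per_case = 6,
                           combo_rate = 0.05, e_drop_rate = 0.2,
                           alias_rate = 0.05, atc_rate = 0.7,
                           resource_coverage = 0.8, substrate_rate = 0.15,
                           enzymes = cyp_enzymes()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  rates <- c(combo_rate = combo_rate, e_drop_rate = e_drop_rate,
             alias_rate = alias_rate, atc_rate = atc_rate,
             resource_coverage = resource_coverage,
             substrate_rate = substrate_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  if (n_drugs < 1L || n_cases < 1L) {
    stop("n_cases and n_drugs must be positive", call. = FALSE)
  }
  if (combo_rate > 0 && n_drugs < 2L) {
    stop("combo_rate > 0 requires at least two drugs", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_cases = as.integer(n_cases),
         n_drugs = as.integer(n_drugs), zipf_exponent = zipf_exponent,
         mean_entries_per_case = mean_entries_per_case,
         combo_rate = combo_rate, e_drop_rate = e_drop_rate,
         alias_rate = alias_rate, atc_rate = atc_rate,
         resource_coverage = resource_coverage,
         substrate_rate = substrate_rate, enzymes = enzymes),
    class = "fixture_config"
  )
}

# Pronounceable synthetic drug names; suffix pool mirrors common INN
# endings so about half the universe ends in 'e' (the spellings the
# 'e'-rule can recover).
make_drug_names <- function(n) {
  syl <- c("ba", "do", "fi", "lu", "mo", "na", "pi", "ra", "se", "ti",
           "vo", "ze", "ka", "mi", "tu", "ge")
  suf <- c("ine", "ide", "ole", "one", "ate", "ol", "in", "an", "il",
           "pril", "olol", "pine")
  names <- character(n)
  taken <- character(0)
  i <- 1L
  while (i <= n) {
    nm <- paste0(paste(sample(syl, sample(2:3, 1), replace = TRUE),
                       collapse = ""),
                 sample(suf, 1))
    if (!nm %in% taken) {
      names[i] <- nm
      taken <- c(taken, nm)
      i <- i + 1L
    }
  }
  names
}

# Systematic unique substance-level ATC codes.
make_atc_codes <- function(n) {
  stopifnot(n <= 2600L)
  i <- seq_len(n) - 1L
  paste0(LETTERS[1L + i %% 26L], sprintf("%02d", i %/% 26L),
         "AA", sprintf("%02d", 1L + i %% 99L))
}

#' Generate a synthetic medication dataset with ground truth
#'
#' Produces a medication-entry table shaped like a real ADR study export
#' (case id, raw name — possibly German-spelled or a '/'-joined
#' combination — and an optional ATC code) alongside the complete ground
#' truth: the drug universe with per-drug raw spellings, mutation types,
#' planted entry and case counts, the frequent-drug subset at the 3%
#' case threshold, the name index, and the override map for aliases.
#' Byte-identical output for a given config.
#'
#' @param config A [fixture_config()].
#' @return List with `table` (tibble: `case_id`, `name`, `atc`) and
#'   `truth` (list: `drugs` tibble, `index`, `overrides`, `n_cases`,
#'   `n_entries`, `frequent`, `recoverable_e`, `unresolvable`).
#' @export
generate_medication_dataset <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    n_drugs <- config$n_drugs
    canonical <- make_drug_names(n_drugs)
    atc <- make_atc_codes(n_drugs)

    # per-drug raw spelling (a property of the drug, applied consistently)
    raw <- canonical
    mutation <- rep("none", n_drugs)
    u <- runif(n_drugs)
    ends_e <- endsWith(canonical, "e")
    for (i in seq_len(n_drugs)) {
      if (ends_e[i] && u[i] < config$e_drop_rate) {
        cand <- substr(canonical[i], 1L, nchar(canonical[i]) - 1L)
        # invertible only if the truncated form collides with nothing
        if (!cand %in% canonical && !cand %in% raw[seq_len(i - 1L)]) {
          raw[i] <- cand
          mutation[i] <- "e_drop"
        }
      } else if (u[i] < config$e_drop_rate + config$alias_rate) {
        repeat {
          cand <- paste0("alias", sprintf("%03d", i),
                         sample(letters, 1))
          if (!cand %in% canonical && !paste0(cand, "e") %in% canonical &&
              !cand %in% raw[seq_len(i - 1L)]) break
        }
        raw[i] <- cand
        mutation[i] <- "alias"
      }
    }
    expected_method <- unname(c(none = "EXACT", e_drop = "E_SUFFIX",
                                alias = "OVERRIDE")[mutation])

    # Zipf-like popularity; drug 1 is the most frequent
    w <- (1 / seq_len(n_drugs)^config$zipf_exponent)
    w <- w / sum(w)

    rows <- vector("list", config$n_cases)
    for (cs in seq_len(config$n_cases)) {
      k <- min(1L + rpois(1L, max(config$mean_entries_per_case - 1, 0)),
               n_drugs)
      picked <- sample.int(n_drugs, k, replace = FALSE, prob = w)
      rows[[cs]] <- tibble::tibble(case_id = sprintf("case%04d", cs),
                                   drug_id = picked)
    }
    entries <- dplyr::bind_rows(rows)
    n_entries <- nrow(entries)

    truth_counts <- entries |>
      dplyr::group_by(drug_id = .data$drug_id) |>
      dplyr::summarise(entry_count = dplyr::n(),
                       case_count = dplyr::n_distinct(.data$case_id),
                       .groups = "drop")
    entry_count <- integer(n_drugs)
    case_count <- integer(n_drugs)
    entry_count[truth_counts$drug_id] <- truth_counts$entry_count
    case_count[truth_counts$drug_id] <- truth_counts$case_count

    # merge a fraction of rows into combination products within a case
    entries$merge_up <- runif(n_entries) < config$combo_rate &
      duplicated(entries$case_id)
    out_rows <- list()
    i <- 1L
    j <- 1L
    while (i <= n_entries) {
      ids <- entries$drug_id[i]
      cs <- entries$case_id[i]
      if (i < n_entries && entries$merge_up[i + 1L] &&
          entries$case_id[i + 1L] == cs) {
        ids <- c(ids, entries$drug_id[i + 1L])
        i <- i + 2L
      } else {
        i <- i + 1L
      }
      if (length(ids) == 1L) {
        has_atc <- runif(1) < config$atc_rate
        out_rows[[j]] <- tibble::tibble(
          case_id = cs, name = raw[ids],
          atc = if (has_atc) atc[ids] else NA_character_)
      } else {
        out_rows[[j]] <- tibble::tibble(
          case_id = cs, name = paste(raw[ids], collapse = "/"),
          atc = NA_character_)
      }
      j <- j + 1L
    }
    table <- dplyr::bind_rows(out_rows)

    drugs <- tibble::tibble(
      canonical_name = canonical, raw_name = raw, atc = atc,
      rank = seq_len(n_drugs), mutation = mutation,
      expected_method = expected_method,
      entry_count = entry_count, case_count = case_count,
      case_fraction = case_count / config$n_cases
    )
    aliases <- drugs$mutation == "alias"
    truth <- list(
      drugs = drugs,
      index = name_index(
        atc_to_name = stats::setNames(canonical, atc),
        names = canonical),
      overrides = override_map(
        stats::setNames(drugs$canonical_name[aliases],
                        drugs$raw_name[aliases]),
        allow_new = TRUE),
      n_cases = config$n_cases,
      n_entries = n_entries,
      frequent = drugs$canonical_name[drugs$case_fraction >= 0.03 &
                                        drugs$entry_count > 0],
      recoverable_e = drugs$raw_name[drugs$mutation == "e_drop"],
      unresolvable = drugs$raw_name[aliases]
    )
    list(table = table, truth = truth)
  })
}

#' Generate a substrate-resource snapshot with planted coverage
#'
#' Samples a fraction of the drug universe into a resource catalog and
#' flags each cataloged drug substrate per enzyme with the configured
#' rate; the returned truth records the planted assessed set and
#' per-enzyme substrate counts, which a classification run must recover
#' exactly.
#'
#' @param config A [fixture_config()].
#' @param truth Ground truth from [generate_medication_dataset()].
#' @param id Resource id.
#' @param policy Coverage policy of the generated resource.
#' @return List with `resource` (a [substrate_resource()]) and `truth`
#'   (list: `assessed`, per-enzyme `substrates`).
#' @export
generate_resource_snapshot <- function(config, truth, id = "SYNTHDB",
                                       policy = "CATALOG") {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed + 1L, {
    universe <- truth$drugs$canonical_name
    n_cov <- round(config$resource_coverage * length(universe))
    covered <- sort(sample(universe, n_cov))
    entries <- lapply(covered, function(nm) {
      config$enzymes[runif(length(config$enzymes)) < config$substrate_rate]
    })
    names(entries) <- covered
    resource <- substrate_resource(id = id, policy = policy,
                                   entries = entries,
                                   catalog_names = covered,
                                   enzymes = config$enzymes,
                                   version = "synthetic")
    substrates <- lapply(stats::setNames(config$enzymes, config$enzymes),
                         function(e) {
                           covered[vapply(covered, function(nm) {
                             e %in% entries[[nm]]
                           }, logical(1))]
                         })
    list(resource = resource,
         truth = list(assessed = covered, substrates = substrates))
  })
}

#' Plant a classification matrix with an exact 2x2 agreement table
#'
#' Builds two tri-state classification vectors over `a + b + c + d`
#' synthetic drugs whose [build_contingency()] equals exactly
#' `(a, b, c, d)`. Used to verify the agreement pipeline end to end
#' against known kappa values.
#'
#' @inheritParams contingency_2x2
#' @param method_a,method_b Method ids for the two raters.
#' @param enzyme Enzyme the planted slice is recorded under.
#' @param enzymes Enzyme panel of the matrix (other enzymes get
#'   non-substrate calls so per-drug assessment stays uniform).
#' @param seed Optional seed; when given, the drug order is shuffled
#'   reproducibly (the contingency table is order-invariant).
#' @return A [classification_matrix()] with the two methods.
#' @export
plant_agreement <- function(a, b, c, d, method_a = "MANUAL",
                            method_b = "DRUGBANK", enzyme = "CYP2D6",
                            enzymes = cyp_enzymes(), seed = NULL) {
  tab <- contingency_2x2(a, b, c, d)   # validates cells
  n <- tab$n
  drugs <- sprintf("synthdrug%04d", seq_len(n))
  sa <- rep(c(TRUE, TRUE, FALSE, FALSE), times = c(a, b, c, d))
  sb <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d))
  if (!is.null(seed)) {
    perm <- withr::with_seed(seed, sample.int(n))
    sa <- sa[perm]
    sb <- sb[perm]
  }
  state <- function(flag) ifelse(flag, "substrate", "non_substrate")
  slices <- list(
    tibble::tibble(drug = drugs, method = method_a, enzyme = enzyme,
                   state = state(sa)),
    tibble::tibble(drug = drugs, method = method_b, enzyme = enzyme,
                   state = state(sb))
  )
  for (other in setdiff(enzymes, enzyme)) {
    slices[[length(slices) + 1L]] <-
      tibble::tibble(drug = rep(drugs, 2L),
                     method = rep(c(method_a, method_b), each = n),
                     enzyme = other,
                     state = "non_substrate")
  }
  classification_matrix(dplyr::bind_rows(slices))
}
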