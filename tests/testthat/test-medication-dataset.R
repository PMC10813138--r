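test_that("reading a medication table preserves rows and reports empty names", {
  reading <- read_medication_table(extdata("medication_mini.csv"))
  expect_equal(nrow(reading$entries), 3L)
  expect_equal(reading$entries$case_id, c("case001", "case001", "case002"))
  expect_equal(reading$entries$source_row, 1:3)
  expect_equal(nrow(reading$rejected), 0L)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,name,atc",
               "c1,Ramipril,C09AA05",
               "c2,,",
               "c3,  ,"), tmp)
  reading <- read_medication_table(tmp)
  expect_equal(nrow(reading$entries), 1L)
  expect_equal(reading$rejected$source_row, c(2L, 3L))
  expect_match(reading$rejected$reason, "empty")
})

test_that("reading fails cleanly on missing files and columns", {
  expect_error(read_medication_table("no/such/file.csv"), "not found")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient,drug", "c1,ramipril"), tmp)
  expect_error(read_medication_table(tmp), "case_id")
})

test_that("combination products split into parts inheriting the case id", {
  entries <- tibble::tibble(
    case_id = c("c1", "c1", "c2"),
    raw_name = c("hydrochlorothiazide/ramipril", "metamizole", "a/b/c"),
    atc_code = c(NA, NA, "C09BA05"),
    source_row = 1:3
  )
  out <- split_combinations(entries)
  expect_equal(nrow(out), 6L)
  expect_equal(out$raw_name[1:2], c("hydrochlorothiazide", "ramipril"))
  expect_equal(out$case_id[1:2], c("c1", "c1"))
  expect_equal(out$raw_name[3], "metamizole")
  expect_false(out$ambiguous_atc[3])
  # combination-level ATC attached to every part and flagged ambiguous
  expect_equal(out$raw_name[4:6], c("a", "b", "c"))
  expect_true(all(out$ambiguous_atc[4:6]))
  expect_equal(out$atc_code[4:6], rep("C09BA05", 3))

  bad <- tibble::tibble(case_id = "c1", raw_name = "/",
                        atc_code = NA_character_, source_row = 1L)
  expect_error(split_combinations(bad), "separator-only")
})

test_that("aggregation computes entry and case counts with conservation", {
  entries <- tibble::tibble(
    case_id = c("c1", "c1", "c2", "c3", "c3", "c2", "c9"),
    raw_name = c("x", "x", "x", "x", "x", "y-spelled", "zzz"),
    atc_code = NA_character_,
    source_row = 1:7
  )
  resolutions <- tibble::tibble(
    raw_name = c("x", "y-spelled", "zzz"),
    canonical_name = c("drug x", "drug y", NA),
    method = c("EXACT", "OVERRIDE", "UNRESOLVED")
  )
  agg <- aggregate_drugs(entries, resolutions)
  # 5 entries of drug x across 3 cases
  x <- agg$records[agg$records$canonical_name == "drug x", ]
  expect_equal(x$entry_count, 5L)
  expect_equal(x$case_count, 3L)
  expect_equal(x$case_fraction, 3 / 4)
  # conservation: counted + unresolved = input entries
  expect_equal(agg$summary$n_entries_counted +
                 agg$summary$n_entries_unresolved, nrow(entries))
  expect_equal(agg$summary$n_entries_unresolved, 1L)
})

test_that("two raw spellings resolving to one canonical name merge", {
  entries <- tibble::tibble(
    case_id = c("c1", "c2"),
    raw_name = c("hydrochlorothiazid", "hydrochlorothiazide"),
    atc_code = NA_character_, source_row = 1:2
  )
  resolutions <- tibble::tibble(
    raw_name = c("hydrochlorothiazid", "hydrochlorothiazide"),
    canonical_name = "hydrochlorothiazide",
    method = c("E_SUFFIX", "EXACT")
  )
  agg <- aggregate_drugs(entries, resolutions)
  expect_equal(nrow(agg$records), 1L)
  expect_equal(agg$records$entry_count, 2L)
  expect_equal(agg$records$case_count, 2L)
})

test_that("frequency threshold is a closed bound on the case fraction", {
  # 2939 cases at 3%: 89 cases qualifies (89/2939 > 0.03), 88 does not
  records <- tibble::tibble(
    canonical_name = c("in", "out"),
    entry_count = c(100L, 100L),
    case_count = c(89L, 88L),
    case_fraction = c(89, 88) / 2939
  )
  sel <- select_frequent_drugs(records, 0.03)
  expect_equal(sel$canonical_name, "in")
  expect_equal(select_frequent_drugs(records, 0)$canonical_name,
               records$canonical_name[order(-records$entry_count,
                                            records$canonical_name)])
  expect_error(select_frequent_drugs(records, 1.5), "0, 1")
  expect_error(
    select_frequent_drugs(dplyr::select(records, -"case_fraction"), 0.03),
    "case count"
  )
})

test_that("frequent-drug selection is monotone in the threshold", {
  cfg <- fixture_config(seed = 42, n_cases = 60, n_drugs = 40)
  ds <- generate_medication_dataset(cfg)
  records <- dplyr::rename(ds$truth$drugs, name = "canonical_name")
  records <- tibble::tibble(canonical_name = records$name,
                            entry_count = records$entry_count,
                            case_count = records$case_count,
                            case_fraction = records$case_fraction)
  thresholds <- c(0, 0.01, 0.03, 0.1, 0.5, 1)
  sets <- lapply(thresholds,
                 function(t) select_frequent_drugs(records, t)$canonical_name)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("exclusion rules remove listed names and supplement ATC groups", {
  entries <- tibble::tibble(
    case_id = c("c1", "c1", "c2"),
    raw_name = c("Multivitamin", "ramipril", "ascorbic acid"),
    atc_code = c(NA, "C09AA05", "A11GA01"),
    source_row = 1:3
  )
  out <- apply_exclusions(entries, default_exclusion_rules())
  expect_equal(out$kept$raw_name, "ramipril")
  expect_setequal(out$excluded$rule,
                  c("excluded name", "excluded ATC prefix"))
})
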