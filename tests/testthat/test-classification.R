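test_that("automatic classification counts assessed and substrate drugs", {
  cat <- substrate_resource(
    "DB", "CATALOG",
    entries = stats::setNames(
      c(rep(list("CYP2D6"), 2), rep(list(character()), 6)),
      paste0("drug", 1:8)),
    catalog_names = paste0("drug", 1:8)
  )
  drugs <- paste0("drug", 1:10)   # 8 cataloged, 2 not
  slice <- classify_automatic(drugs, cat)
  expect_equal(nrow(slice), 10L * length(cyp_enzymes()))
  counts <- classification_counts(classification_matrix(slice))
  expect_true(all(counts$n_assessed == 8L))
  expect_equal(counts$n_substrate[counts$enzyme == "CYP2D6"], 2L)
  expect_equal(counts$n_substrate[counts$enzyme == "CYP2C9"], 0L)

  expect_equal(nrow(classify_automatic(character(), cat)), 0L)
  expect_warning(classify_automatic(c("drug1", NA), cat), "unresolved")
})

test_that("per-method totals respect substrate <= assessed <= drugs", {
  cfg <- fixture_config(seed = 3, n_cases = 20, n_drugs = 60)
  ds <- generate_medication_dataset(cfg)
  snap <- generate_resource_snapshot(cfg, ds$truth)
  slice <- classify_automatic(ds$truth$drugs$canonical_name,
                              snap$resource)
  counts <- classification_counts(classification_matrix(slice))
  expect_true(all(counts$n_substrate <= counts$n_assessed))
  expect_true(all(counts$n_assessed <= cfg$n_drugs))
  # planted coverage and substrate sets recovered exactly
  expect_true(all(counts$n_assessed == length(snap$truth$assessed)))
  for (enz in cyp_enzymes()) {
    expect_equal(counts$n_substrate[counts$enzyme == enz],
                 length(snap$truth$substrates[[enz]]))
  }
})

test_that("classification is idempotent and order-independent", {
  flock <- read_substrate_snapshot(extdata("flockhart_snapshot.tsv"))
  drugs <- c("losartan", "metoprolol", "absent-drug", "apixaban")
  s1 <- classify_automatic(drugs, flock)
  s2 <- classify_automatic(rev(drugs), flock)
  key <- function(s) s[order(s$drug, s$enzyme), ]
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)
  expect_equal(key(s1), key(classify_automatic(drugs, flock)),
               ignore_attr = TRUE)
})

test_that("manual tables load with validation errors naming the problem", {
  manual <- read_manual_assessments(extdata("manual_assessments.tsv"))
  expect_equal(nrow(manual), 10L)
  expect_type(manual$CYP2D6, "logical")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tCYP2D6\tCYP2C9\tCYP2C19",
               "ramipril\t0\t0\t0",
               "ramipril\t1\t0\t0"), tmp)
  expect_error(read_manual_assessments(tmp), "duplicate.*ramipril")

  writeLines(c("name\tCYP2D6\tCYP2C9",
               "ramipril\t0\t0"), tmp)
  expect_error(read_manual_assessments(tmp), "CYP2C19")
})

test_that("manual classification marks out-of-table drugs not assessed", {
  manual <- read_manual_assessments(extdata("manual_assessments.tsv"))
  slice <- classify_manual(c("tilidine", "never-reviewed"), manual)
  states <- stats::setNames(slice$state, paste(slice$drug, slice$enzyme))
  expect_equal(states[["tilidine CYP2C19"]], "substrate")
  expect_equal(states[["tilidine CYP2D6"]], "non_substrate")
  expect_equal(states[["never-reviewed CYP2C19"]], "not_assessed")
})

test_that("unique classifications find single-method substrate calls", {
  dis <- reference_disagreements()
  m <- matrix_from_codes(dis[dis$enzyme == "CYP2C19", ],
                         c("manual", "drugbank", "fda", "flockhart"))
  uniq <- unique_classifications(m, "CYP2C19")
  # tilidine: substrate under the manual method only
  expect_true(any(uniq$drug == "tilidine" & uniq$method == "manual"))
  # every listed automatic-only drug is attributed to drugbank
  expect_setequal(uniq$method[uniq$drug != "tilidine"], "drugbank")

  # all methods agreeing means no unique rows
  agree <- classification_matrix(tibble::tibble(
    drug = rep("d", 2), method = c("A", "B"),
    enzyme = "CYP2D6", state = "substrate"))
  expect_equal(nrow(unique_classifications(agree, "CYP2D6")), 0L)

  one <- classification_matrix(tibble::tibble(
    drug = "d", method = "A", enzyme = "CYP2D6", state = "substrate"))
  expect_error(unique_classifications(one, "CYP2D6"), "two methods")
})

test_that("a planted set of resource-only substrates is reported in full", {
  n_only <- 13L
  drugs <- sprintf("only%02d", seq_len(n_only))
  m <- classification_matrix(dplyr::bind_rows(
    tibble::tibble(drug = drugs, method = "DRUGBANK",
                   enzyme = "CYP2C9", state = "substrate"),
    tibble::tibble(drug = drugs, method = "MANUAL",
                   enzyme = "CYP2C9",
                   state = rep(c("non_substrate", "not_assessed"),
                               length.out = n_only))
  ))
  uniq <- unique_classifications(m, "CYP2C9")
  expect_equal(nrow(uniq), n_only)
  expect_true(all(uniq$method == "DRUGBANK"))
})

test_that("the matrix constructor rejects duplicates and bad states", {
  expect_error(classification_matrix(tibble::tibble(
    drug = c("d", "d"), method = "A", enzyme = "CYP2D6",
    state = "substrate")), "duplicate")
  expect_error(classification_matrix(tibble::tibble(
    drug = "d", method = "A", enzyme = "CYP2D6", state = "maybe")),
    "invalid")
})
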