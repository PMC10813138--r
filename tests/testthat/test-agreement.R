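test_that("jointly assessed drugs are the intersection of assessed sets", {
  m <- plant_agreement(2, 1, 1, 3)
  expect_equal(length(jointly_assessed(m, "MANUAL", "DRUGBANK")), 7L)
  expect_equal(jointly_assessed(m, "MANUAL", "MANUAL"),
               jointly_assessed(m, "MANUAL", "DRUGBANK"))
  expect_error(jointly_assessed(m, "MANUAL", "NOPE"), "unknown method")

  disjoint <- classification_matrix(tibble::tibble(
    drug = c("d1", "d1", "d2", "d2"),
    method = c("A", "B", "A", "B"),
    enzyme = "CYP2D6",
    state = c("substrate", "not_assessed", "not_assessed", "substrate")))
  expect_equal(length(jointly_assessed(disjoint, "A", "B")), 0L)
  expect_error(build_contingency(disjoint, "A", "B", "CYP2D6"),
               "jointly assessed")
})

test_that("contingency counts equal a brute-force tally on random plants", {
  for (seed in 1:20) {
    cells <- withr::with_seed(seed, sample(0:12, 4, replace = TRUE))
    if (sum(cells) == 0) cells[1] <- 1
    m <- plant_agreement(cells[1], cells[2], cells[3], cells[4],
                         seed = seed)
    tab <- build_contingency(m, "MANUAL", "DRUGBANK", "CYP2D6")
    # brute force: tally the two state vectors drug by drug
    wide <- tidyr::pivot_wider(
      m[m$enzyme == "CYP2D6", ],
      names_from = "method", values_from = "state")
    brute <- table(factor(wide$MANUAL, tri_states()),
                   factor(wide$DRUGBANK, tri_states()))
    expect_equal(c(tab$a, tab$b, tab$c, tab$d),
                 c(brute["substrate", "substrate"],
                   brute["substrate", "non_substrate"],
                   brute["non_substrate", "substrate"],
                   brute["non_substrate", "non_substrate"]),
                 ignore_attr = TRUE)
  }
})

test_that("kappa handles perfect, chance-level and undefined agreement", {
  expect_equal(cohens_kappa(contingency_2x2(5, 0, 0, 5))$kappa, 1)
  expect_equal(cohens_kappa(contingency_2x2(1, 1, 1, 1))$kappa, 0)
  und <- cohens_kappa(contingency_2x2(0, 0, 0, 12))
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$kappa))
  expect_true(is.na(und$band))
  expect_error(contingency_2x2(-1, 0, 0, 2), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "n >= 1")
})

test_that("kappa is symmetric under rater swap and label swap", {
  for (seed in 1:30) {
    cells <- withr::with_seed(seed, sample(0:9, 4, replace = TRUE))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b + c + d == 0) a <- 1
    k0 <- cohens_kappa(contingency_2x2(a, b, c, d))$kappa
    k_swap <- cohens_kappa(contingency_2x2(a, c, b, d))$kappa
    k_label <- cohens_kappa(contingency_2x2(d, c, b, a))$kappa
    expect_equal(k0, k_swap)
    expect_equal(k0, k_label)
    k <- cohens_kappa(contingency_2x2(a, b, c, d))
    if (k$status == "ok") {
      # kappa never exceeds observed agreement; 1 only without disagreement
      expect_lte(k$kappa, k$p_o + 1e-12)
      expect_equal(k$kappa == 1, b == 0 && c == 0)
    }
  }
})

test_that("banding reproduces the conventional labels on rounded kappa", {
  expect_equal(kappa_band(c(0.84, 0.71, 0.48, 0.43, 0.20)),
               c("almost perfect", "substantial", "moderate", "moderate",
                 "fair"))
  # half-open edges on the rounded value
  expect_equal(kappa_band(c(-0.01, 0, 0.19, 0.20, 0.40, 0.41, 0.60,
                            0.61, 0.80, 0.81, 1)),
               c("poor", "slight", "slight", "fair", "fair", "moderate",
                 "moderate", "substantial", "substantial",
                 "almost perfect", "almost perfect"))
  expect_error(kappa_band(1.2), "out of")
  expect_equal(kappa_band(NA_real_), NA_character_)
})

test_that("reconstruction from marginals inverts the contingency table", {
  for (seed in 1:50) {
    cells <- withr::with_seed(seed, sample(0:15, 4, replace = TRUE))
    if (sum(cells) == 0) cells[4] <- 5
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    back <- reconstruct_contingency(tab$n, tab$a + tab$b, tab$a + tab$c,
                                    tab$b)
    expect_equal(c(back$a, back$b, back$c, back$d),
                 c(tab$a, tab$b, tab$c, tab$d))
  }
  expect_error(reconstruct_contingency(10, 2, 8, 3), "non-negative")
})

test_that("venn summary reproduces planted assessed-set sizes", {
  # coverage structure shaped like the published method comparison:
  # manual 109, catalog resource 796, two curated lists 109 and 167,
  # manual overlaps 100 / 12 / 26
  universe <- sprintf("d%03d", 1:895)
  manual <- universe[1:109]
  drugbank <- universe[c(1:100, 110:805)]
  fda <- universe[c(1:12, 806:902 - 7)]   # 12 overlapping manual
  fda <- unique(fda)[1:109]
  flockhart <- universe[c(1:26, 700:840)]
  sets <- list(MANUAL = manual, DRUGBANK = drugbank, FDA = fda,
               FLOCKHART = flockhart)
  slices <- lapply(names(sets), function(m) {
    tibble::tibble(drug = sets[[m]], method = m, enzyme = "CYP2D6",
                   state = "non_substrate")
  })
  m <- classification_matrix(dplyr::bind_rows(slices))
  vs <- venn_summary(m)
  expect_equal(unname(vs$sizes[c("MANUAL", "DRUGBANK", "FDA",
                                 "FLOCKHART")]),
               c(109L, 796L, 109L, 167L))
  expect_equal(unname(vs$sizes["MANUAL&DRUGBANK"]), 100L)
  expect_equal(unname(vs$sizes["MANUAL&FDA"]), 12L)
  expect_equal(unname(vs$sizes["MANUAL&FLOCKHART"]), 26L)
  # brute-force oracle over every intersection
  for (nm in names(vs$sizes)) {
    members <- strsplit(nm, "&", fixed = TRUE)[[1]]
    expect_equal(unname(vs$sizes[nm]),
                 length(Reduce(intersect, sets[members])))
  }
  single <- venn_summary(classification_matrix(slices[[1]]))
  expect_equal(names(single$sizes), "MANUAL")
})

test_that("venn intersection sizes satisfy inclusion-exclusion", {
  cfg <- fixture_config(seed = 5, n_cases = 10, n_drugs = 40)
  ds <- generate_medication_dataset(cfg)
  m <- classification_matrix(dplyr::bind_rows(
    classify_automatic(ds$truth$drugs$canonical_name,
                       generate_resource_snapshot(cfg, ds$truth,
                                                  id = "R1")$resource),
    classify_automatic(ds$truth$drugs$canonical_name,
                       generate_resource_snapshot(
                         fixture_config(seed = 6, n_cases = 10,
                                        n_drugs = 40),
                         ds$truth, id = "R2")$resource)
  ))
  vs <- venn_summary(m)
  union_size <- length(unique(c(vs$sets$R1, vs$sets$R2)))
  expect_equal(union_size,
               unname(vs$sizes["R1"] + vs$sizes["R2"] -
                        vs$sizes["R1&R2"]))
})

test_that("disagreement tables rank discordant drugs by entry frequency", {
  dis <- reference_disagreements()
  codes <- dis[dis$enzyme == "CYP2C9", ]
  m <- matrix_from_codes(codes, c("manual", "drugbank"))
  records <- tibble::tibble(canonical_name = codes$drug,
                            entry_count = codes$entries)
  out <- disagreement_table(m, "manual", "drugbank", "CYP2C9", records,
                            total_entries = 23878L)
  # most frequent discordant drug first, with its printed share
  expect_equal(out$drug[1], "acetylsalicylic acid")
  expect_equal(out$entry_count[1], 952L)
  expect_equal(out$entry_percent[1], 4.0)
  # apixaban is substrate under both methods: not a disagreement
  expect_false("apixaban" %in% out$drug)
  # brute-force filter + sort oracle
  sa <- stats::setNames(codes$manual, codes$drug)
  sb <- stats::setNames(codes$drugbank, codes$drug)
  brute <- names(sa)[sa != sb & sa != "NA" & sb != "NA"]
  expect_setequal(out$drug, brute)
  expect_true(all(diff(out$entry_count) <= 0))

  # identical classifications: empty table
  same <- classification_matrix(tibble::tibble(
    drug = rep("d", 2), method = c("A", "B"), enzyme = "CYP2D6",
    state = "substrate"))
  expect_equal(nrow(disagreement_table(
    same, "A", "B", "CYP2D6",
    tibble::tibble(canonical_name = "d", entry_count = 1L))), 0L)

  # a discordant drug without an entry count is an error
  expect_error(disagreement_table(m, "manual", "drugbank", "CYP2C9",
                                  records[-1, ]), "entry count")
})
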