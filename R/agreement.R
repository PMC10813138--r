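# Agreement statistics: joint-assessment sets, 2x2 contingency tables,
# Cohen's kappa with qualitative bands, Venn summaries, and disagreement
# tables weighted by entry frequency.

#' Drugs jointly assessed by two methods
#'
#' The universe over which agreement is computed: drugs whose state is
#' anything other than `"not_assessed"` under both methods. Since
#' automatic resources assess per drug (all enzymes or none), the set is
#' computed per drug.
#'
#' @param matrix A [classification_matrix()].
#' @param method_a,method_b Method identifiers present in the matrix.
#' @return Sorted character vector of drug names.
#' @export
jointly_assessed <- function(matrix, method_a, method_b) {
  for (m in c(method_a, method_b)) {
    if (!m %in% matrix_methods(matrix)) {
      stop("unknown method id: ", m, call. = FALSE)
    }
  }
  assessed_set <- function(m) {
    sl <- matrix[matrix$method == m & matrix$state != "not_assessed", ]
    unique(sl$drug)
  }
  sort(intersect(assessed_set(method_a), assessed_set(method_b)))
}

#' Construct a 2x2 agreement contingency table
#'
#' @param a Both methods call substrate.
#' @param b Method A only.
#' @param c Method B only.
#' @param d Neither calls substrate.
#' @param method_a,method_b,enzyme Optional labels.
#' @return Object of class `contingency_2x2` with fields `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
contingency_2x2 <- function(a, b, c, d, method_a = "A", method_b = "B",
                            enzyme = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("contingency table must have n >= 1", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(n),
                 method_a = method_a, method_b = method_b,
                 enzyme = enzyme),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2> ", x$method_a, " vs ", x$method_b,
      if (!is.na(x$enzyme)) paste0(" (", x$enzyme, ")"),
      ": a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d, " n=", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Build the 2x2 table from a classification matrix
#'
#' Counts substrate/non-substrate calls for one enzyme over the jointly
#' assessed drug set only; `"not_assessed"` drugs never enter a cell.
#'
#' @inheritParams jointly_assessed
#' @param enzyme Enzyme identifier.
#' @return A [contingency_2x2()].
#' @export
build_contingency <- function(matrix, method_a, method_b, enzyme) {
  assert_enzyme(enzyme, matrix_enzymes(matrix))
  joint <- jointly_assessed(matrix, method_a, method_b)
  if (length(joint) == 0L) {
    stop("no drugs jointly assessed by ", method_a, " and ", method_b,
         call. = FALSE)
  }
  state_of <- function(m) {
    sl <- matrix[matrix$method == m & matrix$enzyme == enzyme, ]
    stats::setNames(sl$state, sl$drug)[joint]
  }
  sa <- state_of(method_a) == "substrate"
  sb <- state_of(method_b) == "substrate"
  contingency_2x2(
    a = sum(sa & sb), b = sum(sa & !sb),
    c = sum(!sa & sb), d = sum(!sa & !sb),
    method_a = method_a, method_b = method_b, enzyme = enzyme
  )
}

#' Reconstruct a 2x2 table from published marginals
#'
#' Published method comparisons often print only the per-method substrate
#' marginals over the jointly assessed set, plus a listing of the drugs
#' the two methods classified differently. Those determine the full
#' table: with `a_only` the number of drugs called substrate by method A
#' only, `a = marginal_a - a_only`, `c = marginal_b - a`, and
#' `d = n - a - b - c`.
#'
#' @param n Jointly assessed drug count.
#' @param marginal_a,marginal_b Substrate counts of the two methods over
#'   the joint set.
#' @param a_only Number of drugs substrate under method A but
#'   non-substrate under method B.
#' @inheritParams contingency_2x2
#' @return A [contingency_2x2()].
#' @export
#' @examples
#' # 100 jointly assessed drugs, marginals 9 and 12, no A-only calls:
#' cohens_kappa(reconstruct_contingency(100, 9, 12, 0))
reconstruct_contingency <- function(n, marginal_a, marginal_b, a_only,
                                    method_a = "A", method_b = "B",
                                    enzyme = NA_character_) {
  a <- marginal_a - a_only
  c <- marginal_b - a
  d <- n - a - a_only - c
  contingency_2x2(a, a_only, c, d, method_a = method_a,
                  method_b = method_b, enzyme = enzyme)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary raters:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)}
#' with observed agreement \eqn{p_o = (a+d)/n} and expected agreement
#' \eqn{p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2}. The ratio is evaluated in
#' integer arithmetic (\eqn{\kappa = (n(a+d) - S)/(n^2 - S)} with
#' \eqn{S = (a+b)(a+c) + (c+d)(b+d)}), so no rounding occurs before
#' presentation. When \eqn{p_e = 1} — e.g. both methods assess every drug
#' identically trivially, such as zero substrates on both sides — kappa is
#' undefined; this is reported as a status, not an error, mirroring the
#' "-" cell such comparisons get in published tables.
#'
#' @param table A [contingency_2x2()].
#' @return Object of class `kappa_result` with fields `kappa` (NA when
#'   undefined), `p_o`, `p_e`, `band` (label for kappa rounded to two
#'   decimals), `n`, `status` (`"ok"` or `"undefined"`), and `table`.
#' @export
#' @examples
#' cohens_kappa(contingency_2x2(9, 0, 3, 88))   # 0.84, almost perfect
#' cohens_kappa(contingency_2x2(0, 0, 0, 12))   # undefined
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- table$n
  s <- (a + b) * (a + c) + (c + d) * (b + d)
  p_o <- (a + d) / n
  p_e <- s / n^2
  if (n^2 == s) {
    kappa <- NA_real_
    status <- "undefined"
    band <- NA_character_
  } else {
    kappa <- (n * (a + d) - s) / (n^2 - s)
    status <- "ok"
    band <- kappa_band(round(kappa, 2))
  }
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, band = band,
                 n = n, status = status, table = table),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$status == "undefined") {
    cat("Cohen's kappa: undefined (expected agreement = 1), n = ",
        x$n, "\n", sep = "")
  } else {
    cat(sprintf("Cohen's kappa = %.2f (%s), p_o = %.3f, p_e = %.3f, n = %d\n",
                x$kappa, x$band, x$p_o, x$p_e, x$n))
  }
  invisible(x)
}

#' Qualitative agreement band for a rounded kappa
#'
#' Labels a kappa value (rounded to two decimals) on half-open bands:
#' below 0 "poor", \[0, 0.20) "slight", \[0.20, 0.41) "fair",
#' \[0.41, 0.61) "moderate", \[0.61, 0.81) "substantial", and
#' \[0.81, 1.00\] "almost perfect". Note the fair band is closed at 0.20;
#' the classical convention puts 0.20 in "slight", but published
#' comparisons commonly label a rounded 0.20 "fair" and this package
#' follows that usage (see the methods vignette).
#'
#' @param kappa Numeric vector of kappa values rounded to 2 decimals, in
#'   `[-1, 1]`; `NA` passes through.
#' @return Character vector of band labels.
#' @export
#' @examples
#' kappa_band(c(0.84, 0.71, 0.48, 0.20))
kappa_band <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 - 1e-9 | kappa > 1 + 1e-9))) {
    stop("kappa out of [-1, 1]", call. = FALSE)
  }
  # compare on integer hundredths to keep the band edges exact
  k100 <- round(kappa * 100)
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    k100 < 0 ~ "poor",
    k100 < 20 ~ "slight",
    k100 < 41 ~ "fair",
    k100 < 61 ~ "moderate",
    k100 < 81 ~ "substantial",
    .default = "almost perfect"
  )
}

#' Assessed-set sizes and intersections across methods
#'
#' Computes each method's assessed drug set and the size of every
#' intersection of two or more methods — the numbers behind a Venn
#' diagram of method coverage.
#'
#' @param matrix A [classification_matrix()].
#' @return Object of class `venn_summary`: list with `sets` (named list
#'   of drug vectors) and `sizes` (named integer vector; intersection
#'   names join method ids with `"&"`).
#' @export
venn_summary <- function(matrix) {
  methods <- matrix_methods(matrix)
  sets <- lapply(methods, function(m) {
    sort(unique(matrix$drug[matrix$method == m &
                              matrix$state != "not_assessed"]))
  })
  names(sets) <- methods
  sizes <- integer()
  if (length(methods) >= 1L) {
    for (k in seq_along(methods)) {
      combos <- utils::combn(methods, k, simplify = FALSE)
      for (cmb in combos) {
        sizes[paste(cmb, collapse = "&")] <-
          length(Reduce(intersect, sets[cmb]))
      }
    }
  }
  structure(list(sets = sets, sizes = sizes), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("<venn_summary> assessed-set sizes:\n")
  for (nm in names(x$sizes)) {
    cat("  ", nm, ": ", x$sizes[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Classification disagreements weighted by entry frequency
#'
#' Lists drugs that both methods assessed but classified differently for
#' one enzyme, together with how often the drug appears in the dataset —
#' a disagreement on a drug documented in 4% of entries matters more in
#' practice than one on a drug seen ten times.
#'
#' @inheritParams build_contingency
#' @param records Drug-record tibble with `canonical_name` and
#'   `entry_count`.
#' @param total_entries Denominator for `entry_percent`; defaults to
#'   `sum(records$entry_count)`.
#' @return Tibble with `enzyme`, `drug`, one state column per method
#'   (named by the method id), `entry_count`, `entry_percent` (1 decimal),
#'   sorted by descending `entry_count`.
#' @export
disagreement_table <- function(matrix, method_a, method_b, enzyme,
                               records, total_entries = NULL) {
  assert_enzyme(enzyme, matrix_enzymes(matrix))
  total_entries <- total_entries %||% sum(records$entry_count)
  joint <- jointly_assessed(matrix, method_a, method_b)
  state_of <- function(m) {
    sl <- matrix[matrix$method == m & matrix$enzyme == enzyme, ]
    stats::setNames(sl$state, sl$drug)[joint]
  }
  sa <- state_of(method_a)
  sb <- state_of(method_b)
  differ <- sa != sb & sa != "not_assessed" & sb != "not_assessed"
  drugs <- joint[differ]
  idx <- match(drugs, records$canonical_name)
  if (anyNA(idx)) {
    stop("no entry count for drug(s): ",
         paste(drugs[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    enzyme = rep(enzyme, length(drugs)),
    drug = drugs,
    !!method_a := unname(sa[differ]),
    !!method_b := unname(sb[differ]),
    entry_count = records$entry_count[idx],
    entry_percent = round(100 * records$entry_count[idx] / total_entries, 1)
  )
  out[order(-out$entry_count, out$drug), , drop = FALSE]
}
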