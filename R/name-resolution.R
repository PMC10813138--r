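# Resolution of raw (German) substance names to canonical English names.
#
# Cascade: specific ATC code -> exact normalized name -> name + 'e'
# (a surprisingly effective German-to-English orthography rule for INNs,
# e.g. "hydrochlorothiazid" -> "hydrochlorothiazide") -> manual override
# -> unresolved.

#' Default normalization rule table
#'
#' Rules applied to a raw substance name before dictionary lookup:
#' a regular expression matching dose/strength tokens (removed), and a set
#' of German salt/ester suffixes that are stripped when glued directly to
#' the substance name (e.g. `"metoprololtartrat"` -> `"metoprolol"`).
#' Suffixes are only stripped when at least three characters remain, so
#' short names are never emptied.
#'
#' @return A list with elements `dose_pattern` and `salt_suffixes`.
#' @export
default_name_rules <- function() {
  list(
    dose_pattern = paste0(
      "\\b[0-9]+([.,][0-9]+)?\\s*",
      "(mg|g|µg|ug|mcg|ml|l|i\\.?e\\.?|ie|%)?\\b"
    ),
    salt_suffixes = c(
      "hydrochlorid", "dihydrochlorid", "tartrat", "hemifumarat",
      "fumarat", "succinat", "sulfat", "hydrogensulfat", "maleat",
      "mesilat", "besilat", "acetat", "natrium", "kalium"
    )
  )
}

#' Normalize a raw substance name
#'
#' Lowercases, collapses whitespace, removes dose tokens and strips
#' configured salt suffixes. Resolution proper is done by
#' [resolve_names()]; abbreviations such as `"ASS"` normalize to
#' `"ass"` here and are left to the override map.
#'
#' @param x Character vector of raw names.
#' @param rules Rule table, see [default_name_rules()].
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_raw("  Ramipril 5mg ")        # "ramipril"
#' normalize_raw("Metoprololtartrat")      # "metoprolol"
normalize_raw <- function(x, rules = default_name_rules()) {
  if (any(is.na(x) | stringr::str_squish(x) == "")) {
    stop("raw name empty", call. = FALSE)
  }
  out <- tolower(stringr::str_squish(x))
  out <- stringr::str_squish(gsub(rules$dose_pattern, " ", out,
                                  ignore.case = TRUE))
  if (length(rules$salt_suffixes) > 0L) {
    for (suf in rules$salt_suffixes) {
      hit <- endsWith(out, suf) & nchar(out) - nchar(suf) >= 3L
      out[hit] <- substr(out[hit], 1L, nchar(out[hit]) - nchar(suf))
    }
    out <- stringr::str_squish(out)
  }
  if (any(out == "")) {
    stop("name empty after normalization: ",
         paste(x[out == ""], collapse = ", "), call. = FALSE)
  }
  out
}

#' Is an ATC code specific to a single substance?
#'
#' Higher-level ATC codes (e.g. `"C09"`) group many substances and cannot
#' identify one; only the full 7-character substance-level code (letter,
#' two digits, two letters, two digits) is accepted for code-based
#' resolution.
#'
#' @param atc_code Character vector of ATC codes (NA allowed).
#' @return Logical vector.
#' @export
#' @examples
#' is_specific_atc(c("C09AA05", "C09", NA, ""))
is_specific_atc <- function(atc_code) {
  !is.na(atc_code) &
    grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", toupper(atc_code))
}

#' Build a name index for resolution
#'
#' @param atc_to_name A tibble/data.frame with columns `atc` and `name`,
#'   or a named character vector (names = ATC codes).
#' @param names Character vector of canonical English drug names; defaults
#'   to the names appearing in `atc_to_name`.
#' @return A `name_index` object with the ATC map (uppercase keys) and the
#'   lowercase canonical name set.
#' @export
name_index <- function(atc_to_name = NULL, names = NULL) {
  map <- character()
  if (!is.null(atc_to_name)) {
    if (is.data.frame(atc_to_name)) {
      stopifnot(all(c("atc", "name") %in% base::names(atc_to_name)))
      map <- stats::setNames(tolower(atc_to_name$name),
                             toupper(atc_to_name$atc))
    } else {
      map <- stats::setNames(tolower(atc_to_name),
                             toupper(base::names(atc_to_name)))
    }
    bad <- !is_specific_atc(base::names(map))
    if (any(bad)) {
      stop("non-substance-level ATC key(s) in index: ",
           paste(base::names(map)[bad], collapse = ", "), call. = FALSE)
    }
  }
  name_set <- sort(unique(tolower(stringr::str_squish(
    c(names %||% character(), unname(map))
  ))))
  structure(list(atc_to_name = map, name_set = name_set),
            class = "name_index")
}

#' @export
print.name_index <- function(x, ...) {
  cat("<name_index> ", length(x$name_set), " canonical names, ",
      length(x$atc_to_name), " ATC mappings\n", sep = "")
  invisible(x)
}

#' Read a name index from TSV files
#'
#' `atc_path` is a two-column TSV with header `atc<TAB>name`; `names_path`
#' is a one-column list of canonical names with header `name` (optional).
#'
#' @param atc_path,names_path File paths; either may be `NULL`.
#' @return A [name_index()] object.
#' @export
read_name_index <- function(atc_path = NULL, names_path = NULL) {
  atc_tab <- NULL
  extra <- NULL
  if (!is.null(atc_path)) {
    atc_tab <- readr::read_tsv(atc_path, col_types = "cc", progress = FALSE)
    stopifnot(all(c("atc", "name") %in% names(atc_tab)))
  }
  if (!is.null(names_path)) {
    extra <- readr::read_tsv(names_path, col_types = "c",
                             progress = FALSE)[[1]]
  }
  name_index(atc_to_name = atc_tab, names = extra)
}

#' Build or read a manual override map
#'
#' Raw names that no automatic rule can translate (abbreviations like
#' `"ASS"`, brand names, German names without the trailing-'e' pattern)
#' are translated by hand via an override map from normalized raw name to
#' canonical name. Unless `allow_new` is set, override targets must exist
#' in the index's name set, which guards against typos introducing
#' phantom drugs.
#'
#' @param x Named character vector (names = normalized raw names, values =
#'   canonical names) or a data.frame with columns `raw`, `canonical`.
#' @param index Optional [name_index()] used to validate targets.
#' @param allow_new Allow override targets outside the index name set.
#' @return Named character vector of class `override_map`.
#' @export
override_map <- function(x = character(), index = NULL, allow_new = FALSE) {
  if (is.data.frame(x)) {
    x <- stats::setNames(x$canonical, x$raw)
  }
  out <- stats::setNames(tolower(stringr::str_squish(x)),
                         tolower(stringr::str_squish(names(x) %||%
                                                       character())))
  if (!is.null(index) && !allow_new) {
    bad <- setdiff(unname(out), index$name_set)
    if (length(bad) > 0L) {
      stop("override target(s) not in name set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(out, class = "override_map")
}

#' @rdname override_map
#' @param path TSV file with columns `raw` and `canonical`.
#' @export
read_override_map <- function(path, index = NULL, allow_new = FALSE) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stopifnot(all(c("raw", "canonical") %in% names(tab)))
  override_map(tab, index = index, allow_new = allow_new)
}

#' Resolve raw substance names to canonical English names
#'
#' Applies the resolution cascade to each (raw name, ATC code) pair, in
#' this exact order, recording which step fired:
#'
#' 1. `ATC` — the full 7-character ATC code is present, substance-level
#'    specific, and known to the index;
#' 2. `EXACT` — the normalized name is in the canonical name set;
#' 3. `E_SUFFIX` — the normalized name plus a single trailing `'e'` is in
#'    the canonical name set;
#' 4. `OVERRIDE` — the normalized name has a manual override;
#' 5. `UNRESOLVED` — nothing matched; `canonical_name` is `NA`.
#'
#' A malformed (non-specific) ATC code skips step 1 with a warning rather
#' than failing the whole run.
#'
#' @param raw_names Character vector of raw names.
#' @param atc_codes Optional character vector of ATC codes (recycled NA
#'   if `NULL`).
#' @param index A [name_index()].
#' @param overrides An optional [override_map()].
#' @param rules Normalization rules, see [default_name_rules()].
#' @param warn_malformed_atc Emit one warning listing malformed non-NA
#'   ATC codes.
#' @return Tibble with columns `raw_name`, `atc_code`, `canonical_name`,
#'   `method`, `atc_used`.
#' @export
resolve_names <- function(raw_names, atc_codes = NULL, index,
                          overrides = NULL, rules = default_name_rules(),
                          warn_malformed_atc = TRUE) {
  stopifnot(inherits(index, "name_index"))
  n <- length(raw_names)
  atc_codes <- atc_codes %||% rep(NA_character_, n)
  stopifnot(length(atc_codes) == n)
  atc_up <- toupper(atc_codes)
  norm <- normalize_raw(raw_names, rules)

  canonical <- rep(NA_character_, n)
  method <- rep("UNRESOLVED", n)
  atc_used <- rep(NA_character_, n)

  specific <- is_specific_atc(atc_up)
  malformed <- !is.na(atc_codes) & atc_codes != "" & !specific
  if (warn_malformed_atc && any(malformed)) {
    warning("skipping non-specific ATC code(s): ",
            paste(unique(atc_codes[malformed]), collapse = ", "),
            call. = FALSE)
  }

  # (1) ATC
  hit <- specific & atc_up %in% names(index$atc_to_name)
  canonical[hit] <- unname(index$atc_to_name[atc_up[hit]])
  method[hit] <- "ATC"
  atc_used[hit] <- atc_up[hit]

  # (2) exact name
  open <- method == "UNRESOLVED"
  hit <- open & norm %in% index$name_set
  canonical[hit] <- norm[hit]
  method[hit] <- "EXACT"

  # (3) 'e' suffix
  open <- method == "UNRESOLVED"
  withe <- paste0(norm, "e")
  hit <- open & withe %in% index$name_set
  canonical[hit] <- withe[hit]
  method[hit] <- "E_SUFFIX"

  # (4) manual override
  if (!is.null(overrides) && length(overrides) > 0L) {
    open <- method == "UNRESOLVED"
    hit <- open & norm %in% names(overrides)
    canonical[hit] <- unname(unclass(overrides)[norm[hit]])
    method[hit] <- "OVERRIDE"
  }

  tibble::tibble(
    raw_name = raw_names,
    atc_code = atc_codes,
    canonical_name = canonical,
    method = method,
    atc_used = atc_used
  )
}

#' @rdname resolve_names
#' @param raw_name,atc_code Scalar versions for a single lookup.
#' @export
resolve_name <- function(raw_name, atc_code = NA_character_, index,
                         overrides = NULL, rules = default_name_rules()) {
  resolve_names(raw_name, atc_code, index, overrides, rules)
}
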