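# Substrate resources: coverage policies, snapshot files, tri-state lookup.
#
# The single most consequential modelling choice in comparing substrate
# resources is what "assessed" means. A catalog-style database (Drugbank
# and its kin) has an entry for essentially every marketed drug, so a drug
# it catalogs with no CYP2 substrate record has been assessed and found to
# be a non-substrate. A curated list (the FDA clinical-substrates table,
# the Flockhart table) says nothing about drugs it does not list. The two
# semantics are encoded explicitly as coverage policies:
#   CATALOG      assessed-set = catalog_names
#   LISTED_ONLY  assessed-set = the listed entries

#' Construct a substrate resource
#'
#' @param id Resource identifier (e.g. `"DRUGBANK"`, `"FDA"`).
#' @param policy Coverage policy, `"CATALOG"` or `"LISTED_ONLY"`.
#' @param entries Named list mapping canonical drug name to a character
#'   vector of enzymes the drug is a substrate of (possibly empty).
#' @param catalog_names For `CATALOG` resources, the full set of cataloged
#'   names; defaults to `names(entries)`. Ignored for `LISTED_ONLY`.
#' @param enzymes Configured enzyme set.
#' @param version Free-text version/date string of the snapshot.
#' @return An object of class `substrate_resource`.
#' @export
substrate_resource <- function(id, policy, entries,
                               catalog_names = NULL,
                               enzymes = cyp_enzymes(),
                               version = NA_character_) {
  policy <- match.arg(policy, c("CATALOG", "LISTED_ONLY"))
  stopifnot(is.list(entries))
  nm <- tolower(names(entries) %||% character())
  names(entries) <- nm
  for (e in entries) {
    bad <- setdiff(e, enzymes)
    if (length(bad) > 0L) {
      stop("enzyme(s) outside configured set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (policy == "CATALOG") {
    catalog_names <- sort(unique(tolower(catalog_names %||% nm)))
    outside <- setdiff(nm, catalog_names)
    if (length(outside) > 0L) {
      stop("entries outside catalog: ", paste(outside, collapse = ", "),
           call. = FALSE)
    }
  } else {
    catalog_names <- sort(unique(nm))
  }
  structure(
    list(id = id, policy = policy, entries = entries,
         catalog_names = catalog_names, enzymes = enzymes,
         version = version),
    class = "substrate_resource"
  )
}

#' @export
print.substrate_resource <- function(x, ...) {
  cat("<substrate_resource> ", x$id, " [", x$policy, "] ",
      length(assessed_names(x)), " assessed drugs",
      if (!is.na(x$version)) paste0(", version ", x$version), "\n",
      sep = "")
  invisible(x)
}

#' Names a resource has assessed
#'
#' @param resource A [substrate_resource()].
#' @return Sorted character vector of assessed canonical names.
#' @export
assessed_names <- function(resource) {
  stopifnot(inherits(resource, "substrate_resource"))
  if (resource$policy == "CATALOG") resource$catalog_names
  else sort(unique(names(resource$entries)))
}

#' Tri-state substrate lookup
#'
#' Under `CATALOG` policy a drug absent from the catalog is
#' `"not_assessed"`; a cataloged drug is `"substrate"` if the enzyme is in
#' its substrate set, else `"non_substrate"`. Under `LISTED_ONLY` the same
#' logic runs over the listed entries only. The lookup is total: every
#' (name, enzyme) pair yields exactly one state.
#'
#' @param resource A [substrate_resource()].
#' @param names Character vector of canonical drug names.
#' @param enzyme A single enzyme identifier from the resource's set.
#' @return Character vector of tri-states, same length as `names`.
#' @export
substrate_lookup <- function(resource, names, enzyme) {
  stopifnot(inherits(resource, "substrate_resource"))
  assert_enzyme(enzyme, resource$enzymes)
  names <- tolower(names)
  assessed <- names %in% assessed_names(resource)
  is_sub <- vapply(names, function(nm) {
    enzyme %in% (resource$entries[[nm]] %||% character())
  }, logical(1), USE.NAMES = FALSE)
  dplyr::case_when(
    !assessed ~ "not_assessed",
    is_sub ~ "substrate",
    .default = "non_substrate"
  )
}

#' Read a substrate-resource snapshot file
#'
#' The snapshot format is a TSV with pragma lines before the header:
#' `#policy=CATALOG|LISTED_ONLY` (mandatory), and optional `#id=` and
#' `#version=`. Columns: `name` (mandatory), optional `atc` and `note`,
#' and one 0/1 (or TRUE/FALSE) column per enzyme. Any other column is an
#' error. Duplicate names are merged by union of their enzyme sets, with
#' a warning.
#'
#' @param path Snapshot file path.
#' @param enzymes Configured enzyme set the columns are validated against.
#' @param id Override the resource id (default: pragma, else file name).
#' @return A [substrate_resource()].
#' @export
read_substrate_snapshot <- function(path, enzymes = cyp_enzymes(),
                                    id = NULL) {
  if (!file.exists(path)) {
    stop("snapshot not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  pragma_lines <- grep("^#", lines, value = TRUE)
  pragmas <- list()
  for (pl in pragma_lines) {
    m <- regmatches(pl, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", pl))[[1]]
    if (length(m) == 3L) pragmas[[m[2]]] <- stringr::str_squish(m[3])
  }
  if (is.null(pragmas$policy)) {
    stop("snapshot ", path, ": missing '#policy=' pragma", call. = FALSE)
  }
  policy <- match.arg(toupper(pragmas$policy), c("CATALOG", "LISTED_ONLY"))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"name" %in% names(tab)) {
    stop("snapshot ", path, ": missing 'name' column", call. = FALSE)
  }
  enzyme_cols <- setdiff(names(tab), c("name", "atc", "note"))
  unknown <- setdiff(enzyme_cols, enzymes)
  if (length(unknown) > 0L) {
    stop("snapshot ", path, ": unknown enzyme column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab$name <- tolower(stringr::str_squish(tab$name))
  if (anyDuplicated(tab$name)) {
    warning("snapshot ", path, ": duplicate drug name(s) merged: ",
            paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
            call. = FALSE)
  }
  as_bool <- function(x) {
    x <- toupper(stringr::str_squish(x))
    out <- x %in% c("1", "TRUE", "T", "X", "YES")
    out[is.na(x) | x == ""] <- FALSE
    out
  }
  entries <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    set <- enzyme_cols[vapply(enzyme_cols,
                              function(ec) as_bool(tab[[ec]][i]),
                              logical(1))]
    entries[[nm]] <- sort(unique(c(entries[[nm]], set)))
  }
  substrate_resource(
    id = id %||% pragmas$id %||%
      toupper(tools::file_path_sans_ext(basename(path))),
    policy = policy,
    entries = entries,
    enzymes = enzymes,
    version = pragmas$version %||% NA_character_
  )
}

#' Write a substrate resource as a snapshot file
#'
#' Writes the versioned pragma header and one row per cataloged name with
#' 0/1 enzyme flags. `read_substrate_snapshot()` of the result
#' reconstructs an equivalent resource.
#'
#' @param resource A [substrate_resource()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_substrate_snapshot <- function(resource, path) {
  stopifnot(inherits(resource, "substrate_resource"))
  nms <- assessed_names(resource)
  header <- c(
    paste0("#policy=", resource$policy),
    paste0("#id=", resource$id),
    if (!is.na(resource$version)) paste0("#version=", resource$version),
    paste(c("name", resource$enzymes), collapse = "\t")
  )
  rows <- vapply(nms, function(nm) {
    set <- resource$entries[[nm]] %||% character()
    paste(c(nm, as.integer(resource$enzymes %in% set)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Parse a Drugbank-style XML export into snapshot rows
#'
#' Reads a minimal XML dialect: a root element containing `<drug>`
#' elements, each with a `<name>`, optional `<atc-codes><atc-code
#' code="..."/>` children, and `<enzymes><enzyme>` children carrying the
#' enzyme `<name>` and `<actions><action>` entries. Only enzyme records
#' whose actions include `"substrate"` and whose name is in the configured
#' enzyme set contribute to the substrate flags; every drug is retained in
#' the catalog regardless (a cataloged drug with no qualifying enzyme
#' record is an assessed non-substrate under `CATALOG` policy).
#'
#' @param path XML file path.
#' @param enzymes Configured enzyme set.
#' @return Tibble with columns `name`, `atc`, and one logical column per
#'   enzyme.
#' @export
parse_drugbank_xml <- function(path, enzymes = cyp_enzymes()) {
  if (!file.exists(path)) {
    stop("XML file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  drugs <- xml2::xml_find_all(doc, ".//drug")
  if (length(drugs) == 0L) {
    stop("malformed XML in ", path, ": no <drug> elements under ",
         xml2::xml_name(doc), call. = FALSE)
  }
  rows <- lapply(seq_along(drugs), function(i) {
    d <- drugs[[i]]
    nm_node <- xml2::xml_find_first(d, "./name")
    if (is.na(nm_node)) {
      stop("malformed XML in ", path, ": drug[", i, "] has no <name>",
           call. = FALSE)
    }
    nm <- tolower(stringr::str_squish(xml2::xml_text(nm_node)))
    atcs <- xml2::xml_attr(
      xml2::xml_find_all(d, "./atc-codes/atc-code"), "code")
    enz_nodes <- xml2::xml_find_all(d, "./enzymes/enzyme")
    sub_set <- character()
    for (en in enz_nodes) {
      enz_name <- toupper(stringr::str_squish(
        xml2::xml_text(xml2::xml_find_first(en, "./name"))))
      actions <- tolower(xml2::xml_text(
        xml2::xml_find_all(en, "./actions/action")))
      if (enz_name %in% enzymes && "substrate" %in% actions) {
        sub_set <- c(sub_set, enz_name)
      }
    }
    row <- tibble::tibble(name = nm,
                          atc = paste(atcs, collapse = ";"))
    for (e in enzymes) row[[e]] <- e %in% sub_set
    row
  })
  dplyr::bind_rows(rows)
}

#' Turn snapshot rows into a substrate resource
#'
#' @param rows Tibble with a `name` column and one logical/0-1 column per
#'   enzyme (as produced by [parse_drugbank_xml()]).
#' @inheritParams substrate_resource
#' @return A [substrate_resource()].
#' @export
as_substrate_resource <- function(rows, id, policy = "CATALOG",
                                  enzymes = cyp_enzymes(),
                                  version = NA_character_) {
  stopifnot("name" %in% names(rows))
  entries <- list()
  for (i in seq_len(nrow(rows))) {
    nm <- tolower(rows$name[i])
    set <- enzymes[vapply(enzymes, function(e) {
      isTRUE(as.logical(rows[[e]][i]))
    }, logical(1))]
    entries[[nm]] <- sort(unique(c(entries[[nm]], set)))
  }
  substrate_resource(id = id, policy = policy, entries = entries,
                     enzymes = enzymes, version = version)
}
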