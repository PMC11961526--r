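#' Read a wide specimen measurement table
#'
#' Reads a wide-format table (one row per specimen-element) with the label
#' columns `individual_id`, `element`, `side`, `ecotype`, `variety`, `sex`,
#' `castrated`, `fusion_state`, `castration_age`, `collection_year`,
#' `locality`, followed by one column per measurement code. Empty cells are
#' treated as absent measurements. CSV (UTF-8, comma, header) and XLSX
#' (first sheet, identical schema) are supported. All measurement values
#' are converted to millimetres according to `unit_policy`.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"xlsx"`; default guessed from the extension.
#' @param registry Measurement registry used to recognise measurement
#'   columns (default [measurement_registry()]).
#' @param unit_policy Named character vector mapping measurement codes to
#'   their unit in the file, `"mm"` (default for unlisted codes) or `"cm"`.
#'   `cm` values are multiplied by 10.
#' @return A tibble of validated specimen records in mm. Columns present in
#'   the file but neither labels nor registry codes are reported via a
#'   warning and kept under their own names (never silently dropped); the
#'   attribute `"unknown_columns"` lists them.
#' @seealso [validate_specimen_table()], [write_specimen_table()]
#' @export
read_specimen_table <- function(path, format = c("guess", "csv", "xlsx"),
                                registry = measurement_registry(),
                                unit_policy = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = readxl::read_excel(path, sheet = 1L)
  )
  as_specimen_table(raw, registry = registry, unit_policy = unit_policy)
}

.label_cols <- function() {
  c("individual_id", "element", "side", "ecotype", "variety", "sex",
    "castrated", "fusion_state", "castration_age", "collection_year",
    "locality")
}

#' Coerce a raw wide table into a validated specimen table
#'
#' @param raw A data frame with the wide schema of [read_specimen_table()].
#' @inheritParams read_specimen_table
#' @return Validated specimen tibble in mm.
#' @export
as_specimen_table <- function(raw, registry = measurement_registry(),
                              unit_policy = NULL) {
  labels <- .label_cols()
  missing_lab <- setdiff(c("individual_id", "element"), names(raw))
  if (length(missing_lab)) {
    stop("required columns absent: ", paste(missing_lab, collapse = ", "))
  }
  codes <- intersect(names(raw), unique(registry$code))
  unknown <- setdiff(names(raw), c(labels, unique(registry$code)))
  if (length(unknown)) {
    warning("columns not in schema or registry (kept as-is): ",
            paste(unknown, collapse = ", "))
  }
  tab <- tibble::as_tibble(raw)
  # fill optional label columns so downstream code can rely on them
  if (!"side" %in% names(tab)) tab$side <- "unknown"
  if (!"fusion_state" %in% names(tab)) tab$fusion_state <- "unknown"
  if (!"castrated" %in% names(tab)) tab$castrated <- FALSE
  if (!"castration_age" %in% names(tab)) tab$castration_age <- NA_real_
  tab$castrated <- as.logical(tab$castrated)
  tab$castration_age <- as.numeric(tab$castration_age)
  for (cd in codes) {
    v <- as.numeric(tab[[cd]])
    unit <- if (!is.null(unit_policy) && cd %in% names(unit_policy)) {
      unit_policy[[cd]]
    } else {
      "mm"
    }
    if (!unit %in% c("mm", "cm")) stop("unsupported unit for ", cd, ": ", unit)
    if (unit == "cm") v <- v * 10
    tab[[cd]] <- v
  }
  attr(tab, "unknown_columns") <- unknown
  validate_specimen_table(tab, registry = registry)
  tab
}

#' Validate a specimen table
#'
#' Checks that every measurement value is positive (absent values allowed),
#' that measurement columns belong to the registry for the row's element,
#' and that group labels (when present) satisfy the taxonomy.
#'
#' @param tab Specimen tibble.
#' @param registry Measurement registry.
#' @return `tab`, invisibly. Validation failures raise an error naming the
#'   offending rows and codes.
#' @export
validate_specimen_table <- function(tab, registry = measurement_registry()) {
  if (!all(tab$element %in% osteo_elements())) {
    stop("unknown element(s): ",
         paste(setdiff(unique(tab$element), osteo_elements()), collapse = ", "))
  }
  codes <- intersect(names(tab), unique(registry$code))
  problems <- character(0)
  for (cd in codes) {
    v <- tab[[cd]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      problems <- c(problems, paste0("row ", bad, ": ", cd, " = ", v[bad]))
    }
    # a value is only licit where the registry defines the code for that element
    legal <- registry$element[registry$code == cd]
    off <- which(!is.na(v) & !(tab$element %in% legal))
    if (length(off)) {
      problems <- c(problems,
                    paste0("row ", off, ": ", cd, " not defined for element '",
                           tab$element[off], "'"))
    }
  }
  if (length(problems)) {
    stop("nonpositive or misplaced measurement value(s):\n  ",
         paste(problems, collapse = "\n  "))
  }
  if (all(c("ecotype", "variety", "sex", "castrated") %in% names(tab))) {
    validate_group_labels(tab)
  }
  invisible(tab)
}

#' Write a specimen table as wide CSV
#'
#' @param tab Specimen tibble (mm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(tab, path) {
  readr::write_csv(tab, path, na = "")
  invisible(path)
}

#' Apply the sample inclusion rules
#'
#' Osteometric analysis of adult animals requires epiphyseal fusion, and
#' castration only alters bone growth while growth is still ongoing: the
#' filters keep osteologically mature specimens (fused epiphyses) and, for
#' castrates, only animals castrated before the cutoff age (default 4.5
#' years, the onset of osteological adulthood in reindeer, strict `<`).
#' Intact animals are unaffected by the age rule. Records with unknown
#' fusion state are excluded unless `allow_unknown_fusion = TRUE`.
#'
#' @param tab Specimen tibble.
#' @param castration_age_cutoff_years Cutoff in years (default 4.5).
#' @param allow_unknown_fusion Keep records whose fusion state is unknown
#'   (default `FALSE`).
#' @return List with `kept` (tibble) and `exclusions` (tibble with `row_id`,
#'   `individual_id`, `element`, `reason`). The operation is idempotent.
#' @examples
#' tab <- simulate_assemblage(synth_params(n_per_group = 2, seed = 1))
#' apply_inclusion_rules(tab)$exclusions
#' @export
apply_inclusion_rules <- function(tab, castration_age_cutoff_years = 4.5,
                                  allow_unknown_fusion = FALSE) {
  stopifnot(castration_age_cutoff_years >= 0)
  fusion <- tab$fusion_state
  reason <- rep(NA_character_, nrow(tab))
  reason[fusion == "unfused"] <- "unfused"
  if (!allow_unknown_fusion) {
    reason[is.na(reason) & fusion == "unknown"] <- "fusion_unknown"
  }
  late <- tab$castrated & !is.na(tab$castration_age) &
    tab$castration_age >= castration_age_cutoff_years
  reason[is.na(reason) & late] <- "castration_age"
  drop <- !is.na(reason)
  exclusions <- tibble::tibble(
    row_id = which(drop),
    individual_id = tab$individual_id[drop],
    element = tab$element[drop],
    reason = reason[drop]
  )
  list(kept = tab[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Write an exclusion log as CSV
#'
#' @param exclusions Exclusion tibble from [apply_inclusion_rules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  readr::write_csv(exclusions, path)
  invisible(path)
}

#' Keep one side per individual and element
#'
#' Paired elements must not enter an analysis twice for the same animal.
#' With `preference = "max_complete"` (default) the side with more recorded
#' measurements wins; ties break deterministically to the left side, then
#' to the earlier row.
#'
#' @param tab Specimen tibble.
#' @param registry Measurement registry (used to count recorded values).
#' @param preference `"max_complete"`, `"left_first"`, or `"right_first"`.
#' @return Tibble with at most one row per `(individual_id, element)`.
#' @export
dedupe_sides <- function(tab, registry = measurement_registry(),
                         preference = c("max_complete", "left_first", "right_first")) {
  preference <- match.arg(preference)
  codes <- intersect(names(tab), unique(registry$code))
  n_vals <- rowSums(!is.na(as.matrix(tab[, codes, drop = FALSE])))
  side_rank <- function(side, first) {
    r <- match(side, c(first, setdiff(c("left", "right"), first), "unknown"))
    ifelse(is.na(r), 4L, r)
  }
  pref_rank <- switch(preference,
    max_complete = side_rank(tab$side, "left"),
    left_first = side_rank(tab$side, "left"),
    right_first = side_rank(tab$side, "right")
  )
  ord_key <- if (preference == "max_complete") {
    order(tab$individual_id, tab$element, -n_vals, pref_rank, seq_len(nrow(tab)))
  } else {
    order(tab$individual_id, tab$element, pref_rank, -n_vals, seq_len(nrow(tab)))
  }
  tab2 <- tab[ord_key, , drop = FALSE]
  keep <- !duplicated(tab2[, c("individual_id", "element")])
  out <- tab2[keep, , drop = FALSE]
  # restore original row order among the survivors
  out[order(match(
    paste(out$individual_id, out$element),
    paste(tab$individual_id, tab$element)
  )), , drop = FALSE]
}

#' Build a complete-case measurement matrix for one element and subset
#'
#' Retains only specimens possessing every variable of the subset
#' (complete-case), in registry variable order. Dropped specimens are
#' recorded on the result.
#'
#' @param tab Specimen tibble (ideally after inclusion rules and side
#'   dedup).
#' @param element One element name.
#' @param subset_id Variable subset id (see [region_codes()]).
#' @param registry Measurement registry.
#' @param override Optional explicit code list overriding region tags.
#' @return An object of class `osteo_matrix`: a list with `element`,
#'   `subset_id`, `codes`, `x` (numeric matrix, rows = specimens, mm),
#'   `specimens` (label tibble aligned with rows), and `dropped`
#'   (individual ids removed as incomplete).
#' @export
select_matrix <- function(tab, element, subset_id = "all",
                          registry = measurement_registry(),
                          override = NULL) {
  codes <- region_codes(registry, element, subset_id, override = override)
  if (length(codes) < 2L) {
    stop("subset '", subset_id, "' for ", element,
         " resolves to fewer than 2 variables")
  }
  sub <- tab[tab$element == element, , drop = FALSE]
  missing_cols <- setdiff(codes, names(sub))
  for (mc in missing_cols) sub[[mc]] <- NA_real_
  x <- as.matrix(sub[, codes, drop = FALSE])
  complete <- stats::complete.cases(x)
  if (!any(complete)) {
    stop("no specimen has complete data for ", element, "/", subset_id)
  }
  dropped <- sub$individual_id[!complete]
  sub <- sub[complete, , drop = FALSE]
  x <- x[complete, , drop = FALSE]
  rownames(x) <- sub$individual_id
  structure(
    list(element = element, subset_id = subset_id, codes = codes,
         x = x, specimens = sub[, intersect(.label_cols(), names(sub))],
         dropped = dropped),
    class = "osteo_matrix"
  )
}

#' @export
print.osteo_matrix <- function(x, ...) {
  cat("osteo_matrix:", x$element, "/", x$subset_id, "-",
      nrow(x$x), "specimens x", length(x$codes), "variables\n")
  cat("variables:", paste(x$codes, collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("dropped (incomplete):", length(x$dropped), "specimens\n")
  }
  invisible(x)
}
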