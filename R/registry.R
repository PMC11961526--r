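#' Long-bone and pelvis elements recognised by the package
#'
#' @return Character vector of the seven skeletal elements.
#' @export
osteo_elements <- function() {
  c("humerus", "radioulna", "metacarpus", "femur", "tibia", "metatarsus", "pelvis")
}

#' Axis classes and bone regions used in the measurement registry
#'
#' @name registry-vocab
#' @return Character vectors of the valid axis classes / regions.
NULL

#' @rdname registry-vocab
#' @export
osteo_axis_classes <- function() {
  c("length", "breadth", "depth", "circumference", "other")
}

#' @rdname registry-vocab
#' @export
osteo_regions <- function() {
  c("proximal", "distal", "shaft", "whole")
}

# One element's measurement definitions, given as a compact spec string
# "code axis region" to keep the table readable. Units are always mm.
.def <- function(element, spec) {
  parts <- strsplit(trimws(strsplit(spec, ";")[[1]]), "\\s+")
  tibble::tibble(
    code = vapply(parts, `[`, "", 1L),
    element = element,
    axis_class = vapply(parts, `[`, "", 2L),
    region = vapply(parts, `[`, "", 3L),
    canonical_unit = "mm"
  )
}

#' The packaged osteometric measurement registry
#'
#' Enumerates the standard measurement codes per skeletal element together
#' with an axis class (length, breadth, depth, circumference, other), the
#' bone region the measurement is taken from (proximal epiphysis, distal
#' epiphysis, diaphysis/shaft, or whole bone), and the canonical unit (mm).
#' The default registry carries 99 definitions spanning six long bones and
#' the pelvis. Codes follow zooarchaeological convention (GL greatest
#' length, SD smallest diaphysis breadth, SDD smallest diaphysis depth,
#' CD smallest diaphysis circumference, Bd distal breadth, Bp proximal
#' breadth, ...). The region tags drive the fragmentary-specimen variable
#' subsets; an explicit per-subset code list can override them (see
#' [region_codes()]).
#'
#' The exact measurement protocol definitions live in the reference
#' literature; this packaged table is a synthetic stand-in enumeration
#' sufficient to type-check data and derive region subsets.
#'
#' @return A tibble with columns `code`, `element`, `axis_class`, `region`,
#'   `canonical_unit`, one row per measurement definition.
#' @examples
#' reg <- measurement_registry()
#' nrow(reg)
#' dplyr::count(reg, element)
#' @export
measurement_registry <- function() {
  reg <- dplyr::bind_rows(
    .def("humerus", "
      GL length whole; GLl length whole; GLC length whole; PL length whole;
      Bp breadth proximal; Dp depth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BT breadth distal; HT other distal; HTC other distal;
      Dd depth distal"),
    .def("radioulna", "
      GL length whole; PL length whole; LO length proximal; SDO depth proximal;
      DPA depth proximal; Bp breadth proximal; BFp breadth proximal; Dp depth proximal;
      BPC breadth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BFd breadth distal; Dd depth distal"),
    .def("metacarpus", "
      GL length whole; Ll length whole; PL length whole;
      Bp breadth proximal; BAp breadth proximal; Dp depth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BFd breadth distal; Dd depth distal;
      DVl depth distal; BDF breadth distal"),
    .def("femur", "
      GL length whole; GLC length whole; PL length whole;
      Bp breadth proximal; BTr breadth proximal; DC depth proximal; Dp depth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BTd breadth distal; Dd depth distal; DdM depth distal"),
    .def("tibia", "
      GL length whole; Ll length whole; PL length whole;
      Bp breadth proximal; BFp breadth proximal; Dp depth proximal; DpM depth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BFd breadth distal; Dd depth distal; Dda depth distal"),
    .def("metatarsus", "
      GL length whole; Ll length whole; PL length whole;
      Bp breadth proximal; BAp breadth proximal; Dp depth proximal;
      SD breadth shaft; SDD depth shaft; CD circumference shaft;
      Bd breadth distal; BFd breadth distal; Dd depth distal;
      DVl depth distal; BDF breadth distal"),
    .def("pelvis", "
      GL length whole; LA length proximal; LAR length proximal; Dam depth proximal;
      GBA breadth proximal; GBTc breadth proximal;
      SB breadth shaft; SH other shaft; SC circumference shaft;
      LS length distal; DPS depth distal; GBTi breadth distal;
      LFo length distal; BFo breadth distal")
  )
  validate_registry(reg)
  reg
}

#' Validate a measurement registry
#'
#' Checks the structural invariants: known elements / axis classes / regions,
#' codes unique within element, and `region = "whole"` reserved for
#' length-type measurements spanning the bone.
#'
#' @param registry A registry tibble (see [measurement_registry()]).
#' @return The registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  needed <- c("code", "element", "axis_class", "region", "canonical_unit")
  if (!all(needed %in% names(registry))) {
    stop("registry must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(registry$element %in% osteo_elements())) stop("unknown element in registry")
  if (!all(registry$axis_class %in% osteo_axis_classes())) stop("unknown axis_class in registry")
  if (!all(registry$region %in% osteo_regions())) stop("unknown region in registry")
  dup <- duplicated(registry[, c("element", "code")])
  if (any(dup)) {
    stop("duplicated code within element: ",
         paste(unique(registry$code[dup]), collapse = ", "))
  }
  bad <- registry$region == "whole" & registry$axis_class != "length"
  if (any(bad)) {
    stop("region 'whole' is reserved for length measurements: ",
         paste(registry$code[bad], collapse = ", "))
  }
  invisible(registry)
}

#' Measurement codes for a bone-region variable subset
#'
#' Resolves the codes entering an analysis for one element and subset.
#' Subsets mirror the analysis units of fragmentary material: `proximal`,
#' `distal`, and `shaft` take the region-tagged codes; `all` takes every
#' code of the element; `complete_reduced` is a small subset for intact
#' bones (greatest length plus the principal proximal, shaft, and distal
#' dimensions). An explicit `override` code list wins over region tags,
#' accommodating externally specified subset definitions.
#'
#' @param registry Registry tibble.
#' @param element One element name.
#' @param subset_id One of `"all"`, `"proximal"`, `"distal"`, `"shaft"`,
#'   `"complete_reduced"`.
#' @param override Optional explicit character vector of codes.
#' @return Character vector of codes, in registry order.
#' @export
region_codes <- function(registry, element,
                         subset_id = c("all", "proximal", "distal", "shaft",
                                       "complete_reduced"),
                         override = NULL) {
  subset_id <- match.arg(subset_id)
  reg <- registry[registry$element == element, , drop = FALSE]
  if (nrow(reg) == 0L) stop("no registry entries for element '", element, "'")
  if (!is.null(override)) {
    unknown <- setdiff(override, reg$code)
    if (length(unknown)) {
      stop("override codes not in registry for ", element, ": ",
           paste(unknown, collapse = ", "))
    }
    return(reg$code[reg$code %in% override])
  }
  codes <- switch(subset_id,
    all = reg$code,
    proximal = reg$code[reg$region == "proximal"],
    distal = reg$code[reg$region == "distal"],
    shaft = reg$code[reg$region == "shaft"],
    complete_reduced = {
      pick <- c("GL", "Bp", "SD", "Bd", "DPS", "Dam", "SB")
      reg$code[reg$code %in% pick]
    }
  )
  if (length(codes) == 0L) stop("empty code list for ", element, "/", subset_id)
  codes
}

#' The seven canonical sample groups
#'
#' The study design partitions specimens into seven groups by ecotype
#' (tundra/mountain `tarandus` vs forest `fennicus`), variety within
#' tarandus (domestic vs wild), sex, and castration status. Group indices
#' follow the conventional ordering: 1 castrated domestic male, 2 intact
#' domestic male, 3 domestic female, 4 wild male, 5 wild female,
#' 6 fennicus male, 7 fennicus female.
#'
#' @return Tibble with columns `group`, `ecotype`, `variety`, `sex`,
#'   `castrated`, `label`.
#' @export
canonical_groups <- function() {
  tibble::tibble(
    group = 1:7,
    ecotype = c(rep("tarandus", 5), rep("fennicus", 2)),
    variety = c(rep("domestic", 3), rep("wild", 2),
                rep("not_applicable", 2)),
    sex = c("male", "male", "female", "male", "female", "male", "female"),
    castrated = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    label = c("domestic_castrate", "domestic_male", "domestic_female",
              "wild_male", "wild_female", "fennicus_male", "fennicus_female")
  )
}

#' Validate group label columns of a specimen table
#'
#' Enforces the group taxonomy invariants: fennicus has no wild/domestic
#' variety; castrates are domestic males.
#'
#' @param tab A data frame with columns `ecotype`, `variety`, `sex`,
#'   `castrated`.
#' @return `tab`, invisibly.
#' @export
validate_group_labels <- function(tab) {
  stopifnot(all(c("ecotype", "variety", "sex", "castrated") %in% names(tab)))
  if (!all(tab$ecotype %in% c("tarandus", "fennicus"))) stop("unknown ecotype")
  if (!all(tab$variety %in% c("domestic", "wild", "not_applicable"))) stop("unknown variety")
  if (!all(tab$sex %in% c("male", "female"))) stop("unknown sex")
  if (!is.logical(tab$castrated)) stop("castrated must be logical")
  bad_fen <- tab$ecotype == "fennicus" & tab$variety != "not_applicable"
  if (any(bad_fen)) stop("fennicus specimens must have variety 'not_applicable'")
  bad_cas <- tab$castrated & !(tab$sex == "male" & tab$variety == "domestic")
  if (any(bad_cas)) stop("castrated specimens must be domestic males")
  invisible(tab)
}

#' Attach the canonical group label to a specimen table
#'
#' @param tab Specimen table with `ecotype`, `variety`, `sex`, `castrated`.
#' @return `tab` with columns `group` (1-7) and `group_label` added.
#' @export
assign_groups <- function(tab) {
  validate_group_labels(tab)
  tab <- tab[, setdiff(names(tab), c("group", "group_label")), drop = FALSE]
  key <- canonical_groups()
  out <- dplyr::left_join(
    tab,
    dplyr::rename(key, group_label = "label"),
    by = c("ecotype", "variety", "sex", "castrated")
  )
  if (any(is.na(out$group))) stop("some rows do not match a canonical group")
  out
}
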