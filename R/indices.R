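#' Mennerich slenderness indices
#'
#' Dimensionless shape ratios relating a transverse dimension to bone
#' length, used to compare gracility across sexes, ecotypes, and
#' castration status. Index 1 is smallest diaphysis breadth over greatest
#' length, `SD * 100 / GL`; index 3 is distal breadth over greatest
#' length, `Bd / GL * 100`. Both are invariant under a common rescaling of
#' the inputs, so any consistent unit works.
#'
#' @param SD,Bd,GL Positive measurements (same unit).
#' @return The index value(s).
#' @examples
#' mennerich_index1(20, 200) # 10
#' mennerich_index3(50, 200) # 25
#' @name mennerich
NULL

#' @rdname mennerich
#' @export
mennerich_index1 <- function(SD, GL) {
  if (any(SD <= 0) || any(GL <= 0)) stop("SD and GL must be positive")
  SD * 100 / GL
}

#' @rdname mennerich
#' @export
mennerich_index3 <- function(Bd, GL) {
  if (any(Bd <= 0) || any(GL <= 0)) stop("Bd and GL must be positive")
  Bd / GL * 100
}

.axis_spec_codes <- function(spec) {
  switch(spec,
    ME1 = c("SD", "GL"),
    ME3 = c("Bd", "GL"),
    spec
  )
}

.axis_value <- function(spec, tab) {
  switch(spec,
    ME1 = mennerich_index1(tab[["SD"]], tab[["GL"]]),
    ME3 = mennerich_index3(tab[["Bd"]], tab[["GL"]]),
    tab[[spec]]
  )
}

#' Build scatterplot data from measurements and indices
#'
#' Pairs two axis specifications -- each a measurement code or one of the
#' index names `"ME1"`, `"ME3"` -- into one point per specimen possessing
#' all needed measurements, carrying the group label for colouring.
#' Combining a slenderness index with a size variable turns the
#' two-dimensional plot into a de facto size-and-shape comparison.
#'
#' @param tab Specimen tibble.
#' @param element Element to plot.
#' @param x_spec,y_spec Measurement code or `"ME1"` / `"ME3"`.
#' @param registry Measurement registry.
#' @param unit Output unit for plain measurement axes, `"mm"` (default) or
#'   `"cm"`; indices are dimensionless and unaffected.
#' @return Tibble with `individual_id`, `group_label`, `x`, `y`,
#'   `x_label`, `y_label`. Empty input yields an empty tibble.
#' @export
build_scatter <- function(tab, element, x_spec, y_spec,
                          registry = measurement_registry(),
                          unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  el_codes <- registry$code[registry$element == element]
  for (sp in c(x_spec, y_spec)) {
    needed <- .axis_spec_codes(sp)
    unknown <- setdiff(needed, el_codes)
    if (length(unknown)) {
      stop("'", sp, "' needs code(s) not defined for ", element, ": ",
           paste(unknown, collapse = ", "),
           "; valid codes: ", paste(el_codes, collapse = ", "))
    }
  }
  sub <- tab[tab$element == element, , drop = FALSE]
  need <- unique(c(.axis_spec_codes(x_spec), .axis_spec_codes(y_spec)))
  for (cd in setdiff(need, names(sub))) sub[[cd]] <- NA_real_
  ok <- stats::complete.cases(sub[, need, drop = FALSE])
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(individual_id = character(0),
                          group_label = character(0),
                          x = numeric(0), y = numeric(0),
                          x_label = character(0), y_label = character(0)))
  }
  spec <- assign_groups(sub)
  fac <- function(sp) if (sp %in% c("ME1", "ME3") || unit == "mm") 1 else 0.1
  tibble::tibble(
    individual_id = sub$individual_id,
    group_label = spec$group_label,
    x = .axis_value(x_spec, sub) * fac(x_spec),
    y = .axis_value(y_spec, sub) * fac(y_spec),
    x_label = x_spec,
    y_label = y_spec
  )
}

#' Pairwise bounding-box overlap diagnostic for a scatter
#'
#' A non-canonical, purely quantitative aid: cluster separation in the
#' scatterplots is assessed visually in practice, but a coarse numeric
#' screen is convenient for batch runs. For every pair of groups the 2-D
#' bounding boxes of their points are intersected; the score is the
#' intersection area divided by the smaller box's area (0 = disjoint
#' boxes, 1 = nested).
#'
#' @param points Tibble from [build_scatter()].
#' @return Tibble with `group_a`, `group_b`, `overlap` in \[0,1\].
#' @export
scatter_overlap_diagnostic <- function(points) {
  gs <- sort(unique(points$group_label))
  box <- function(g) {
    p <- points[points$group_label == g, ]
    c(range(p$x), range(p$y))
  }
  res <- list()
  if (length(gs) >= 2) {
    for (i in seq_len(length(gs) - 1)) {
      for (j in seq(i + 1, length(gs))) {
        a <- box(gs[i]); b <- box(gs[j])
        ox <- overlap_range(a[1:2], b[1:2])
        oy <- overlap_range(a[3:4], b[3:4])
        inter <- if (is.null(ox) || is.null(oy)) 0 else diff(ox) * diff(oy)
        area <- function(bb) max(diff(bb[1:2]), 0) * max(diff(bb[3:4]), 0)
        smaller <- min(area(a), area(b))
        res[[length(res) + 1L]] <- tibble::tibble(
          group_a = gs[i], group_b = gs[j],
          overlap = if (smaller > 0) inter / smaller else as.numeric(inter > 0)
        )
      }
    }
  }
  dplyr::bind_rows(res)
}
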