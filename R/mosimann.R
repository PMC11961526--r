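#' Isometric size of a specimen
#'
#' The Mosimann isometric size index: the arithmetic mean of the natural
#' logarithms of a specimen's measurements, `IS = sum(log(V)) / n`.
#' Multiplying every measurement by a constant `c` shifts the index by
#' exactly `log(c)`.
#'
#' @param values Positive numeric vector of measurements (one specimen),
#'   or a matrix with one specimen per row.
#' @return Scalar (or per-row vector) isometric size, in natural-log units.
#' @examples
#' isize(c(exp(1), exp(3))) # 2
#' @export
isize <- function(values) {
  if (any(values <= 0) || anyNA(values)) stop("all values must be positive")
  if (is.matrix(values)) rowMeans(log(values)) else mean(log(values))
}

#' Log shape ratios of a specimen
#'
#' Each measurement's log minus the specimen's isometric size,
#' `LSR_v = log(V_v) - IS`. The components sum to zero, so the vector
#' captures proportions free of isometric scale: rescaling all
#' measurements by a common factor leaves it unchanged.
#'
#' @inheritParams isize
#' @return Vector (or matrix, specimens in rows) of log shape ratios.
#' @examples
#' log_shape_ratios(c(exp(1), exp(3))) # c(-1, 1)
#' @export
log_shape_ratios <- function(values) {
  is_v <- isize(values)
  if (is.matrix(values)) log(values) - is_v else log(values) - is_v
}

#' Size-and-shape classifier features for a measurement matrix
#'
#' Builds the per-specimen feature vector `[iSize, LSR]` over exactly the
#' matrix's variable subset, so fragment analyses and complete-bone
#' analyses stay internally consistent. Because log shape ratios sum to
#' zero, one component is collinear; the last variable's LSR (registry
#' order) is dropped from the classifier features by default and recorded
#' for audit. With `p` variables the feature dimension is therefore `p`
#' (1 size + p-1 shape). `drop_policy = "none"` keeps all components for
#' callers that handle the singularity themselves (e.g. via identity
#' shrinkage).
#'
#' @param m An `osteo_matrix` from [select_matrix()].
#' @param drop_policy `"last"` (default) or `"none"`.
#' @return An object of class `osteo_features`: list with `features`
#'   (numeric matrix: column `isize` then `lsr_<code>` columns),
#'   `specimens` (label tibble with `group_label`), `codes`,
#'   `dropped_code`, `element`, `subset_id`.
#' @export
size_shape_features <- function(m, drop_policy = c("last", "none")) {
  drop_policy <- match.arg(drop_policy)
  stopifnot(inherits(m, "osteo_matrix"))
  if (length(m$codes) < 2L) stop("need at least 2 variables for size/shape features")
  is_v <- isize(m$x)
  lsr <- log_shape_ratios(m$x)
  dropped <- NA_character_
  if (drop_policy == "last") {
    dropped <- m$codes[length(m$codes)]
    lsr <- lsr[, -ncol(lsr), drop = FALSE]
  }
  feats <- cbind(isize = is_v, lsr)
  colnames(feats) <- c("isize", paste0("lsr_", colnames(lsr)))
  spec <- assign_groups(m$specimens)
  structure(
    list(features = feats, specimens = spec, codes = m$codes,
         dropped_code = dropped, element = m$element, subset_id = m$subset_id),
    class = "osteo_features"
  )
}

#' Write a feature table as CSV
#'
#' @param f `osteo_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(f, path) {
  out <- dplyr::bind_cols(
    tibble::tibble(individual_id = f$specimens$individual_id,
                   group_label = f$specimens$group_label),
    tibble::as_tibble(f$features)
  )
  readr::write_csv(out, path)
  invisible(path)
}
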