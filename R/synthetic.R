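#' Parameters for the synthetic assemblage generator
#'
#' The generator draws log-measurements per group and element from a
#' multivariate normal (so measurements are log-normal: positive, with
#' multiplicative biological variation) and exponentiates. Its mean
#' structure encodes the features the downstream analyses assume:
#'
#' * a per-group log-size offset `delta` acting equally on every
#'   log-measurement, so group differences in isometric size are exactly
#'   `delta` differences. The default ordering is strictly decreasing in
#'   the conventional size ranking: fennicus male > domestic male >
#'   domestic castrate > fennicus female > wild male > domestic female >
#'   wild female;
#' * per-group, per-element shape offsets (zero-sum over the element's
#'   variables) built from a gracility contrast (+ on lengths, - on shaft
#'   variables): fennicus groups and females are more gracile, so their
#'   shaft-breadth/length ratios (ME1) are smaller at equal size, and
#'   sexual dimorphism is stronger in diaphysis than in length dimensions;
#' * a castration deficit applied to the intact-male mean, scaled per
#'   variable by `castration_length_sparing` on length-type variables:
#'   castration affects breadth, depth, and circumference most while
#'   lengths are spared. The deficit magnitude is calibrated so the
#'   castrate group's expected isometric size equals `delta["domestic_castrate"]`,
#'   keeping castrates between intact males and females;
#' * an equicorrelated within-group covariance: correlation `rho` between
#'   all pairs of log-measurements and per-variable log-sd by axis class.
#'
#' @param registry Measurement registry.
#' @param n_per_group Specimens per group and element (default 20).
#' @param delta Named per-group log-size offsets (natural-log units),
#'   names as in `canonical_groups()$label`.
#' @param fennicus_gracility,female_gracility Shape-contrast coefficients
#'   (log units).
#' @param castration_length_sparing Factor in \[0,1\] scaling the castration
#'   effect on length variables relative to breadth/depth/circumference
#'   (default 0.25: the length deficit is a quarter of the breadth deficit
#'   in log units).
#' @param rho Common correlation between log-measurements, in \[0,1).
#' @param sigma Named log-sd per axis class.
#' @param element_effect_scale Named multiplier on all group effects per
#'   element (default 1 everywhere); lowering an element's value weakens
#'   its group separation, e.g. to emulate the weakly discriminative
#'   metapodials.
#' @param missingness `"none"` or a scheme from [fragmentation_scheme()].
#' @param seed Integer seed; the same seed reproduces the assemblage
#'   byte-identically.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(registry = measurement_registry(),
                         n_per_group = 20,
                         delta = c(domestic_castrate = 0.075,
                                   domestic_male = 0.10,
                                   domestic_female = 0.00,
                                   wild_male = 0.02,
                                   wild_female = -0.03,
                                   fennicus_male = 0.14,
                                   fennicus_female = 0.045),
                         fennicus_gracility = 0.025,
                         female_gracility = 0.015,
                         castration_length_sparing = 0.25,
                         rho = 0.55,
                         sigma = c(length = 0.030, breadth = 0.055,
                                   depth = 0.055, circumference = 0.050,
                                   other = 0.055),
                         element_effect_scale = NULL,
                         missingness = "none",
                         seed = 1L) {
  groups <- canonical_groups()
  if (!setequal(names(delta), groups$label)) {
    stop("delta must be named by the 7 canonical group labels")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (castration_length_sparing < 0 || castration_length_sparing > 1) {
    stop("castration_length_sparing must lie in [0, 1]")
  }
  els <- osteo_elements()
  if (is.null(element_effect_scale)) {
    element_effect_scale <- stats::setNames(rep(1, length(els)), els)
  }
  baseline <- .default_baseline(registry)
  p <- structure(
    list(registry = registry, n_per_group = n_per_group,
         delta = delta[groups$label],
         fennicus_gracility = fennicus_gracility,
         female_gracility = female_gracility,
         castration_length_sparing = castration_length_sparing,
         rho = rho, sigma = sigma,
         element_effect_scale = element_effect_scale,
         baseline = baseline, missingness = missingness,
         seed = as.integer(seed)),
    class = "synth_params"
  )
  p
}

# round-magnitude baseline log-means (mm) per variable, by axis class and
# region; config, not biological claims -- lengths >> epiphysis breadths >>
# shaft dimensions, with element-specific length scales
.default_baseline <- function(registry) {
  len_scale <- c(humerus = log(215), radioulna = log(265),
                 metacarpus = log(195), femur = log(245), tibia = log(300),
                 metatarsus = log(235), pelvis = log(250))
  lm <- numeric(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    ax <- registry$axis_class[i]
    rg <- registry$region[i]
    lm[i] <- if (ax == "length") {
      len_scale[[registry$element[i]]]
    } else if (ax == "circumference") {
      log(80)
    } else if (rg == "shaft") {
      log(25)
    } else if (ax == "other") {
      log(35)
    } else {
      log(45)
    }
  }
  tibble::tibble(element = registry$element, code = registry$code,
                 log_mean = lm)
}

#' Per-group mean log-measurement vectors for one element
#'
#' The deterministic mean structure the generator samples around; exposed
#' so parameter-recovery tests can compare sample statistics against the
#' configured truth.
#'
#' @param params `synth_params`.
#' @param element Element name.
#' @return Matrix, 7 rows (canonical group labels) x element variables.
#' @export
synth_group_means <- function(params, element) {
  reg <- params$registry[params$registry$element == element, , drop = FALSE]
  base <- params$baseline$log_mean[params$baseline$element == element]
  groups <- canonical_groups()
  scale_e <- params$element_effect_scale[[element]]
  # gracility contrast: + length, - shaft, centered to zero sum
  u <- ifelse(reg$axis_class == "length", 1,
              ifelse(reg$region == "shaft", -1, 0))
  u <- u - mean(u)
  mu <- matrix(NA_real_, nrow = 7, ncol = nrow(reg),
               dimnames = list(groups$label, reg$code))
  for (g in seq_len(7)) {
    coef_g <- params$fennicus_gracility * (groups$ecotype[g] == "fennicus") +
      params$female_gracility * (groups$sex[g] == "female")
    mu[g, ] <- base + scale_e * (params$delta[[groups$label[g]]] + coef_g * u)
  }
  # castrate: intact-male mean minus an axis-class-targeted deficit whose
  # average equals the configured isometric-size gap
  s_v <- ifelse(reg$axis_class == "length", params$castration_length_sparing, 1)
  gap <- scale_e * (params$delta[["domestic_male"]] - params$delta[["domestic_castrate"]])
  D <- gap / mean(s_v)
  mu["domestic_castrate", ] <- mu["domestic_male", ] - D * s_v
  mu
}

#' Within-group covariance of log-measurements for one element
#'
#' Equicorrelation `rho` with per-variable log-sd by axis class.
#'
#' @inheritParams synth_group_means
#' @return Covariance matrix over the element's variables.
#' @export
synth_covariance <- function(params, element) {
  reg <- params$registry[params$registry$element == element, , drop = FALSE]
  sd_v <- params$sigma[reg$axis_class]
  p <- length(sd_v)
  R <- matrix(params$rho, p, p)
  diag(R) <- 1
  S <- diag(sd_v) %*% R %*% diag(sd_v)
  dimnames(S) <- list(reg$code, reg$code)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate covariance (not positive definite); lower rho")
  S
}

#' Simulate a synthetic bone assemblage
#'
#' Draws `n_per_group` specimens for each group x element from the
#' log-normal model described in [synth_params()]. A synthetic individual
#' spans all requested elements (same `individual_id` per group index), as
#' in skeletal collections. All labels are populated; castrates receive a
#' castration age drawn uniformly between 2 and 4 years.
#'
#' @param params `synth_params`.
#' @param elements Elements to simulate (default the six long bones).
#' @return Specimen tibble in the wide schema of [read_specimen_table()].
#'   The same `params$seed` yields an identical table.
#' @examples
#' tab <- simulate_assemblage(synth_params(n_per_group = 3, seed = 42))
#' dplyr::count(tab, element)
#' @export
simulate_assemblage <- function(params,
                                elements = setdiff(osteo_elements(), "pelvis")) {
  stopifnot(inherits(params, "synth_params"))
  groups <- canonical_groups()
  n <- params$n_per_group
  withr::with_seed(params$seed, {
    rows <- list()
    for (el in elements) {
      mu <- synth_group_means(params, el)
      S <- synth_covariance(params, el)
      L <- chol(S)
      p <- ncol(mu)
      for (g in seq_len(7)) {
        z <- matrix(stats::rnorm(n * p), n, p)
        logx <- z %*% L + matrix(mu[g, ], n, p, byrow = TRUE)
        vals <- exp(logx)
        colnames(vals) <- colnames(mu)
        lab <- groups$label[g]
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            individual_id = sprintf("%s_%03d", lab, seq_len(n)),
            element = el,
            side = "left",
            ecotype = groups$ecotype[g],
            variety = groups$variety[g],
            sex = groups$sex[g],
            castrated = groups$castrated[g],
            fusion_state = "fused",
            castration_age = if (groups$castrated[g]) {
              stats::runif(n, 2, 4)
            } else {
              NA_real_
            },
            collection_year = NA_integer_,
            locality = "synthetic"
          ),
          tibble::as_tibble(vals)
        )
      }
    }
    tab <- dplyr::bind_rows(rows)
  })
  if (!identical(params$missingness, "none")) {
    tab <- apply_fragmentation(tab, params$missingness,
                               seed = params$seed + 1L,
                               registry = params$registry)
  }
  tab
}

#' Region-atomic fragmentation scheme
#'
#' Models marrow-extraction breakage: with probability `p` a record is
#' fragmented, surviving as exactly one bone region -- only that region's
#' measurement codes remain, everything else (including whole-bone
#' lengths) is lost. The surviving region is drawn uniformly from
#' `regions`.
#'
#' @param p Fragmentation probability per record, in \[0,1\].
#' @param regions Candidate surviving regions.
#' @return An object of class `fragmentation_scheme`.
#' @export
fragmentation_scheme <- function(p, regions = c("proximal", "distal", "shaft")) {
  stopifnot(p >= 0, p <= 1, all(regions %in% osteo_regions()))
  structure(list(p = p, regions = regions), class = "fragmentation_scheme")
}

#' Apply a fragmentation scheme to a specimen table
#'
#' @param tab Specimen tibble.
#' @param scheme A [fragmentation_scheme()].
#' @param seed Integer seed making the fragmentation decisions reproducible.
#' @param registry Measurement registry (region lookup).
#' @return The table with non-surviving measurements set to absent.
#' @export
apply_fragmentation <- function(tab, scheme, seed,
                                registry = measurement_registry()) {
  stopifnot(inherits(scheme, "fragmentation_scheme"))
  if (scheme$p == 0) return(tab)
  codes <- intersect(names(tab), unique(registry$code))
  withr::with_seed(as.integer(seed), {
    frag <- stats::runif(nrow(tab)) < scheme$p
    pick <- sample(scheme$regions, nrow(tab), replace = TRUE)
  })
  for (i in which(frag)) {
    keep <- registry$code[registry$element == tab$element[i] &
                            registry$region == pick[i]]
    lose <- setdiff(codes, keep)
    tab[i, lose] <- NA_real_
  }
  tab
}

#' @export
print.synth_params <- function(x, ...) {
  cat("synth_params: n_per_group =", x$n_per_group,
      "| rho =", x$rho, "| seed =", x$seed, "\n")
  cat("delta (log-size):",
      paste(names(x$delta), round(x$delta, 3), sep = "=", collapse = ", "), "\n")
  cat("castration_length_sparing =", x$castration_length_sparing, "\n")
  invisible(x)
}
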