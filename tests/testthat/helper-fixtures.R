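# Shared fixtures: tiny hand-built specimen tables and tuned-down
# generator configurations used across the test files.

# a minimal valid specimen row; override any field via ...
spec_row <- function(individual_id = "id1", element = "femur", side = "left",
                     ecotype = "tarandus", variety = "domestic", sex = "male",
                     castrated = FALSE, fusion_state = "fused",
                     castration_age = NA_real_, ...) {
  tibble::tibble(
    individual_id = individual_id, element = element, side = side,
    ecotype = ecotype, variety = variety, sex = sex, castrated = castrated,
    fusion_state = fusion_state, castration_age = castration_age,
    collection_year = NA_integer_, locality = "fixture", ...
  )
}

# a three-class, clean-Gaussian generator configuration: one group per
# ecotype/variety class (the female groups), no shape contrasts, class
# gaps set to `gap_sd` pooled standard deviations of isometric size
three_class_params <- function(n_per_group, gap_sd = 4, seed = 1L,
                               element = "femur") {
  p0 <- synth_params(seed = seed)
  S <- synth_covariance(p0, element)
  sd_isize <- sqrt(sum(S) / ncol(S)^2)
  gap <- gap_sd * sd_isize
  synth_params(
    n_per_group = n_per_group,
    delta = c(domestic_castrate = 0, domestic_male = 0, domestic_female = 0,
              wild_male = gap, wild_female = gap,
              fennicus_male = 2 * gap, fennicus_female = 2 * gap),
    fennicus_gracility = 0, female_gracility = 0,
    castration_length_sparing = 1,
    seed = seed
  )
}

# the three single-group class table drawn from three_class_params
three_class_table <- function(n_per_group, gap_sd = 4, seed = 1L,
                              element = "femur") {
  tab <- simulate_assemblage(
    three_class_params(n_per_group, gap_sd, seed, element),
    elements = element
  )
  keep <- c("domestic_female", "wild_female", "fennicus_female")
  tab <- osteorda::assign_groups(tab)
  tab[tab$group_label %in% keep, , drop = FALSE]
}

# split + tune + fit + held-out evaluation for a labelled feature set;
# returns test balanced accuracy (percent)
holdout_balanced_accuracy <- function(x, class, seed,
                                      grid = default_rda_grid(), k = 10) {
  plan <- suppressWarnings(stratified_split(class, 0.2, seed = seed))
  tuned <- suppressWarnings(
    tune_rda(x[plan$train, , drop = FALSE], class[plan$train],
             grid = grid, k = k, seed = seed + 1L)
  )
  fit <- fit_rda(x[plan$train, , drop = FALSE], class[plan$train],
                 lambda = tuned$lambda, gamma = tuned$gamma)
  pred <- predict_rda(fit, x[plan$test, , drop = FALSE])
  cm <- confusion_matrix(class[plan$test], pred$labels,
                         classes = sort(unique(class)))
  classification_metrics(cm)$balanced_accuracy
}
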