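test_that("packaged registry enumerates 99 definitions with valid structure", {
  reg <- measurement_registry()
  expect_equal(nrow(reg), 99)
  expect_setequal(unique(reg$element), osteo_elements())
  expect_false(any(duplicated(reg[, c("element", "code")])))
  # whole-bone region is reserved for length measurements
  expect_true(all(reg$axis_class[reg$region == "whole"] == "length"))
  expect_true(all(reg$canonical_unit == "mm"))
})

test_that("group taxonomy enumerates exactly 7 canonical groups with invariants", {
  g <- canonical_groups()
  expect_equal(g$group, 1:7)
  expect_true(all(g$variety[g$ecotype == "fennicus"] == "not_applicable"))
  cas <- g[g$castrated, ]
  expect_true(all(cas$sex == "male" & cas$variety == "domestic"))
  # invalid combinations are rejected
  expect_error(validate_group_labels(spec_row(ecotype = "fennicus", variety = "wild")),
               "not_applicable")
  expect_error(validate_group_labels(spec_row(castrated = TRUE, sex = "female")),
               "domestic males")
})

test_that("loader applies per-column unit policy and preserves row order", {
  tab <- dplyr::bind_rows(
    spec_row("a", GL = 25.0, SD = 22),
    spec_row("b", GL = 24.0, SD = 21),
    spec_row("c", GL = 26.0, SD = 23)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  got <- read_specimen_table(path, unit_policy = c(GL = "cm"))
  expect_equal(got$GL, c(250, 240, 260))
  expect_equal(got$SD, c(22, 21, 23))
  expect_equal(got$individual_id, c("a", "b", "c"))
})

test_that("nonpositive measurements are rejected naming the row and code", {
  tab <- dplyr::bind_rows(spec_row("a", SD = 22), spec_row("b", SD = -1))
  expect_error(validate_specimen_table(tab), "row 2.*SD")
  # codes placed on the wrong element are reported too
  bad <- spec_row("a", element = "femur", BT = 30) # BT is a humerus code
  expect_error(validate_specimen_table(bad), "BT not defined")
})

test_that("unknown columns are reported, not silently dropped", {
  tab <- spec_row("a", GL = 250)
  tab$mystery <- 1
  expect_warning(out <- as_specimen_table(tab), "mystery")
  expect_true("mystery" %in% names(out))
  expect_equal(attr(out, "unknown_columns"), "mystery")
})

test_that("a synthetic table round-trips through write and read unchanged", {
  tab <- simulate_assemblage(synth_params(n_per_group = 3, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_specimen_table(tab, path)
  got <- read_specimen_table(path)
  codes <- intersect(names(tab), measurement_registry()$code)
  expect_equal(as.data.frame(got[, codes]), as.data.frame(tab[, codes]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$individual_id, tab$individual_id)
  expect_equal(got$castrated, tab$castrated)
})

test_that("inclusion rules follow fusion and castration-age policy", {
  tab <- dplyr::bind_rows(
    spec_row("young_cut", castrated = TRUE, castration_age = 3.0),
    spec_row("late_cut", castrated = TRUE, castration_age = 5.0),
    spec_row("at_cutoff", castrated = TRUE, castration_age = 4.5),
    spec_row("old_intact", castration_age = NA_real_),
    spec_row("unfused", fusion_state = "unfused"),
    spec_row("fusion_na", fusion_state = "unknown")
  )
  res <- apply_inclusion_rules(tab)
  expect_setequal(res$kept$individual_id, c("young_cut", "old_intact"))
  expect_setequal(res$exclusions$reason,
                  c("castration_age", "unfused", "fusion_unknown"))
  # cutoff is strict: castration at exactly 4.5 y is excluded
  expect_true("at_cutoff" %in% res$exclusions$individual_id)
  # unknown fusion kept only under the permissive policy
  res2 <- apply_inclusion_rules(tab, allow_unknown_fusion = TRUE)
  expect_true("fusion_na" %in% res2$kept$individual_id)
  # intact animals are never touched by the age rule
  expect_false("old_intact" %in% res$exclusions$individual_id)
})

test_that("inclusion rules are idempotent", {
  tab <- simulate_assemblage(synth_params(n_per_group = 5, seed = 2))
  once <- apply_inclusion_rules(tab)
  twice <- apply_inclusion_rules(once$kept)
  expect_equal(as.data.frame(twice$kept), as.data.frame(once$kept))
  expect_equal(nrow(twice$exclusions), 0)
})

test_that("side dedup keeps the more complete side, ties to left", {
  tab <- dplyr::bind_rows(
    spec_row("x", side = "left", GL = 250, SD = 22),
    spec_row("x", side = "right", GL = 251, SD = 22.5, Bd = 45), # more complete
    spec_row("y", side = "left", GL = 240, SD = 21),
    spec_row("y", side = "right", GL = 241, SD = 21.5),          # tie -> left
    spec_row("z", side = "right", GL = 260)                      # singleton kept
  )
  out <- dedupe_sides(tab)
  expect_equal(nrow(out), 3)
  expect_equal(out$side[out$individual_id == "x"], "right")
  expect_equal(out$side[out$individual_id == "y"], "left")
  expect_true("z" %in% out$individual_id)
  # left_first preference overrides completeness
  out2 <- dedupe_sides(tab, preference = "left_first")
  expect_equal(out2$side[out2$individual_id == "x"], "left")
})

test_that("dedup leaves no duplicated (individual, element) pairs on random tables", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- 40
      tab <- spec_row(
        individual_id = sample(paste0("ind", 1:12), n, replace = TRUE),
        element = sample(c("femur", "tibia"), n, replace = TRUE),
        side = sample(c("left", "right"), n, replace = TRUE),
        GL = stats::runif(n, 200, 300)
      )
      out <- dedupe_sides(tab)
      expect_false(any(duplicated(out[, c("individual_id", "element")])))
    }
  })
})

test_that("select_matrix keeps complete cases in registry order", {
  p <- synth_params(n_per_group = 10, seed = 5)
  tab <- simulate_assemblage(p, elements = "humerus")
  # proximal humerus subset excludes GL and all distal/shaft codes
  m <- select_matrix(tab, "humerus", "proximal")
  reg <- measurement_registry()
  prox <- reg$code[reg$element == "humerus" & reg$region == "proximal"]
  expect_equal(m$codes, prox)
  expect_false(any(c("GL", "SD", "Bd") %in% m$codes))
  expect_false(anyNA(m$x))
  # knocking out one shaft code in 4 specimens drops exactly those rows
  tab2 <- tab
  tab2$CD[c(3, 10, 20, 33)] <- NA
  m2 <- select_matrix(tab2, "humerus", "shaft")
  expect_equal(nrow(m2$x), nrow(tab) - 4)
  expect_equal(length(m2$dropped), 4)
  # variable order equals registry order for every subset
  for (sb in c("all", "proximal", "distal", "shaft", "complete_reduced")) {
    ms <- select_matrix(tab, "humerus", sb)
    expect_equal(ms$codes, intersect(reg$code[reg$element == "humerus"], ms$codes))
    expect_false(anyNA(ms$x))
  }
})

test_that("select_matrix honours explicit override lists and fails informatively", {
  tab <- simulate_assemblage(synth_params(n_per_group = 4, seed = 6),
                             elements = "femur")
  m <- select_matrix(tab, "femur", override = c("GL", "SD", "Bd"))
  expect_equal(m$codes, c("GL", "SD", "Bd"))
  expect_error(select_matrix(tab, "femur", override = c("GL", "NOPE")), "NOPE")
  expect_error(select_matrix(tab, "femur", override = c("GL")), "fewer than 2")
  tab$GL <- NA_real_
  expect_error(select_matrix(tab, "femur", override = c("GL", "SD")),
               "no specimen")
})
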