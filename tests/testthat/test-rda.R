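test_that("stratified split allocates round-half-up test shares per stratum", {
  strata <- rep(c("A", "B"), each = 5)
  plan <- stratified_split(strata, test_fraction = 0.2, seed = 1)
  expect_equal(length(plan$train), 8)
  expect_equal(length(plan$test), 2)
  expect_equal(sum(strata[plan$test] == "A"), 1)
  expect_equal(sum(strata[plan$test] == "B"), 1)
  # disjoint and exhaustive
  expect_equal(sort(c(plan$train, plan$test)), 1:10)
  # identical seed, identical plan
  plan2 <- stratified_split(strata, test_fraction = 0.2, seed = 1)
  expect_identical(plan, plan2)
  # tiny strata go to train with a warning
  expect_warning(p3 <- stratified_split(c(strata, "C", "C"), seed = 2), "train")
  expect_true(all(which(c(strata, "C", "C") == "C") %in% p3$train))
})

test_that("empirical test fraction concentrates on the target", {
  strata <- rep(c("A", "B", "C"), times = c(40, 25, 35))
  fracs <- vapply(1:1000, function(s) {
    length(stratified_split(strata, 0.2, seed = s)$test) / length(strata)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), 0.02)
})

test_that("regularization limits recover LDA, QDA, and spherical forms", {
  withr::with_seed(61, {
    x <- rbind(matrix(stats::rnorm(60, 0), 30),
               matrix(stats::rnorm(60, 2), 30))
    y <- rep(c("a", "b"), each = 30)
  })
  # lambda = 1: both class covariances equal the pooled estimate
  m_lda <- fit_rda(x, y, lambda = 1, gamma = 0)
  expect_equal(m_lda$reg_covariances$a, m_lda$pooled)
  expect_equal(m_lda$reg_covariances$b, m_lda$pooled)
  # lambda = 0, gamma = 0: per-class sample covariances
  m_qda <- fit_rda(x, y, lambda = 0, gamma = 0)
  expect_equal(m_qda$reg_covariances$a, stats::cov(x[y == "a", ]))
  # gamma = 1: scalar multiples of the identity
  m_sph <- fit_rda(x, y, lambda = 0.5, gamma = 1)
  S <- m_sph$reg_covariances$a
  expect_equal(S, diag(S[1, 1], ncol(x)))
})

test_that("1-D two-class prediction has its boundary at the midpoint", {
  withr::with_seed(62, {
    x <- matrix(c(stats::rnorm(200, 0), stats::rnorm(200, 2)), ncol = 1)
    y <- rep(c("one", "two"), each = 200)
  })
  m <- fit_rda(x, y, lambda = 1, gamma = 0, priors = "uniform")
  # empirical means are close to 0 and 2; decision flips near 1
  pred <- predict_rda(m, matrix(c(0.8, 1.2), ncol = 1))
  expect_equal(pred$labels, c("one", "two"))
})

test_that("posteriors sum to one and labels survive score translation", {
  withr::with_seed(63, {
    x <- matrix(stats::rnorm(300), 100, 3)
    y <- sample(c("a", "b", "c"), 100, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  })
  m <- fit_rda(x, y, lambda = 0.5, gamma = 0.25)
  pred <- predict_rda(m, x)
  expect_equal(rowSums(pred$posterior), rep(1, 100), tolerance = 1e-8)
  # adding any constant to all scores changes no decision
  shifted <- pred$scores + 123.456
  expect_equal(m$classes[apply(shifted, 1, which.max)], pred$labels)
  # scaling all unnormalized prior weights equally changes no decision
  m2 <- fit_rda(x, y, lambda = 0.5, gamma = 0.25,
                priors = c(a = 1.5, b = 0.9, c = 0.6)) # 3x the empirical-ish
  m3 <- fit_rda(x, y, lambda = 0.5, gamma = 0.25,
                priors = c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(predict_rda(m2, x)$labels, predict_rda(m3, x)$labels)
})

test_that("predictions match brute-force Gaussian density evaluation", {
  skip_if_not_installed("mvtnorm")
  withr::with_seed(64, {
    for (rep in 1:5) {
      p <- 4
      x <- rbind(matrix(stats::rnorm(40 * p, 0), ncol = p),
                 matrix(stats::rnorm(40 * p, 1), ncol = p),
                 matrix(stats::rnorm(40 * p, 2), ncol = p))
      y <- rep(c("a", "b", "c"), each = 40)
      lam <- stats::runif(1)
      gam <- stats::runif(1, 0, 0.5)
      m <- fit_rda(x, y, lambda = lam, gamma = gam)
      new_x <- matrix(stats::rnorm(20 * p, 1), ncol = p)
      pred <- predict_rda(m, new_x)
      # oracle: prior times Gaussian density with the model's covariances
      dens <- sapply(m$classes, function(k) {
        m$priors[[k]] * mvtnorm::dmvnorm(new_x, mean = m$means[[k]],
                                         sigma = m$reg_covariances[[k]])
      })
      expect_equal(pred$labels, m$classes[apply(dens, 1, which.max)])
      expect_equal(pred$posterior, dens / rowSums(dens),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("the LDA limit matches an independent closed-form discriminant", {
  withr::with_seed(65, {
    for (rep in 1:20) {
      p <- sample(2:4, 1)
      K <- sample(2:3, 1)
      n_k <- 15
      x <- do.call(rbind, lapply(seq_len(K), function(k) {
        matrix(stats::rnorm(n_k * p, mean = k), ncol = p)
      }))
      y <- rep(letters[1:K], each = n_k)
      m <- fit_rda(x, y, lambda = 1, gamma = 0)
      pred <- predict_rda(m, x)
      # oracle: linear scores x'W mu - 0.5 mu'W mu + log pi, W = pooled^-1
      W <- solve(m$pooled)
      lin <- sapply(m$classes, function(k) {
        mu <- m$means[[k]]
        drop(x %*% W %*% mu) - 0.5 * drop(t(mu) %*% W %*% mu) +
          log(m$priors[[k]])
      })
      expect_equal(pred$labels, m$classes[apply(lin, 1, which.max)])
    }
  })
})

test_that("translating all features leaves predictions unchanged", {
  withr::with_seed(66, {
    x <- rbind(matrix(stats::rnorm(90, 0), ncol = 3),
               matrix(stats::rnorm(90, 1.5), ncol = 3))
    y <- rep(c("a", "b"), each = 30)
    shift <- c(100, -50, 7)
  })
  x_shift <- sweep(x, 2, shift, `+`)
  m1 <- fit_rda(x, y, lambda = 0.3, gamma = 0.1)
  m2 <- fit_rda(x_shift, y, lambda = 0.3, gamma = 0.1)
  expect_equal(predict_rda(m1, x)$labels,
               predict_rda(m2, x_shift)$labels)
})

test_that("singular covariances fail with actionable advice", {
  x <- cbind(1:20, (1:20) * 2) # perfectly collinear features
  y <- rep(c("a", "b"), 10)
  expect_error(fit_rda(x, y, lambda = 0, gamma = 0), "gamma")
  # and gamma > 0 indeed rescues the fit
  expect_s3_class(fit_rda(x, y, lambda = 0, gamma = 0.5), "rda_model")
})

test_that("tuning is deterministic, handles degenerate grids, ties to regularization", {
  withr::with_seed(67, {
    x <- rbind(matrix(stats::rnorm(100, 0), ncol = 2),
               matrix(stats::rnorm(100, 8), ncol = 2))
    y <- rep(c("a", "b"), each = 50)
  })
  one <- tune_rda(x, y, grid = data.frame(lambda = 1, gamma = 0), seed = 5)
  expect_equal(c(one$lambda, one$gamma), c(1, 0))
  t1 <- tune_rda(x, y, seed = 9)
  t2 <- tune_rda(x, y, seed = 9)
  expect_identical(t1$cv_table, t2$cv_table)
  # clean separation: every grid point is perfect, tie broken to (1, 1)
  expect_equal(c(t1$lambda, t1$gamma), c(1, 1))
  expect_warning(tune_rda(x[c(1:5, 51:55), ], y[c(1:5, 51:55)], k = 10,
                          grid = data.frame(lambda = 1, gamma = 0)),
                 "reduced")
  expect_error(tune_rda(x, y, grid = data.frame(lambda = numeric(0),
                                                gamma = numeric(0))),
               "empty")
})

test_that("tuning prefers pooling when classes truly share a covariance", {
  picks <- vapply(1:50, function(s) {
    withr::with_seed(1000 + s, {
      p <- 4
      x <- do.call(rbind, lapply(0:2, function(k) {
        matrix(stats::rnorm(20 * p, mean = k * 0.8), ncol = p)
      }))
      y <- rep(c("a", "b", "c"), each = 20)
    })
    tune_rda(x, y, seed = s)$lambda
  }, numeric(1))
  expect_gte(mean(picks >= 0.5), 0.8)
})

test_that("well-separated groups are recovered on held-out data", {
  # two synthetic groups 4 pooled SDs apart in iSize
  bas <- vapply(1:20, function(s) {
    tab <- three_class_table(40, gap_sd = 4, seed = 100 + s)
    tab <- tab[tab$group_label != "wild_female", , drop = FALSE]
    f <- size_shape_features(select_matrix(tab, "femur", "all"))
    holdout_balanced_accuracy(f$features, f$specimens$group_label, seed = s)
  }, numeric(1))
  expect_gte(stats::median(bas), 95)
})

test_that("model serialization carries the full parameterization", {
  withr::with_seed(68, {
    x <- rbind(matrix(stats::rnorm(40), ncol = 2),
               matrix(stats::rnorm(40, 2), ncol = 2))
    y <- rep(c("a", "b"), each = 20)
  })
  m <- fit_rda(x, y, lambda = 0.25, gamma = 0.1)
  lst <- rda_model_to_list(m)
  expect_equal(lst$lambda, 0.25)
  expect_equal(names(lst$means), c("a", "b"))
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(txt)
  expect_equal(back$means$a, unname(m$means$a))
})
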