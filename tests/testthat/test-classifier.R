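sep_data <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- tibble::tibble(
      stride_length = c(runif(n / 2, 0.9, 1.4), runif(n / 2, 0.05, 0.3)),
      max_pitch = c(runif(n / 2, 15, 25), runif(n / 2, 2, 6))
    )
    list(x = x, y = rep(c("normal", "fog"), each = n / 2))
  })
}

test_that("perfectly separated data trains to 100% accuracy", {
  d <- sep_data()
  model <- fog_train(d$x, d$y)
  pred <- predict(model, d$x)
  expect_equal(pred$label, d$y)
  expect_s3_class(tidy(model), "tbl_df")
  expect_equal(glance(model)$n_features, 2)
})

test_that("degenerate training inputs are rejected", {
  d <- sep_data()
  expect_error(
    fog_train(d$x, rep("fog", nrow(d$x))),
    class = "gaitcue_validation_error"
  )
  expect_error(
    fog_train(d$x, rep(c("fog", "bad"), nrow(d$x) / 2)),
    class = "gaitcue_validation_error"
  )
})

test_that("training is deterministic and survives JSON round-trip", {
  d <- sep_data(seed = 5)
  cfg <- classifier_config(n_estimators = 5, seed = 42)
  m1 <- fog_train(d$x, d$y, cfg)
  m2 <- fog_train(d$x, d$y, cfg)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fog_model(m1, p1)
  write_fog_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_fog_model(p1)
  expect_equal(predict(back, d$x), predict(m1, d$x))
})

test_that("a hand-built stump votes as specified", {
  stump_model <- structure(
    list(
      trees = list(list(
        feature = 1, threshold = 0.5,
        left = list(leaf = "fog"), right = list(leaf = "normal")
      )),
      alphas = 2.0,
      feature_names = "stride_length",
      config = list(decision_threshold = 0.5, max_tree_depth = 1)
    ),
    class = "fog_adaboost"
  )
  pred <- predict(stump_model, tibble::tibble(stride_length = 0.3))
  expect_equal(pred$label, "fog")
  expect_equal(pred$score, 1.0)
  expect_equal(
    predict(stump_model, tibble::tibble(stride_length = 0.8))$score, 0
  )
  # identical input, identical output
  expect_equal(
    predict(stump_model, tibble::tibble(stride_length = 0.3)),
    predict(stump_model, tibble::tibble(stride_length = 0.3))
  )
  expect_error(
    predict(stump_model, tibble::tibble(max_pitch = 1)),
    class = "gaitcue_validation_error"
  )
})

test_that("a three-stump ensemble reproduces the hand-computed weighted vote", {
  model <- structure(
    list(
      trees = list(
        list(
          feature = 1, threshold = 0.5,
          left = list(leaf = "fog"), right = list(leaf = "normal")
        ),
        list(
          feature = 2, threshold = 10,
          left = list(leaf = "fog"), right = list(leaf = "normal")
        ),
        list(
          feature = 1, threshold = 1.0,
          left = list(leaf = "normal"), right = list(leaf = "fog")
        )
      ),
      alphas = c(1.2, 0.7, 0.4),
      feature_names = c("stride_length", "max_pitch"),
      config = list(decision_threshold = 0.5, max_tree_depth = 1)
    ),
    class = "fog_adaboost"
  )
  fv <- tibble::tibble(stride_length = 0.3, max_pitch = 12)
  # stump votes: fog (1.2), normal (0.7), normal (0.4)
  expected <- 1.2 / (1.2 + 0.7 + 0.4)
  pred <- predict(model, fv)
  expect_equal(pred$score, expected)
  expect_equal(pred$label, "fog")
})

test_that("tiny-instance boosting equals the exhaustive stump recursion", {
  cfg <- classifier_config(n_estimators = 2, max_tree_depth = 1)
  for (seed in 1:12) {
    d <- withr::with_seed(seed, {
      n <- sample(4:8, 1)
      x <- matrix(round(runif(n * 2), 2), n, 2)
      y <- ifelse(x[, 1] > median(x[, 1]), "fog", "normal")
      flip <- sample(n, 1)
      y[flip] <- setdiff(c("fog", "normal"), y[flip])
      list(x = x, y = y)
    })
    xdf <- tibble::as_tibble(as.data.frame(d$x))
    pkg <- tryCatch(
      fog_train(xdf, d$y, cfg),
      gaitcue_validation_error = function(e) NULL
    )
    ora <- oracle_adaboost(d$x, d$y, 2)
    if (is.null(pkg)) {
      expect_equal(length(ora$alphas), 0)
      next
    }
    expect_equal(pkg$alphas, ora$alphas, tolerance = 1e-10)
    grid <- matrix(runif(40), 20, 2)
    grid_df <- tibble::as_tibble(as.data.frame(grid))
    names(grid_df) <- pkg$feature_names
    expect_equal(
      predict(pkg, grid_df)$label,
      oracle_adaboost_predict(ora, grid)$label
    )
  }
})

test_that("raising the decision threshold trades sensitivity for specificity", {
  d <- withr::with_seed(3, {
    n <- 200
    x <- tibble::tibble(
      stride_length = c(rnorm(n / 2, 1.1, 0.3), rnorm(n / 2, 0.5, 0.3))
    )
    list(x = x, y = rep(c("normal", "fog"), each = n / 2))
  })
  model <- fog_train(d$x, d$y)
  score <- predict(model, d$x)$score
  prev_sens <- Inf
  prev_spec <- -Inf
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    lab <- ifelse(score > thr, "fog", "normal")
    sens <- sum(lab == "fog" & d$y == "fog") / sum(d$y == "fog")
    spec <- sum(lab == "normal" & d$y == "normal") / sum(d$y == "normal")
    expect_lte(sens, prev_sens)
    expect_gte(spec, prev_spec)
    prev_sens <- sens
    prev_spec <- spec
  }
})

test_that("LOSO on two identical separable subjects is perfect", {
  d <- sep_data(n = 20, seed = 9)
  data <- dplyr::bind_rows(
    dplyr::mutate(d$x, subject = "A", label = d$y),
    dplyr::mutate(d$x, subject = "B", label = d$y)
  )
  cv <- loso_cv(data)
  expect_equal(cv$folds$accuracy, c(100, 100))
  expect_equal(glance(cv)$auc_mean, 100)
  # aggregate accuracy equals the recomputed summed-confusion accuracy
  cm <- cv$confusion
  expect_equal(
    cv$total[["accuracy"]],
    100 * (cm[["tp"]] + cm[["tn"]]) / sum(cm)
  )
  expect_error(
    loso_cv(dplyr::filter(data, subject == "A")),
    class = "gaitcue_validation_error"
  )
})

test_that("labels independent of features give chance-level held-out AUC", {
  d <- withr::with_seed(31, {
    x <- tibble::tibble(
      stride_length = runif(500), max_pitch = runif(500)
    )
    list(
      x = x,
      y = sample(c("fog", "normal"), 500, replace = TRUE),
      subj = sample(sprintf("S%d", 1:10), 500, replace = TRUE)
    )
  })
  cv <- loso_cv(
    dplyr::mutate(d$x, subject = d$subj, label = d$y)
  )
  expect_gt(glance(cv)$auc_mean, 40)
  expect_lt(glance(cv)$auc_mean, 60)
})
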