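# Discrete (SAMME) AdaBoost over shallow decision trees.
#
# The weak learner is a weighted CART-style tree on numeric features:
# exhaustive search over midpoint thresholds, weighted Gini impurity,
# deterministic tie-breaking (lower feature index, then smaller threshold),
# depth capped at the configured maximum. Trees and their weights serialize
# to plain JSON so a trained model is a portable text artifact.

CLASS_LEVELS <- c("normal", "fog")

weighted_gini <- function(w_pos, w_neg) {
  tot <- w_pos + w_neg
  ifelse(tot > 0, tot * (1 - (w_pos / tot)^2 - (w_neg / tot)^2), 0)
}

# Best split of one node; returns NULL if no split improves purity.
best_split <- function(x, y_pos, w) {
  n <- length(y_pos)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]
    wp <- cumsum(w[o] * y_pos[o])
    wn <- cumsum(w[o] * !y_pos[o])
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0L) {
      next
    }
    g <- weighted_gini(wp[distinct], wn[distinct]) +
      weighted_gini(wp[n] - wp[distinct], wn[n] - wn[distinct])
    b <- which.min(g) # earliest index wins ties -> smallest threshold
    cand <- list(
      feature = j,
      threshold = (xs[distinct[b]] + xs[distinct[b] + 1L]) / 2,
      gini = g[b]
    )
    if (is.null(best) || cand$gini < best$gini - 1e-12) {
      best <- cand
    }
  }
  best
}

leaf_label <- function(y_pos, w) {
  w_pos <- sum(w[y_pos])
  w_neg <- sum(w[!y_pos])
  # deterministic tie-break: "normal" (the majority/background class)
  if (w_pos > w_neg) "fog" else "normal"
}

fit_tree <- function(x, y_pos, w, depth) {
  if (depth == 0L || all(y_pos) || !any(y_pos)) {
    return(list(leaf = leaf_label(y_pos, w)))
  }
  sp <- best_split(x, y_pos, w)
  if (is.null(sp)) {
    return(list(leaf = leaf_label(y_pos, w)))
  }
  left <- x[, sp$feature] <= sp$threshold
  parent_gini <- weighted_gini(sum(w[y_pos]), sum(w[!y_pos]))
  if (sp$gini >= parent_gini - 1e-12) {
    return(list(leaf = leaf_label(y_pos, w)))
  }
  list(
    feature = sp$feature, threshold = sp$threshold,
    left = fit_tree(
      x[left, , drop = FALSE], y_pos[left], w[left], depth - 1L
    ),
    right = fit_tree(
      x[!left, , drop = FALSE], y_pos[!left], w[!left], depth - 1L
    )
  )
}

predict_tree <- function(tree, x) {
  n <- nrow(x)
  out <- character(n)
  recurse <- function(node, idx) {
    if (!is.null(node$leaf)) {
      out[idx] <<- node$leaf
      return(invisible(NULL))
    }
    go_left <- x[idx, node$feature] <= node$threshold
    if (any(go_left)) {
      recurse(node$left, idx[go_left])
    }
    if (any(!go_left)) {
      recurse(node$right, idx[!go_left])
    }
  }
  if (n > 0L) {
    recurse(tree, seq_len(n))
  }
  out
}

#' Train the motion-phase FoG classifier
#'
#' Fits a discrete SAMME AdaBoost ensemble of depth-limited decision trees
#' (by default ten estimators of depth at most three) that classifies motion
#' phases as `"normal"` or `"fog"`. Rows with missing feature values are
#' dropped with a warning. Training is deterministic for a given input and
#' configuration.
#'
#' @param features data frame of numeric feature columns (any columns named
#'   `start`, `end` or `degraded` are ignored).
#' @param labels character vector of `"normal"` / `"fog"`, one per row.
#' @param config a [classifier_config()].
#' @return an object of class `fog_adaboost`.
#' @export
fog_train <- function(features, labels, config = classifier_config()) {
  features <- tibble::as_tibble(features)
  features <- features[setdiff(
    names(features), c("start", "end", "degraded")
  )]
  if (!all(labels %in% CLASS_LEVELS)) {
    stop_invalid("labels must be 'normal' or 'fog'")
  }
  if (length(unique(labels)) < 2L) {
    stop_invalid("training data must contain both classes")
  }
  x <- as.matrix(features)
  if (!is.numeric(x)) {
    stop_invalid("all feature columns must be numeric")
  }
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning(sum(!keep), " rows with missing features dropped")
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  y_pos <- labels == "fog"
  n <- nrow(x)
  w <- rep(1 / n, n)
  if (config$balance_classes) {
    w[y_pos] <- 0.5 / sum(y_pos)
    w[!y_pos] <- 0.5 / sum(!y_pos)
  }
  trees <- list()
  alphas <- numeric()
  for (m in seq_len(config$n_estimators)) {
    tree <- fit_tree(x, y_pos, w, config$max_tree_depth)
    pred <- predict_tree(tree, x)
    mis <- pred != labels
    err <- sum(w[mis]) / sum(w)
    if (err <= 0) {
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, log((1 - 1e-10) / 1e-10))
      break # perfect learner dominates; further rounds are redundant
    }
    if (err >= 0.5) {
      break # weak learner no better than chance; stop boosting
    }
    alpha <- log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  if (length(trees) == 0L) {
    stop_invalid("boosting failed: first weak learner was not better than chance")
  }
  structure(
    list(
      trees = trees, alphas = alphas,
      feature_names = colnames(features), config = unclass(config)
    ),
    class = "fog_adaboost"
  )
}

#' Classify motion phases
#'
#' The ensemble score is the alpha-weighted vote share for the `"fog"`
#' class; the label is `"fog"` when the score exceeds the decision
#' threshold.
#'
#' @param object a `fog_adaboost` model.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return a tibble with columns `label` and `score`.
#' @export
predict.fog_adaboost <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0L) {
    stop_invalid(
      "feature schema mismatch; missing: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  x <- as.matrix(newdata[object$feature_names])
  total <- sum(object$alphas)
  score <- rep(0, nrow(x))
  for (m in seq_along(object$trees)) {
    score <- score +
      object$alphas[m] * (predict_tree(object$trees[[m]], x) == "fog")
  }
  score <- if (total > 0) score / total else rep(0.5, nrow(x))
  tibble::tibble(
    label = ifelse(
      score > object$config$decision_threshold, "fog", "normal"
    ),
    score = score
  )
}

#' @export
print.fog_adaboost <- function(x, ...) {
  cat(sprintf(
    "<fog_adaboost> %d trees (max depth %d), features: %s\n",
    length(x$trees), x$config$max_tree_depth,
    paste(x$feature_names, collapse = ", ")
  ))
  invisible(x)
}

#' Serialize a trained classifier to JSON
#'
#' @param model a `fog_adaboost`.
#' @param path file path.
#' @return `read_fog_model()` returns the reconstructed model.
#' @export
write_fog_model <- function(model, path) {
  doc <- list(
    schema = "gaitcue/model/1",
    feature_names = model$feature_names,
    alphas = model$alphas,
    trees = model$trees,
    config = model$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fog_model
#' @export
read_fog_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$schema, "gaitcue/model/1")) {
    stop_invalid("unrecognized model schema in ", path)
  }
  structure(
    list(
      trees = doc$trees, alphas = as.numeric(doc$alphas),
      feature_names = doc$feature_names,
      config = doc$config
    ),
    class = "fog_adaboost"
  )
}

#' A constant classifier stub
#'
#' Always predicts the given label; useful for exercising the cueing
#' pipeline independently of a trained model.
#'
#' @param label `"fog"` or `"normal"`.
#' @return an object usable wherever a trained model is expected.
#' @export
constant_classifier <- function(label = "fog") {
  if (!label %in% CLASS_LEVELS) {
    stop_invalid("label must be 'normal' or 'fog'")
  }
  structure(list(label = label), class = "constant_classifier")
}

#' @export
predict.constant_classifier <- function(object, newdata, ...) {
  n <- nrow(newdata)
  tibble::tibble(
    label = rep(object$label, n),
    score = rep(as.numeric(object$label == "fog"), n)
  )
}
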