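# Trained predictors: a multinomial (softmax) regression of genotype class on
# per-probe X, Y and X*Y intensity terms with the heterozygote as reference
# class (the "MRM"), and a classification tree grown by best Gini splits with
# a minimum node size of five (the "CART"). Both are authored here rather than
# delegated so their exact parameterisation and stopping rules are pinned.

mrm_features <- function(x, y, features = c("xy", "sum")) {
  features <- match.arg(features)
  x <- as.matrix(x); y <- as.matrix(y)
  assert_that(all(dim(x) == dim(y)), "x and y intensity matrices must match")
  k <- ncol(x)
  if (features == "xy") {
    f <- cbind(1, x, y, x * y)
    colnames(f) <- c("(intercept)",
                     paste0("b_", seq_len(k)), paste0("c_", seq_len(k)),
                     paste0("d_", seq_len(k)))
  } else {
    f <- cbind(1, x + y)
    colnames(f) <- c("(intercept)", paste0("s_", seq_len(k)))
  }
  f
}

# penalised negative log-likelihood and gradient; beta is a (p x 2) matrix of
# coefficients for the two non-reference classes (hom, WT); het is reference.
mrm_objective <- function(beta_vec, feat, ymat, ridge) {
  p <- ncol(feat)
  beta <- matrix(beta_vec, p, 2)
  eta <- feat %*% beta                    # n x 2 : l2 (hom), l3 (norm)
  m <- pmax(eta[, 1], eta[, 2], 0)
  logz <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))
  ll <- sum(eta[, 1] * ymat[, 1] + eta[, 2] * ymat[, 2] - logz)
  pen <- beta
  pen[1, ] <- 0                           # intercepts unpenalised
  -ll + ridge * sum(pen^2) / 2
}

mrm_gradient <- function(beta_vec, feat, ymat, ridge) {
  p <- ncol(feat)
  beta <- matrix(beta_vec, p, 2)
  eta <- feat %*% beta
  m <- pmax(eta[, 1], eta[, 2], 0)
  z <- exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m)
  pr <- cbind(exp(eta[, 1] - m), exp(eta[, 2] - m)) / z
  grad <- -t(feat) %*% (ymat - pr)
  pen <- beta
  pen[1, ] <- 0
  as.vector(grad + ridge * pen)
}

#' Fit the multinomial intensity regression model (MRM)
#'
#' Class probabilities follow the softmax with heterozygote reference:
#' `p(het) = 1 / (1 + e^{l_hom} + e^{l_wt})`, `p(hom) = e^{l_hom} / (...)`,
#' `p(WT) = e^{l_wt} / (...)`, where each linear predictor is
#' `a_g + sum_k (b_gk x_k + c_gk y_k + d_gk x_k y_k)` over probes `k`.
#' Coefficients maximise the ridge-penalised log-likelihood (BFGS with
#' analytic gradient; intercepts unpenalised).
#'
#' @param x,y per-probe channel intensity matrices (samples x probes).
#' @param labels integer genotypes 0 = WT, 1 = het, 2 = deletion homozygote;
#'   all three classes must be present.
#' @param ridge ridge penalty (default 1e-4 guarantees a finite optimum under
#'   separation).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap; non-convergence flags the model with a
#'   warning.
#' @param features `"xy"` for the full x, y, x*y parameterisation, `"sum"` for
#'   the summed-intensity-only mode.
#' @return an `mrm_model`: `coefficients` (p x 2 matrix, columns `hom`, `WT`),
#'   `reference_class = "het"`, `probes`, `features`, `converged`,
#'   `log_likelihood`, `iterations`, `ridge`.
#' @export
fit_mrm <- function(x, y, labels, ridge = 1e-4, tol = 1e-8, max_iter = 5000,
                    features = "xy") {
  labels <- as.integer(labels)
  assert_that(all(GENOTYPE_CODES %in% labels),
              "all three genotype classes must be present in training data",
              class = "delcall_unfittable")
  f <- mrm_features(x, y, features)
  ymat <- cbind(hom = labels == 2L, WT = labels == 0L) * 1
  p <- ncol(f)
  opt <- stats::optim(rep(0, 2 * p), mrm_objective, mrm_gradient,
                      feat = f, ymat = ymat, ridge = ridge,
                      method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  converged <- opt$convergence == 0
  if (!converged) warning("MRM did not converge within max_iter; model flagged")
  beta <- matrix(opt$par, p, 2,
                 dimnames = list(colnames(f), c("hom", "WT")))
  structure(list(coefficients = beta,
                 reference_class = "het",
                 probes = colnames(as.matrix(x)) %||% paste0("probe", seq_len(ncol(as.matrix(x)))),
                 features = features,
                 converged = converged,
                 log_likelihood = -opt$value,
                 iterations = opt$counts[["function"]],
                 ridge = ridge),
            class = "mrm_model")
}

#' @export
print.mrm_model <- function(x, ...) {
  cat("mrm_model:", nrow(x$coefficients), "coefficients per non-reference",
      "class (reference = het), features =", x$features,
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Predict genotype probabilities with a fitted MRM
#'
#' @param model an `mrm_model`.
#' @param x,y channel intensity matrices over the same probes as training.
#' @return list `probabilities` (n x 3 matrix, columns `WT`, `het`, `hom`,
#'   rows sum to 1) and `calls` (argmax; ties broken toward the lowest
#'   genotype code).
#' @export
predict_mrm <- function(model, x, y) {
  x <- as.matrix(x)
  assert_that(ncol(x) == length(model$probes),
              "probe count mismatch with fitted model")
  f <- mrm_features(x, y, model$features)
  eta <- f %*% model$coefficients           # hom, WT
  m <- pmax(eta[, 1], eta[, 2], 0)
  z <- exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m)
  probs <- cbind(WT = exp(eta[, 2] - m) / z,
                 het = exp(-m) / z,
                 hom = exp(eta[, 1] - m) / z)
  calls <- apply(probs[, c("WT", "het", "hom"), drop = FALSE], 1, argmax_first) - 1L
  list(probabilities = probs, calls = as.integer(calls))
}

# ---------------------------------------------------------------------------
# CART

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best (feature, threshold) split by weighted Gini; thresholds at midpoints
# between sorted unique values.
cart_best_split <- function(feat, labels) {
  n <- nrow(feat)
  best <- NULL
  best_gini <- Inf
  for (j in seq_len(ncol(feat))) {
    v <- feat[, j]
    ord <- order(v)
    vs <- v[ord]; ls <- labels[ord]
    uniq <- which(diff(vs) > 0)
    if (!length(uniq)) next
    # cumulative class counts along the sorted order
    cum <- apply(outer(ls, GENOTYPE_CODES, "=="), 2, cumsum)
    tot <- cum[n, ]
    for (i in uniq) {
      left <- cum[i, ]; right <- tot - left
      g <- (i * gini_impurity(left) + (n - i) * gini_impurity(right)) / n
      if (g < best_gini - 1e-12) {
        best_gini <- g
        best <- list(feature = j, threshold = (vs[i] + vs[i + 1]) / 2,
                     gini = g)
      }
    }
  }
  best
}

cart_grow <- function(feat, labels, min_node_size) {
  counts <- as.integer(table(factor(labels, levels = GENOTYPE_CODES)))
  node <- list(counts = counts, n = length(labels))
  if (length(labels) < min_node_size || length(unique(labels)) == 1) {
    node$leaf <- TRUE
    return(node)
  }
  split <- cart_best_split(feat, labels)
  if (is.null(split) || split$gini >= gini_impurity(counts) - 1e-12) {
    node$leaf <- TRUE
    return(node)
  }
  go_left <- feat[, split$feature] <= split$threshold
  node$leaf <- FALSE
  node$feature <- split$feature
  node$threshold <- split$threshold
  node$left <- cart_grow(feat[go_left, , drop = FALSE], labels[go_left],
                         min_node_size)
  node$right <- cart_grow(feat[!go_left, , drop = FALSE], labels[!go_left],
                          min_node_size)
  node
}

#' Fit a classification tree (CART) on probe intensities
#'
#' Greedy binary splits minimising weighted Gini impurity over all (feature,
#' threshold) candidates, thresholds at midpoints between sorted unique
#' values. Growth stops when a node holds fewer than `min_node_size` samples
#' or is pure.
#'
#' @inheritParams fit_mrm
#' @param min_node_size nodes smaller than this are never split (default 5).
#' @return a `cart_model`: recursive `tree` of nodes
#'   `{feature, threshold, left, right}` with per-leaf class counts,
#'   `feature_names`, `min_node_size`.
#' @export
fit_cart <- function(x, y, labels, min_node_size = 5, features = "xy") {
  labels <- as.integer(labels)
  assert_that(all(GENOTYPE_CODES %in% labels),
              "all three genotype classes must be present in training data",
              class = "delcall_unfittable")
  feat <- cart_feature_matrix(x, y, features)
  structure(list(tree = cart_grow(feat, labels, min_node_size),
                 feature_names = colnames(feat),
                 min_node_size = min_node_size,
                 features = features),
            class = "cart_model")
}

cart_feature_matrix <- function(x, y, features = c("xy", "sum")) {
  features <- match.arg(features)
  x <- as.matrix(x); y <- as.matrix(y)
  k <- ncol(x)
  if (features == "xy") {
    f <- cbind(x, y)
    colnames(f) <- c(paste0("x_", seq_len(k)), paste0("y_", seq_len(k)))
  } else {
    f <- x + y
    colnames(f) <- paste0("s_", seq_len(k))
  }
  f
}

cart_predict_one <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[node$feature] <= node$threshold) node$left else node$right
  }
  # majority class; ties toward the lowest genotype code
  GENOTYPE_CODES[argmax_first(node$counts)]
}

#' Predict genotypes with a fitted CART
#'
#' Leaf majority class; ties broken toward the lowest genotype code.
#'
#' @param model a `cart_model`.
#' @param x,y channel intensity matrices over the training probes.
#' @return integer genotype calls 0/1/2.
#' @export
predict_cart <- function(model, x, y) {
  feat <- cart_feature_matrix(x, y, model$features)
  assert_that(ncol(feat) == length(model$feature_names),
              "feature count mismatch with fitted model")
  as.integer(apply(feat, 1, function(r) cart_predict_one(model$tree, r)))
}

cart_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(cart_depth(node$left), cart_depth(node$right))
}

# ---------------------------------------------------------------------------
# Training-size bootstrap and ROC

per_class_metrics <- function(truth, calls) {
  sapply(GENOTYPE_CODES, function(g) {
    tp <- sum(calls == g & truth == g)
    fp <- sum(calls == g & truth != g)
    fn <- sum(calls != g & truth == g)
    c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
}

#' Bootstrap evaluation of training-set size
#'
#' For each training size `n`, draws `reps` random training sets, fits the
#' chosen caller, predicts the held-out remainder and records overall accuracy
#' plus per-class sensitivity and PPV; replicates whose training draw misses a
#' class are redrawn (and counted).
#'
#' @param intens an `intensity_table`.
#' @param labels true genotypes for every individual.
#' @param method `"mrm"` or `"cart"`.
#' @param sizes training-size grid (default 50 to 500 by 50).
#' @param reps replicates per size.
#' @param seed integer seed.
#' @param probes probe columns to use (default: probes inside the deletion).
#' @return a `training_curve`: data frame with one row per size (means and SDs
#'   of accuracy and per-class sensitivity/PPV, resample counts); attribute
#'   `"plateau_size"` = smallest size whose mean accuracy is within one SD of
#'   the largest size's mean.
#' @export
bootstrap_training_curve <- function(intens, labels, method = c("mrm", "cart"),
                                     sizes = seq(50, 500, by = 50), reps = 100,
                                     seed = 1L, probes = NULL) {
  method <- match.arg(method)
  cols <- if (is.null(probes)) deletion_probe_cols(intens) else probes
  x <- intens$x[, cols, drop = FALSE]
  y <- intens$y[, cols, drop = FALSE]
  n_all <- nrow(x)
  assert_that(max(sizes) <= n_all - 50,
              "training sizes must leave at least 50 held-out individuals")
  seeds <- derive_seeds(seed, length(sizes))

  rows <- lapply(seq_along(sizes), function(si) {
    nsz <- sizes[si]
    acc <- numeric(reps)
    sens <- ppv <- matrix(NA_real_, reps, 3)
    resampled <- 0L
    with_seed(seeds[si], {
      for (r in seq_len(reps)) {
        repeat {
          idx <- sample.int(n_all, nsz)
          if (all(GENOTYPE_CODES %in% labels[idx])) break
          resampled <- resampled + 1L
        }
        hold <- setdiff(seq_len(n_all), idx)
        calls <- if (method == "mrm") {
          fit <- fit_mrm(x[idx, , drop = FALSE], y[idx, , drop = FALSE],
                         labels[idx])
          predict_mrm(fit, x[hold, , drop = FALSE], y[hold, , drop = FALSE])$calls
        } else {
          fit <- fit_cart(x[idx, , drop = FALSE], y[idx, , drop = FALSE],
                          labels[idx])
          predict_cart(fit, x[hold, , drop = FALSE], y[hold, , drop = FALSE])
        }
        acc[r] <- mean(calls == labels[hold])
        pm <- per_class_metrics(labels[hold], calls)
        sens[r, ] <- pm["sensitivity", ]
        ppv[r, ] <- pm["ppv", ]
      }
    })
    data.frame(size = nsz, reps = reps, resampled = resampled,
               accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
               sens_wt_mean = mean(sens[, 1], na.rm = TRUE),
               sens_het_mean = mean(sens[, 2], na.rm = TRUE),
               sens_hom_mean = mean(sens[, 3], na.rm = TRUE),
               ppv_wt_mean = mean(ppv[, 1], na.rm = TRUE),
               ppv_het_mean = mean(ppv[, 2], na.rm = TRUE),
               ppv_hom_mean = mean(ppv[, 3], na.rm = TRUE),
               sens_hom_sd = stats::sd(sens[, 3], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  big <- which.max(out$size)
  plateau <- out$size[which(out$accuracy_mean >=
                              out$accuracy_mean[big] - out$accuracy_sd[big])[1]]
  attr(out, "plateau_size") <- plateau
  attr(out, "method") <- method
  class(out) <- c("training_curve", "data.frame")
  out
}

#' One-vs-rest ROC curves and AUC from class probabilities
#'
#' AUC by trapezoid rule over all probability thresholds.
#'
#' @param probabilities n x 3 matrix (columns WT, het, hom).
#' @param truth integer genotypes 0/1/2.
#' @return list per class: `points` (data frame fpr, tpr) and `auc`.
#' @export
roc_curves <- function(probabilities, truth) {
  assert_that(length(unique(truth)) >= 2,
              "AUC undefined: single-class truth",
              class = "delcall_undefined_stat")
  out <- lapply(seq_len(3), function(ci) {
    pos <- truth == GENOTYPE_CODES[ci]
    if (!any(pos) || all(pos)) {
      return(list(points = NULL, auc = NA_real_))
    }
    score <- probabilities[, ci]
    ord <- order(score, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    # collapse tied scores so thresholds sit between distinct values
    keep <- c(diff(score[ord]) != 0, TRUE)
    tpr <- c(0, tp[keep] / sum(pos))
    fpr <- c(0, fp[keep] / sum(!pos))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  })
  names(out) <- GENOTYPE_LABELS
  out
}
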