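# MRM and CART: softmax contract, separable fits, null limits, brute-force
# oracles, bootstrap curve and ROC.

test_that("MRM softmax contract: zero coefficients give 1/3 and the tie-break is WT", {
  blobs <- blob_intensities()
  model <- fit_mrm(blobs$x, blobs$y, blobs$labels)
  model$coefficients[] <- 0
  pr <- predict_mrm(model, blobs$x, blobs$y)
  expect_true(all(abs(pr$probabilities - 1 / 3) < 1e-12))
  expect_true(all(pr$calls == 0L))   # exact three-way tie -> lowest code (WT)
})

test_that("MRM separable fit, probability normalisation and null-model limit", {
  blobs <- blob_intensities()
  model <- fit_mrm(blobs$x, blobs$y, blobs$labels)
  pr <- predict_mrm(model, blobs$x, blobs$y)
  expect_gte(mean(pr$calls == blobs$labels), 0.99)
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-10))

  # labels independent of intensities -> probabilities near class frequencies
  withr::with_seed(33, {
    x <- matrix(rnorm(600), 300, 2); y <- matrix(rnorm(600), 300, 2)
    labels <- sample(0:2, 300, TRUE, prob = c(0.5, 0.3, 0.2))
  })
  null_fit <- fit_mrm(x, y, labels)
  pnull <- predict_mrm(null_fit, x, y)$probabilities
  freq <- tabulate(labels + 1L, 3) / 300
  expect_true(all(abs(colMeans(pnull) - freq) < 0.05))

  expect_error(fit_mrm(x, y, rep(0:1, 150)), class = "delcall_unfittable")
})

test_that("MRM prediction is invariant to an added zero-coefficient probe", {
  blobs <- blob_intensities()
  model <- fit_mrm(blobs$x, blobs$y, blobs$labels)
  padded <- model
  padded$coefficients <- rbind(model$coefficients[1:3, , drop = FALSE],
                               0,                                    # b_3
                               model$coefficients[4:5, , drop = FALSE],
                               0,                                    # c_3
                               model$coefficients[6:7, , drop = FALSE],
                               0)                                    # d_3
  padded$probes <- c(model$probes, "pad")
  x3 <- cbind(blobs$x, 99); y3 <- cbind(blobs$y, -7)
  pr <- predict_mrm(model, blobs$x, blobs$y)
  pr3 <- predict_mrm(padded, x3, y3)
  expect_equal(pr3$probabilities, pr$probabilities, tolerance = 1e-10)
  expect_error(predict_mrm(model, x3, y3), "probe count")
})

test_that("MRM decision boundaries survive channel rescaling when ridge ~ 0", {
  blobs <- blob_intensities()
  base <- fit_mrm(blobs$x, blobs$y, blobs$labels, ridge = 0)
  scaled <- fit_mrm(blobs$x * 10, blobs$y, blobs$labels, ridge = 0)
  acc_base <- mean(predict_mrm(base, blobs$x, blobs$y)$calls == blobs$labels)
  acc_scaled <- mean(predict_mrm(scaled, blobs$x * 10, blobs$y)$calls == blobs$labels)
  expect_lt(abs(acc_base - acc_scaled), 0.02)
})

test_that("CART: stopping rule, purity, and piecewise-constant prediction", {
  # one feature separating classes perfectly -> pure training predictions
  withr::with_seed(11, {
    g <- rep(0:2, each = 10)
    x <- matrix((2 - g) * 5 + rnorm(30, 0, 0.1), ncol = 1)
    y <- matrix(rnorm(30, 1, 0.1), ncol = 1)
  })
  tree <- fit_cart(x, y, g)
  expect_identical(predict_cart(tree, x, y), g)

  # a node of four samples is never split (leaf)
  tiny_x <- matrix(c(1, 2, 30, 40), ncol = 1)
  tiny_y <- matrix(0, 4, 1)
  root <- delcall:::cart_grow(cbind(tiny_x, tiny_y), c(0, 1, 2, 2), 5)
  expect_true(root$leaf)
  expect_identical(sum(root$counts), 4L)

  # perturbations that cross no threshold never change the call
  pr1 <- predict_cart(tree, x + 0.001, y)
  expect_identical(pr1, predict_cart(tree, x, y))
})

test_that("CART equals an exhaustive-split oracle on a 12-sample toy", {
  # independent oracle: recursive exhaustive search over every feature and
  # every midpoint, recomputing Gini from scratch
  oracle_grow <- function(feat, labels, min_node = 5) {
    gini <- function(l) { p <- table(l) / length(l); 1 - sum(p^2) }
    if (length(labels) < min_node || length(unique(labels)) == 1) {
      return(list(leaf = TRUE, labels = labels))
    }
    best <- NULL; best_score <- Inf
    for (j in seq_len(ncol(feat))) {
      for (t in sort(unique(feat[, j]))) {
        thr_cands <- sort(unique(feat[, j]))
        idx <- which(thr_cands == t)
        if (idx == length(thr_cands)) next
        thr <- (t + thr_cands[idx + 1]) / 2
        l <- labels[feat[, j] <= thr]; r <- labels[feat[, j] > thr]
        score <- (length(l) * gini(l) + length(r) * gini(r)) / length(labels)
        if (score < best_score - 1e-12) {
          best_score <- score; best <- list(j = j, thr = thr)
        }
      }
    }
    if (is.null(best) || best_score >= gini(labels) - 1e-12) {
      return(list(leaf = TRUE, labels = labels))
    }
    keep <- feat[, best$j] <= best$thr
    list(leaf = FALSE, j = best$j, thr = best$thr,
         left = oracle_grow(feat[keep, , drop = FALSE], labels[keep], min_node),
         right = oracle_grow(feat[!keep, , drop = FALSE], labels[!keep], min_node))
  }
  oracle_predict <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$j] <= node$thr) node$left else node$right
    }
    cnt <- tabulate(node$labels + 1L, 3)
    (0:2)[which(cnt == max(cnt))[1]]
  }
  withr::with_seed(77, {
    feat_x <- matrix(round(rnorm(24), 2), 12, 2)
    feat_y <- matrix(round(rnorm(24), 2), 12, 2)
    labels <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
    grid_x <- matrix(round(rnorm(60), 2), 30, 2)
    grid_y <- matrix(round(rnorm(60), 2), 30, 2)
  })
  tree <- fit_cart(feat_x, feat_y, labels)
  oracle <- oracle_grow(cbind(feat_x, feat_y), labels)
  got <- predict_cart(tree, grid_x, grid_y)
  want <- apply(cbind(grid_x, grid_y), 1, function(r) oracle_predict(oracle, r))
  expect_identical(got, as.integer(want))
})

test_that("parameter recovery at n = 100 training: MRM hits high hom sensitivity; both degrade with shrinking separation", {
  sim_sep <- function(sep_sd, seed) {
    withr::with_seed(seed, {
      n <- 400
      g <- sample(0:2, n, TRUE, prob = c(0.375, 0.486, 0.139))
      mu <- (2 - g) * sep_sd / 3             # class means sep_sd pooled-sds apart
      list(g = g,
           x = matrix(rnorm(6 * n, mu, 1 / 3), n, 6),
           y = matrix(rnorm(6 * n, mu, 1 / 3), n, 6),
           idx = sample(n, 100))
    })
  }
  hom_sens <- function(d, method) {
    hold <- setdiff(seq_along(d$g), d$idx)
    calls <- if (method == "mrm") {
      fit <- fit_mrm(d$x[d$idx, ], d$y[d$idx, ], d$g[d$idx])
      predict_mrm(fit, d$x[hold, ], d$y[hold, ])$calls
    } else {
      fit <- fit_cart(d$x[d$idx, ], d$y[d$idx, ], d$g[d$idx])
      predict_cart(fit, d$x[hold, ], d$y[hold, ])
    }
    hom <- d$g[hold] == 2
    sum(calls == 2 & hom) / sum(hom)
  }
  seeds <- (1:6) * 100
  # MRM reaches >= 0.95 hom-del sensitivity at 3 pooled-sd separation in
  # every replicate. CART with its < 5 stopping rule and ~14 homozygote
  # training samples is markedly less stable (as the source study also found)
  # and is held to the monotone-degradation clause below.
  for (s in seeds) expect_gte(hom_sens(sim_sep(3, s), "mrm"), 0.95)
  for (method in c("mrm", "cart")) {
    mean_sens <- vapply(c(3, 1.5, 0.75), function(sep) {
      mean(vapply(seeds, function(s) hom_sens(sim_sep(sep, s), method), 0))
    }, 0)
    expect_true(all(diff(mean_sens) < 0))    # degrades as separation shrinks
  }
})

test_that("bootstrap_training_curve is seeded, improves with n and detects a plateau", {
  # heavily overlapping classes (1 pooled-sd separation) so that training
  # size actually matters
  withr::with_seed(61, {
    n <- 500
    g <- sample(0:2, n, TRUE, prob = c(0.375, 0.486, 0.139))
    x <- matrix(rnorm(2 * n, (2 - g) * 0.5, 0.5), n, 2)
    y <- matrix(rnorm(2 * n, (2 - g) * 0.5, 0.5), n, 2)
  })
  it <- structure(list(individual_id = as.character(1:n),
                       probes = data.frame(probe_id = c("delprobe01", "delprobe02"),
                                           in_deletion = c(TRUE, TRUE)),
                       x = x, y = y, s = x + y), class = "intensity_table")
  curve <- bootstrap_training_curve(it, g, method = "mrm",
                                    sizes = c(50, 150, 300), reps = 8, seed = 3)
  curve2 <- bootstrap_training_curve(it, g, method = "mrm",
                                     sizes = c(50, 150, 300), reps = 8, seed = 3)
  expect_identical(as.data.frame(curve), as.data.frame(curve2))
  expect_gt(stats::cor(curve$size, curve$accuracy_mean, method = "spearman"), 0)
  expect_true(attr(curve, "plateau_size") %in% curve$size)
  expect_error(bootstrap_training_curve(it, g, sizes = 460), "held-out")
})

test_that("ROC: perfect separation, shuffled labels, monotone-transform invariance", {
  withr::with_seed(91, {
    truth <- sample(0:2, 2000, TRUE)
    perfect <- t(sapply(truth, function(g) { p <- c(0.01, 0.01, 0.01); p[g + 1] <- 0.98; p }))
    shuffled <- perfect[sample(2000), ]
  })
  roc_p <- roc_curves(perfect, truth)
  expect_equal(roc_p$WT$auc, 1)
  expect_equal(roc_p$hom$auc, 1)
  roc_s <- roc_curves(shuffled, truth)
  for (cls in c("WT", "het", "hom")) {
    expect_lt(abs(roc_s[[cls]]$auc - 0.5), 0.05)
  }
  # monotone transform of scores leaves AUC unchanged
  roc_m <- roc_curves(perfect^3, truth)
  expect_equal(roc_m$het$auc, roc_p$het$auc, tolerance = 1e-12)
  expect_error(roc_curves(perfect, rep(1, 2000)),
               class = "delcall_undefined_stat")
})
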