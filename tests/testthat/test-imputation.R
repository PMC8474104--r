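# Li-Stephens imputation: enumeration oracle, limits, thresholds and the
# cross-validation harness.

test_that("split_reference partitions individuals deterministically", {
  p <- simulate_haplotype_panel(small_config(n = 120, seed = 4))
  cfg <- imputation_config(n_ref_individuals = 30, seed = 5, runs = 1)
  sp1 <- split_reference(p, cfg)
  sp2 <- split_reference(p, cfg)
  expect_identical(sp1$ref_individuals, sp2$ref_individuals)
  expect_identical(sort(c(sp1$ref_individuals, sp1$test_individuals)), 1:120)
  expect_identical(length(intersect(sp1$ref_individuals, sp1$test_individuals)), 0L)
  # masking removes only the deletion column
  expect_true(all(is.na(sp1$test_alleles[, p$del_index])))
  expect_false(anyNA(sp1$test_alleles[, -p$del_index]))
  expect_error(split_reference(p, imputation_config(n_ref_individuals = 200)),
               "below the panel size")
})

test_that("forward-backward equals exhaustive path enumeration (3 markers x 4 reference haplotypes)", {
  ref <- rbind(c(0, 1, 0),
               c(1, 1, 1),
               c(0, 0, 1),
               c(1, 0, 0))   # deletion = column 2
  test <- rbind(c(0, NA, 0),
                c(1, NA, 1),
                c(1, NA, 0))
  morgans <- c(0.004, 0.01)
  ne <- 500; theta <- 0.05
  h <- nrow(ref)
  rho <- 1 - exp(-4 * ne * morgans / h)

  # oracle: sum over all h^3 copying paths with explicit transition and
  # emission products
  oracle_posterior <- function(obs) {
    emis <- function(o, a) if (is.na(o)) 1 else if (o == a) 1 - theta else theta
    total <- 0; post <- numeric(h)
    for (s1 in 1:h) for (s2 in 1:h) for (s3 in 1:h) {
      tr12 <- rho[1] / h + if (s1 == s2) 1 - rho[1] else 0
      tr23 <- rho[2] / h + if (s2 == s3) 1 - rho[2] else 0
      w <- (1 / h) * emis(obs[1], ref[s1, 1]) * tr12 *
        emis(obs[2], ref[s2, 2]) * tr23 * emis(obs[3], ref[s3, 3])
      total <- total + w
      post[s2] <- post[s2] + w
    }
    post <- post / total
    sum(post * ((1 - theta) * ref[, 2] + theta * (1 - ref[, 2])))
  }
  want <- apply(test, 1, oracle_posterior)
  got <- impute_deletion_haplotype(test, ref, del_index = 2, morgans,
                                   Ne = ne, theta = theta)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("copying-model limits: exact copy, uninformative flanks, theta decay", {
  p <- simulate_haplotype_panel(small_config(n = 60, seed = 44, site_noise = 0))
  m <- ncol(p$alleles)
  morgans <- rep(1e-6, m - 1)               # tight map
  carriers <- which(p$alleles[, p$del_index] == 1)
  ref <- p$alleles[c(carriers[1:5], setdiff(1:120, carriers)[1:5]), ]
  # a test haplotype identical to a deletion-carrying reference
  test <- ref[1, , drop = FALSE]
  test[, p$del_index] <- NA
  post <- impute_deletion_haplotype(test, ref, p$del_index, morgans,
                                    Ne = 20000, theta = 1e-4)
  expect_gt(post, 0.99)

  # all-missing flanks: posterior ~ reference deletion frequency
  blank <- matrix(NA_integer_, 1, m)
  f <- mean(ref[, p$del_index])
  post_blank <- impute_deletion_haplotype(blank, ref, p$del_index, morgans,
                                          Ne = 20000, theta = 1e-3)
  expect_lt(abs(post_blank - f), 0.01)

  # posterior decays toward the reference frequency as theta grows (monotone)
  thetas <- c(1e-4, 0.05, 0.2, 0.45)
  posts <- vapply(thetas, function(th) {
    impute_deletion_haplotype(test, ref, p$del_index, morgans,
                              Ne = 20000, theta = th)
  }, 0)
  expect_true(all(diff(abs(posts - f)) < 0))
})

test_that("genotype composition and thresholded calling behave as specified", {
  expect_equal(unname(impute_deletion_genotype(1, 1)), cbind(0, 0, 1),
               ignore_attr = TRUE)
  expect_equal(unname(impute_deletion_genotype(0.5, 0.5)),
               cbind(0.25, 0.5, 0.25), ignore_attr = TRUE)
  withr::with_seed(6, { p1 <- runif(50); p2 <- runif(50) })
  triple <- impute_deletion_genotype(p1, p2)
  expect_true(all(abs(rowSums(triple) - 1) < 1e-12))

  probs <- rbind(c(0.95, 0.03, 0.02),
                 c(0.6, 0.3, 0.1),
                 c(0.2, 0.7, 0.1))
  expect_identical(call_genotypes(probs, 0.7), c(0L, NA, 1L))
  expect_identical(call_genotypes(probs, 0.9), c(0L, NA, NA))
  # probability exactly at the threshold is called
  expect_identical(call_genotypes(rbind(c(0.7, 0.2, 0.1)), 0.7), 0L)
  expect_error(call_genotypes(probs, 0.2), "1/3")
})

test_that("cross-validation metrics, threshold monotonicity and strict-call nesting", {
  p <- simulate_haplotype_panel(small_config(n = 150, seed = 52))
  cfg <- imputation_config(n_ref_individuals = 40, runs = 4, seed = 9)
  cv <- imputation_cross_validation(p, attr(p, "map"), cfg)
  pr <- cv$per_run
  expect_identical(nrow(pr), 8L)            # runs x thresholds
  # no-call proportion at 0.9 >= at 0.7 in every run
  wide <- merge(pr[pr$threshold == 0.7, c("run", "no_call")],
                pr[pr$threshold == 0.9, c("run", "no_call")], by = "run")
  expect_true(all(wide$no_call.y >= wide$no_call.x))
  expect_true(all(pr$adjusted_correct >= pr$correct - 1e-12))
  expect_equal(pr$adjusted_correct,
               pr$n_correct / (pr$n_total - pr$n_no_call), tolerance = 1e-12)
  expect_identical(dimnames(cv$summary[["0.7"]])[[1]],
                   c("min", "q1", "median", "mean", "sd", "q3", "max"))

  # strict threshold never calls what the relaxed one left uncalled
  sp <- split_reference(p, cfg, seed = delcall:::derive_seeds(cfg$seed, 1))
  morg <- delcall:::adjacent_morgans(p, attr(p, "map"))
  ph <- impute_deletion_haplotype(sp$test_alleles, sp$ref_alleles,
                                  p$del_index, morg)
  odd <- seq(1, length(ph), 2)
  probs <- impute_deletion_genotype(ph[odd], ph[odd + 1])
  relaxed <- call_genotypes(probs, 0.7)
  strict <- call_genotypes(probs, 0.9)
  expect_true(all(is.na(strict[is.na(relaxed)])))
})

test_that("single-origin panels impute better than recurrent-origin panels", {
  adj <- sapply(c(1, 8), function(orig) {
    p <- simulate_haplotype_panel(small_config(n = 250, seed = 73,
                                               n_del_origins = orig))
    cv <- imputation_cross_validation(
      p, attr(p, "map"),
      imputation_config(n_ref_individuals = 60, runs = 4, seed = 2,
                        thresholds = 0.7))
    cv$summary[["0.7"]]["mean", "adjusted_correct"]
  })
  expect_gt(adj[1], 0.95)                   # near-perfect LD limit
  expect_gt(adj[1], adj[2])                 # heterogeneity degrades imputation
})
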