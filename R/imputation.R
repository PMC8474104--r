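# Haplotype-copying imputation of a masked deletion allele from a genotyped
# reference panel: a Li-Stephens hidden-state model standing in for the
# IMPUTE2 binary. Each test haplotype copies one of H reference haplotypes;
# between adjacent markers the copied haplotype switches with probability
# rho_j = 1 - exp(-4 Ne c_j / H) (c_j = map distance in Morgans), spread
# uniformly over the H reference haplotypes; the emitted allele matches the
# copied haplotype with probability 1 - theta. The deletion column is masked
# (uninformative emission) in the test data, and its posterior is the
# state-posterior-weighted, theta-smoothed reference deletion allele.

#' Imputation configuration
#'
#' @param n_ref_individuals reference-panel size (individuals).
#' @param Ne effective population size for the switching rate.
#' @param theta emission mismatch probability in (0, 1).
#' @param thresholds genotype-calling thresholds, each in (1/3, 1].
#' @param runs cross-validation repetitions.
#' @param seed integer seed.
#' @return an `imputation_config` list.
#' @export
imputation_config <- function(n_ref_individuals = 100, Ne = 20000,
                              theta = 1e-3, thresholds = c(0.7, 0.9),
                              runs = 1000, seed = 1L) {
  assert_that(theta > 0 && theta < 1, "theta must be in (0, 1)")
  assert_that(all(thresholds > 1 / 3 & thresholds <= 1),
              "thresholds must lie in (1/3, 1]")
  assert_that(runs >= 1, "runs must be >= 1")
  structure(list(n_ref_individuals = as.integer(n_ref_individuals),
                 Ne = Ne, theta = theta, thresholds = sort(thresholds),
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "imputation_config")
}

#' Split a panel into reference and masked test sets
#'
#' Randomly selects `n_ref_individuals` as the reference (deletion typed); the
#' remaining individuals form the test set with the deletion column masked to
#' `NA`.
#'
#' @param panel a [haplotype_panel()].
#' @param config an [imputation_config()].
#' @param seed seed for the draw (defaults to `config$seed`).
#' @return list `ref_alleles` (2 n_ref x m), `test_alleles` (deletion column
#'   `NA`), `truth` (deletion genotypes of the test individuals),
#'   `ref_individuals`, `test_individuals`.
#' @export
split_reference <- function(panel, config, seed = config$seed) {
  n_ind <- n_individuals_panel(panel)
  assert_that(config$n_ref_individuals < n_ind,
              "reference size must be below the panel size")
  with_seed(seed, {
    ref_ind <- sort(sample.int(n_ind, config$n_ref_individuals))
    test_ind <- setdiff(seq_len(n_ind), ref_ind)
    chrom_rows <- function(ind) as.vector(rbind(2L * ind - 1L, 2L * ind))
    ref <- panel$alleles[chrom_rows(ref_ind), , drop = FALSE]
    test <- panel$alleles[chrom_rows(test_ind), , drop = FALSE]
    g <- pair_into_diploids(panel)
    truth <- deletion_genotypes(g)[test_ind]
    test[, panel$del_index] <- NA_integer_
    list(ref_alleles = ref, test_alleles = test, truth = truth,
         ref_individuals = ref_ind, test_individuals = test_ind)
  })
}

# map distances in Morgans between adjacent panel markers, floored.
adjacent_morgans <- function(panel, map, floor_morgans = 1e-8) {
  cm <- stats::approx(map$positions_bp, map$cumulative_cM,
                      xout = panel$positions_bp, rule = 2)$y
  d <- diff(cm) / 100
  if (all(d <= 0)) {
    message("zero-width recombination map: using uniform tiny floor")
  }
  pmax(d, floor_morgans)
}

#' Deletion-allele posteriors by Li-Stephens forward-backward
#'
#' Vectorised over test haplotypes: runs the scaled forward-backward recursion
#' over all markers (masked sites emit 1 for every state) and returns, for
#' each test haplotype, the posterior probability that it carries the deletion
#' allele.
#'
#' @param test_alleles matrix of test haplotypes (rows) x panel variants, with
#'   `NA` at masked sites (at least the deletion column).
#' @param ref_alleles reference haplotype matrix over the same variant grid,
#'   deletion column typed.
#' @param del_index deletion column.
#' @param morgans inter-marker distances in Morgans (length m - 1), e.g. from
#'   the recombination map.
#' @param Ne effective population size.
#' @param theta emission mismatch probability.
#' @return numeric vector of deletion-allele posteriors in `[0, 1]`.
#' @export
impute_deletion_haplotype <- function(test_alleles, ref_alleles, del_index,
                                      morgans, Ne = 20000, theta = 1e-3) {
  test_alleles <- matrix(as.integer(test_alleles), nrow = NROW(test_alleles))
  h <- nrow(ref_alleles)
  m <- ncol(ref_alleles)
  assert_that(ncol(test_alleles) == m,
              "test and reference must share the variant grid")
  assert_that(length(morgans) == m - 1, "need m - 1 inter-marker distances")
  rho <- 1 - exp(-4 * Ne * morgans / h)
  n <- nrow(test_alleles)

  emission <- function(j) {
    obs <- test_alleles[, j]
    e <- matrix(1, n, h)
    known <- !is.na(obs)
    if (any(known)) {
      match_mat <- outer(obs[known], ref_alleles[, j], "==")
      e[known, ] <- theta + (1 - 2 * theta) * match_mat
    }
    e
  }

  # forward to the deletion marker
  alpha <- emission(1) / h
  alpha <- alpha / rowSums(alpha)
  if (del_index > 1) for (j in 2:del_index) {
    alpha <- (1 - rho[j - 1]) * alpha + rho[j - 1] / h
    alpha <- alpha * emission(j)
    alpha <- alpha / rowSums(alpha)
  }
  # backward from the last marker to the deletion marker
  beta <- matrix(1, n, h)
  if (del_index < m) for (j in (m - 1):del_index) {
    tmp <- beta * emission(j + 1)
    beta <- (1 - rho[j]) * tmp + rho[j] * rowMeans(tmp)
    beta <- beta / rowSums(beta)
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  ref_del <- ref_alleles[, del_index]
  as.vector(post %*% ((1 - theta) * ref_del + theta * (1 - ref_del)))
}

#' Compose a genotype posterior from two haplotype posteriors
#'
#' Treats the two chromosomes as independent: `P(hom) = p1 p2`,
#' `P(het) = p1 (1 - p2) + p2 (1 - p1)`, `P(WT) = (1 - p1)(1 - p2)`.
#'
#' @param p1,p2 deletion-allele posteriors for the two chromosomes.
#' @return n x 3 matrix with columns `WT`, `het`, `hom` summing to 1.
#' @export
impute_deletion_genotype <- function(p1, p2) {
  assert_prob(p1, "p1"); assert_prob(p2, "p2")
  cbind(WT = (1 - p1) * (1 - p2),
        het = p1 * (1 - p2) + p2 * (1 - p1),
        hom = p1 * p2)
}

#' Threshold genotype probabilities into calls with a no-call state
#'
#' Calls the argmax genotype when its probability reaches the threshold
#' (boundary equality is called); otherwise `NA` (no-call).
#'
#' @param probs n x 3 matrix (columns WT, het, hom).
#' @param threshold calling threshold in (1/3, 1].
#' @return integer vector: 0/1/2 or `NA` for no-call.
#' @export
call_genotypes <- function(probs, threshold) {
  assert_that(threshold > 1 / 3 && threshold <= 1,
              "threshold must lie in (1/3, 1]")
  best <- apply(probs, 1, argmax_first)
  best_p <- probs[cbind(seq_len(nrow(probs)), best)]
  out <- GENOTYPE_CODES[best]
  out[best_p < threshold] <- NA_integer_
  out
}

#' Cross-validated imputation of the deletion genotype
#'
#' Implements the bootstrap design: in each run a random reference panel of
#' `n_ref_individuals` is drawn, the deletion is masked in the remainder,
#' haplotype posteriors are computed by [impute_deletion_haplotype()], and the
#' composed genotype probabilities are called at each threshold. Per-run
#' metrics are aggregated as min / quartiles / mean / SD / max.
#'
#' @param panel a [haplotype_panel()].
#' @param map a [recomb_map()] (defaults to the map attached by the
#'   simulator).
#' @param config an [imputation_config()].
#' @return an `imputation_cv` list: `per_run` (data frame: run, threshold,
#'   correct, adjusted_correct, no_call, per-class sensitivity/specificity/
#'   accuracy/PPV, dosage_correlation), `summary` (stat x metric x threshold),
#'   `config`.
#' @export
imputation_cross_validation <- function(panel, map = attr(panel, "map"),
                                        config = imputation_config()) {
  assert_that(!is.null(map), "a recombination map is required")
  morgans <- adjacent_morgans(panel, map)
  seeds <- derive_seeds(config$seed, config$runs)

  per_run <- vector("list", config$runs * length(config$thresholds))
  k <- 0L
  for (run in seq_len(config$runs)) {
    sp <- split_reference(panel, config, seed = seeds[run])
    p_hap <- impute_deletion_haplotype(sp$test_alleles, sp$ref_alleles,
                                       panel$del_index, morgans,
                                       Ne = config$Ne, theta = config$theta)
    odd <- seq(1, length(p_hap), by = 2)
    probs <- impute_deletion_genotype(p_hap[odd], p_hap[odd + 1])
    for (thr in config$thresholds) {
      calls <- call_genotypes(probs, thr)
      rep <- performance_report(sp$truth, calls)
      k <- k + 1L
      per_run[[k]] <- data.frame(
        run = run, threshold = thr,
        n_correct = rep$n_correct, n_total = rep$n,
        n_no_call = rep$n_no_call,
        correct = rep$correct_proportion,
        adjusted_correct = rep$adjusted_correct_proportion,
        no_call = rep$no_call_proportion,
        sens_wt = rep$per_class["sensitivity", "WT"],
        spec_wt = rep$per_class["specificity", "WT"],
        acc_wt = rep$per_class["accuracy", "WT"],
        ppv_wt = rep$per_class["ppv", "WT"],
        sens_het = rep$per_class["sensitivity", "het"],
        spec_het = rep$per_class["specificity", "het"],
        acc_het = rep$per_class["accuracy", "het"],
        ppv_het = rep$per_class["ppv", "het"],
        sens_hom = rep$per_class["sensitivity", "hom"],
        spec_hom = rep$per_class["specificity", "hom"],
        acc_hom = rep$per_class["accuracy", "hom"],
        ppv_hom = rep$per_class["ppv", "hom"],
        dosage_correlation = rep$dosage_correlation)
    }
  }
  per_run <- do.call(rbind, per_run)

  summarise <- function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    c(min = min(v, na.rm = TRUE), q1 = unname(qs[1]), median = unname(qs[2]),
      mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      q3 = unname(qs[3]), max = max(v, na.rm = TRUE))
  }
  metrics <- setdiff(names(per_run), c("run", "threshold"))
  summary <- lapply(split(per_run, per_run$threshold), function(df) {
    sapply(df[metrics], summarise)
  })
  structure(list(per_run = per_run, summary = summary, config = config),
            class = "imputation_cv")
}

#' @export
print.imputation_cv <- function(x, ...) {
  cat("imputation_cv:", x$config$runs, "runs, thresholds",
      paste(x$config$thresholds, collapse = "/"), "\n")
  for (thr in names(x$summary)) {
    cat("  threshold", thr, ": mean adjusted-correct =",
        signif(x$summary[[thr]]["mean", "adjusted_correct"], 3),
        ", mean no-call =",
        signif(x$summary[[thr]]["mean", "no_call"], 3), "\n")
  }
  invisible(x)
}
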