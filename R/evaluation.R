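# Unified performance metrics for inferred vs directly typed genotypes, plus
# the side-by-side method comparison and the cohort chromosome accounting.

#' Confusion metrics for genotype calls against direct typing
#'
#' One-vs-rest sensitivity, specificity, accuracy, PPV and NPV per class are
#' computed on called samples only; the correct proportion is over all
#' samples, the adjusted-correct proportion is `correct / (total - no-calls)`,
#' and the dosage correlation is the Pearson correlation of the 0/1/2 codes on
#' called samples. Undefined rates (zero denominators) are `NA`, never 0.
#'
#' @param truth integer genotypes 0/1/2.
#' @param calls integer genotypes 0/1/2 with `NA` = no-call.
#' @return a `performance_report`: `confusion` (truth x call incl. `no_call`),
#'   `per_class` (metric x class matrix), `correct_proportion`,
#'   `adjusted_correct_proportion`, `no_call_proportion`,
#'   `dosage_correlation`, `n`, `n_correct`, `n_no_call`.
#' @export
performance_report <- function(truth, calls) {
  assert_that(length(truth) == length(calls),
              "truth and calls must have equal length")
  truth <- as.integer(truth)
  calls <- as.integer(calls)
  n <- length(truth)
  called <- !is.na(calls)
  n_no_call <- sum(!called)
  n_correct <- sum(called & calls == truth)

  conf <- table(factor(truth, levels = GENOTYPE_CODES),
                factor(ifelse(called, calls, -1L), levels = c(GENOTYPE_CODES, -1L)))
  dimnames(conf) <- list(truth = GENOTYPE_LABELS,
                         call = c(GENOTYPE_LABELS, "no_call"))

  per_class <- sapply(GENOTYPE_CODES, function(g) {
    t_pos <- truth == g & called
    c_pos <- calls == g & called
    tp <- sum(t_pos & c_pos); fp <- sum(!t_pos & c_pos & called)
    fn <- sum(t_pos & !c_pos); tn <- sum(!t_pos & !c_pos & called)
    rate <- function(num, den) if (den > 0) num / den else NA_real_
    c(sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, tn + fp),
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      ppv = rate(tp, tp + fp),
      npv = rate(tn, tn + fn))
  })
  colnames(per_class) <- GENOTYPE_LABELS

  n_called <- n - n_no_call
  dosage_cor <- if (n_called >= 2 &&
                    stats::sd(truth[called]) > 0 &&
                    stats::sd(calls[called]) > 0) {
    stats::cor(truth[called], calls[called])
  } else NA_real_

  structure(list(confusion = conf,
                 per_class = per_class,
                 correct_proportion = n_correct / n,
                 adjusted_correct_proportion =
                   if (n_called > 0) n_correct / n_called else NA_real_,
                 no_call_proportion = n_no_call / n,
                 dosage_correlation = dosage_cor,
                 n = n, n_correct = n_correct, n_no_call = n_no_call),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("performance_report: n =", x$n, ", correct =",
      signif(x$correct_proportion, 3), ", adjusted-correct =",
      signif(x$adjusted_correct_proportion, 3), ", no-call =",
      signif(x$no_call_proportion, 3), "\n")
  print(round(x$per_class, 3))
  invisible(x)
}

#' Chromosome accounting from genotype class counts
#'
#' Converts diploid genotype class counts into allele (chromosome) counts:
#' deletion chromosomes `= n_het + 2 n_hom`, intact chromosomes
#' `= 2 n_wt + n_het`.
#'
#' @param n_wt,n_het,n_hom genotype class counts.
#' @return list: `n_individuals`, `n_chromosomes`, `del_chromosomes`,
#'   `wt_chromosomes`, `del_freq`, `hom_fraction`.
#' @export
genotype_chromosome_counts <- function(n_wt, n_het, n_hom) {
  n_wt <- as.integer(n_wt); n_het <- as.integer(n_het); n_hom <- as.integer(n_hom)
  n_ind <- n_wt + n_het + n_hom
  list(n_individuals = n_ind,
       n_chromosomes = 2L * n_ind,
       del_chromosomes = n_het + 2L * n_hom,
       wt_chromosomes = 2L * n_wt + n_het,
       del_freq = (n_het + 2 * n_hom) / (2 * n_ind),
       hom_fraction = n_hom / n_ind)
}

#' Run every caller and association model over one dataset
#'
#' Produces the long-format comparison: per method, a [performance_report()]
#' against the directly typed genotypes and per-model association results.
#' Method failures are isolated (row marked failed), the run continues.
#'
#' @param dataset a `delcall_dataset` from [simulate_dataset()].
#' @param methods subset of
#'   `c("truth", "cutoffs", "hclust", "mrm", "cart", "imputation")`.
#' @param seed integer seed for training draws and imputation runs.
#' @param train_size training-set size for MRM and CART.
#' @param imputation_runs cross-validation runs for the imputation row.
#' @param assoc_models inheritance models fit per method.
#' @return a `method_comparison` list: `calls` (per-method genotype vectors),
#'   `performance` (long data frame), `associations` (long data frame),
#'   `failed` (character).
#' @export
compare_methods <- function(dataset,
                            methods = c("truth", "cutoffs", "hclust", "mrm",
                                        "cart", "imputation"),
                            seed = 1L, train_size = 100,
                            imputation_runs = 3,
                            assoc_models = c("additive", "genotypic")) {
  truth <- deletion_genotypes(dataset$genotypes)
  intens <- dataset$intensities
  del_cols <- deletion_probe_cols(intens)
  n <- length(truth)
  seeds <- derive_seeds(seed, 4)
  calls <- list()
  failed <- character(0)

  for (mth in methods) {
    res <- tryCatch(switch(mth,
      truth = truth,
      cutoffs = {
        # per-probe cut-off calls, majority vote over probes with found cut-offs
        votes <- sapply(del_cols, function(cl) {
          co <- density_cutoffs(intens$s[, cl])
          if (!co$found) rep(NA_integer_, n) else call_by_cutoffs(intens$s[, cl], co)
        })
        apply(votes, 1, function(v) {
          v <- v[!is.na(v)]
          if (!length(v)) NA_integer_ else
            GENOTYPE_CODES[argmax_first(tabulate(v + 1L, 3))]
        })
      },
      hclust = hierarchical_call(intens)$calls,
      mrm = with_seed(seeds[1], {
        idx <- sample.int(n, train_size)
        fit <- fit_mrm(intens$x[idx, del_cols], intens$y[idx, del_cols],
                       truth[idx])
        predict_mrm(fit, intens$x[, del_cols], intens$y[, del_cols])$calls
      }),
      cart = with_seed(seeds[2], {
        idx <- sample.int(n, train_size)
        fit <- fit_cart(intens$x[idx, del_cols], intens$y[idx, del_cols],
                        truth[idx])
        predict_cart(fit, intens$x[, del_cols], intens$y[, del_cols])
      }),
      imputation = {
        cfg <- imputation_config(runs = imputation_runs, seed = seeds[3],
                                 thresholds = 0.7)
        cv <- imputation_cross_validation(dataset$panel, dataset$map, cfg)
        # single representative run's calls for association: rerun run 1
        sp <- split_reference(dataset$panel, cfg,
                              seed = derive_seeds(cfg$seed, 1))
        morg <- adjacent_morgans(dataset$panel, dataset$map)
        ph <- impute_deletion_haplotype(sp$test_alleles, sp$ref_alleles,
                                        dataset$panel$del_index, morg,
                                        Ne = cfg$Ne, theta = cfg$theta)
        odd <- seq(1, length(ph), by = 2)
        cc <- rep(NA_integer_, n)
        cc[sp$test_individuals] <-
          call_genotypes(impute_deletion_genotype(ph[odd], ph[odd + 1]), 0.7)
        cc[sp$ref_individuals] <- truth[sp$ref_individuals]
        cc
      },
      stop_delcall("unknown method: ", mth)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, mth)
      warning("method '", mth, "' failed: ", conditionMessage(res))
    } else {
      calls[[mth]] <- as.integer(res)
    }
  }

  perf_rows <- lapply(names(calls), function(mth) {
    rep <- performance_report(truth, calls[[mth]])
    data.frame(method = mth,
               correct = rep$correct_proportion,
               adjusted_correct = rep$adjusted_correct_proportion,
               no_call = rep$no_call_proportion,
               sens_wt = rep$per_class["sensitivity", "WT"],
               sens_het = rep$per_class["sensitivity", "het"],
               sens_hom = rep$per_class["sensitivity", "hom"],
               ppv_wt = rep$per_class["ppv", "WT"],
               ppv_het = rep$per_class["ppv", "het"],
               ppv_hom = rep$per_class["ppv", "hom"],
               dosage_correlation = rep$dosage_correlation,
               stringsAsFactors = FALSE)
  })

  assoc_rows <- list()
  for (mth in names(calls)) {
    for (mdl in assoc_models) {
      row <- tryCatch({
        res <- genetic_association(calls[[mth]], dataset$phenotypes,
                                   model = mdl)
        cbind(method = mth, as.data.frame(res), failed = FALSE)
      }, error = function(e) {
        data.frame(method = mth, variant_id = "DEL3.7", model = mdl,
                   term = NA_character_, or = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, n = NA_integer_,
                   n_excluded = NA_integer_, converged = FALSE, failed = TRUE,
                   stringsAsFactors = FALSE)
      })
      assoc_rows[[paste(mth, mdl)]] <- row
    }
  }

  structure(list(calls = calls,
                 performance = do.call(rbind, perf_rows),
                 associations = do.call(rbind, assoc_rows),
                 failed = failed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison over", length(x$calls), "methods\n")
  print(x$performance, digits = 3, row.names = FALSE)
  invisible(x)
}
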