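# Case-control association testing by fixed-effects logistic regression with
# covariate adjustment, under the standard genetic encodings (additive,
# genotypic, dominant, recessive, heterozygous).

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binary-response logistic model to relative tolerance 1e-8 (max 50
#' iterations). Separation (any |beta| > 15 while diverging) flags the fit as
#' non-converged; rank-deficient designs raise an error naming the collinear
#' columns.
#'
#' @param response 0/1 vector.
#' @param design numeric design matrix (including the intercept column).
#' @param tol relative convergence tolerance on the deviance.
#' @param max_iter iteration cap.
#' @return a `logistic_fit`: `coefficients`, `se`, `vcov`, `z`, `p` (Wald),
#'   `converged`, `separation`, `iterations`, `deviance`, `n`.
#' @export
fit_logistic <- function(response, design, tol = 1e-8, max_iter = 50) {
  y <- as.numeric(response)
  x <- as.matrix(design)
  assert_that(all(y %in% 0:1), "response must be binary 0/1")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop_delcall("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", "),
                 class = "delcall_rank_deficient")
  }
  beta <- rep(0, ncol(x))
  dev_old <- Inf
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(x, z, w)
    beta <- fit$coefficients
    mu <- stats::plogis(drop(x %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (any(abs(beta) > 15)) {
      separation <- TRUE
      break
    }
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    if (iter >= max_iter) break
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  xtwx <- crossprod(x * sqrt(w))
  vcov <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  se <- sqrt(diag(vcov))
  zstat <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 vcov = vcov, z = zstat,
                 p = 2 * stats::pnorm(-abs(zstat)),
                 converged = converged && !separation,
                 separation = separation,
                 iterations = iter, deviance = dev, n = length(y)),
            class = "logistic_fit")
}

# design columns for the genetic encoding of a 0/1/2 genotype
encode_genotype <- function(g, model) {
  switch(model,
         additive = cbind(dosage = g),
         genotypic = cbind(het = as.numeric(g == 1), hom = as.numeric(g == 2)),
         dominant = cbind(dominant = as.numeric(g >= 1)),
         recessive = cbind(recessive = as.numeric(g == 2)),
         heterozygous = cbind(heterozygous = as.numeric(g == 1)),
         stop_delcall("unknown genetic model: ", model))
}

covariate_design <- function(phenotypes, covariates) {
  cols <- list()
  if ("sex" %in% covariates) cols$sex <- phenotypes$sex
  if ("ethnicity" %in% covariates) {
    eth <- factor(phenotypes$ethnicity)
    if (nlevels(eth) > 1) {
      mm <- stats::model.matrix(~eth)[, -1, drop = FALSE]
      colnames(mm) <- sub("^eth", "ethnicity_", colnames(mm))
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
  }
  if ("rs334" %in% covariates) cols$rs334 <- phenotypes$rs334_genotype
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Genetic association of a genotype vector with case-control status
#'
#' Encodes the genotype per the chosen inheritance model (additive: dosage;
#' genotypic: het and hom indicators vs WT; dominant: `g >= 1`; recessive:
#' `g == 2`; heterozygous: `g == 1`), adds covariate columns and fits
#' [fit_logistic()]. No-call (`NA`) genotypes are excluded complete-case with
#' the excluded count reported. Wald 95% CIs: `exp(beta +/- 1.96 SE)`.
#'
#' @param genotypes integer vector 0/1/2 with optional `NA` no-calls.
#' @param phenotypes a `phenotype_table`.
#' @param covariates subset of `c("sex", "ethnicity", "rs334")`.
#' @param model inheritance model.
#' @param variant_id label carried into the result.
#' @return an `association_result` data frame: one row per genetic term with
#'   `variant_id`, `model`, `term`, `or`, `ci_low`, `ci_high`, `p`, `n`,
#'   `n_excluded`, `converged`.
#' @export
genetic_association <- function(genotypes, phenotypes,
                                covariates = c("sex", "ethnicity", "rs334"),
                                model = c("additive", "genotypic", "dominant",
                                          "recessive", "heterozygous"),
                                variant_id = "DEL3.7") {
  model <- match.arg(model)
  g <- as.integer(genotypes)
  keep <- !is.na(g)
  n_excluded <- sum(!keep)
  g <- g[keep]
  ph <- phenotypes[keep, , drop = FALSE]
  assert_that(all(g %in% 0:2), "genotypes must be coded 0/1/2 (or NA)")

  gcols <- encode_genotype(g, model)
  dropped <- colnames(gcols)[apply(gcols, 2, function(v) length(unique(v)) < 2)]
  if (length(dropped)) {
    warning("dropping constant genetic term(s): ", paste(dropped, collapse = ", "))
    gcols <- gcols[, setdiff(colnames(gcols), dropped), drop = FALSE]
    assert_that(ncol(gcols) > 0, "no variable genetic term left")
  }
  cov <- covariate_design(ph, covariates)
  design <- cbind("(intercept)" = 1, gcols, cov)
  fit <- fit_logistic(ph$status, design)

  terms <- colnames(gcols)
  ci <- exp(cbind(fit$coefficients[terms] - 1.96 * fit$se[terms],
                  fit$coefficients[terms] + 1.96 * fit$se[terms]))
  out <- data.frame(variant_id = variant_id, model = model, term = terms,
                    or = exp(fit$coefficients[terms]),
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p = fit$p[terms], n = fit$n, n_excluded = n_excluded,
                    converged = fit$converged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("association_result", "data.frame")
  out
}

#' Region-wide association scan with a Bonferroni threshold
#'
#' Fits the chosen model at every polymorphic variant; the family-wise
#' threshold `0.05 / m` (m = number of variants tested) is reported alongside
#' and variants are flagged significant iff `p < threshold` (minimum genetic
#' term p per variant). Monomorphic variants are skipped with a reason.
#'
#' @param genotypes individuals x variants matrix (0/1/2).
#' @param phenotypes a `phenotype_table`.
#' @param covariates as in [genetic_association()].
#' @param model inheritance model.
#' @return a `region_scan` list: `results` (per-variant data frame with `p`
#'   and `significant`), `threshold`, `m`, `skipped` (data frame of skipped
#'   variants and reasons).
#' @export
region_scan <- function(genotypes, phenotypes,
                        covariates = c("sex", "ethnicity", "rs334"),
                        model = "additive") {
  assert_that(is.matrix(genotypes) && ncol(genotypes) >= 1,
              "need a genotype matrix with >= 1 variant")
  ids <- colnames(genotypes) %||% sprintf("var%03d", seq_len(ncol(genotypes)))
  poly <- apply(genotypes, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  skipped <- data.frame(variant_id = ids[!poly],
                        reason = if (any(!poly)) "monomorphic" else character(0),
                        stringsAsFactors = FALSE)
  m <- sum(poly)
  assert_that(m >= 1, "no polymorphic variants to test")
  threshold <- 0.05 / m
  rows <- lapply(which(poly), function(j) {
    res <- genetic_association(genotypes[, j], phenotypes, covariates, model,
                               variant_id = ids[j])
    data.frame(variant_id = ids[j], model = model,
               or = res$or[1], ci_low = res$ci_low[1], ci_high = res$ci_high[1],
               p = min(res$p), converged = all(res$converged),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$significant <- results$p < threshold
  structure(list(results = results, threshold = threshold, m = m,
                 skipped = skipped),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat("region_scan:", x$m, "variants tested, Bonferroni threshold",
      signif(x$threshold, 3), "-", sum(x$results$significant),
      "significant\n")
  invisible(x)
}
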