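# LD, extended haplotype homozygosity, haplotype spectra/diversity, Tajima's D
# and haplotype clustering over phased 0/1 panels. All statistics are computed
# from direct haplotype counting on the phased chromosomes.

#' Pairwise linkage disequilibrium between two variants
#'
#' From phased haplotype counts: `D = p11 - pA * pB`,
#' `r = D / sqrt(pA qA pB qB)`, and `D' = D / Dmax` with
#' `Dmax = min(pA qB, qA pB)` when `D > 0`, else `min(pA pB, qA qB)`.
#' `D'` is reported signed.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j distinct variant column indices; both must be polymorphic.
#' @return an `ld_result` list: `r`, `r2`, `dprime`.
#' @export
pairwise_ld <- function(panel, i, j) {
  assert_that(i != j, "i and j must differ")
  a <- panel$alleles[, i]
  b <- panel$alleles[, j]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop_delcall("LD undefined: variant ", if (pa %in% c(0, 1)) i else j,
                 " is monomorphic", class = "delcall_undefined_ld")
  }
  p11 <- mean(a == 1 & b == 1)
  d <- p11 - pa * pb
  qa <- 1 - pa; qb <- 1 - pb
  r <- d / sqrt(pa * qa * pb * qb)
  dmax <- if (d > 0) min(pa * qb, qa * pb) else min(pa * pb, qa * qb)
  dprime <- if (d == 0) 0 else d / dmax
  structure(list(r = r, r2 = r^2, dprime = dprime), class = "ld_result")
}

#' LD profile of every variant against a focal variant
#'
#' @param panel a [haplotype_panel()].
#' @param focal_index focal variant column.
#' @return data frame ordered by position: `variant_id`, `positions_bp`, `r`,
#'   `r2`, `dprime`, `reason` (`NA` unless LD was undefined for that variant).
#' @export
ld_profile <- function(panel, focal_index = panel$del_index) {
  pf <- mean(panel$alleles[, focal_index])
  assert_that(!(pf %in% c(0, 1)), "focal variant is monomorphic")
  others <- setdiff(seq_along(panel$variant_ids), focal_index)
  rows <- lapply(others, function(j) {
    ld <- tryCatch(pairwise_ld(panel, focal_index, j),
                   delcall_undefined_ld = function(e) NULL)
    if (is.null(ld)) {
      data.frame(variant_id = panel$variant_ids[j],
                 positions_bp = panel$positions_bp[j],
                 r = NA_real_, r2 = NA_real_, dprime = NA_real_,
                 reason = "monomorphic", stringsAsFactors = FALSE)
    } else {
      data.frame(variant_id = panel$variant_ids[j],
                 positions_bp = panel$positions_bp[j],
                 r = ld$r, r2 = ld$r2, dprime = ld$dprime,
                 reason = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$positions_bp), , drop = FALSE]
}

# homozygosity of a grouping: sum over distinct classes of C(n_h, 2) / C(n, 2)
pair_homozygosity <- function(group_ids) {
  n <- length(group_ids)
  cnt <- table(group_ids)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity around a focal allele
#'
#' For chromosomes carrying `allele` at the focal variant, EHH at variant `j`
#' is the probability that two randomly drawn carrier chromosomes are
#' identical over all variants between the focal variant and `j` (inclusive):
#' `EHH(j) = sum_h C(n_h, 2) / C(n_A, 2)` over distinct extended haplotypes.
#' Computed outward in both directions; `EHH = 1` at the focal variant.
#'
#' @param panel a [haplotype_panel()].
#' @param focal_index focal variant column.
#' @param allele focal allele, 0 or 1.
#' @return an `ehh_curve` data frame: `variant_id`, `positions_bp`, `ehh`.
#' @export
ehh <- function(panel, focal_index = panel$del_index, allele = 1L) {
  carriers <- panel$alleles[, focal_index] == allele
  assert_that(sum(carriers) >= 2, "fewer than 2 chromosomes carry the focal allele")
  a <- panel$alleles[carriers, , drop = FALSE]
  m <- ncol(a)
  vals <- numeric(m)
  vals[focal_index] <- 1
  # extend right
  key <- rep("", nrow(a))
  if (focal_index < m) for (j in (focal_index + 1):m) {
    key <- paste0(key, a[, j])
    vals[j] <- pair_homozygosity(key)
  }
  key <- rep("", nrow(a))
  if (focal_index > 1) for (j in (focal_index - 1):1) {
    key <- paste0(key, a[, j])
    vals[j] <- pair_homozygosity(key)
  }
  structure(data.frame(variant_id = panel$variant_ids,
                       positions_bp = panel$positions_bp,
                       ehh = vals, stringsAsFactors = FALSE),
            class = c("ehh_curve", "data.frame"))
}

#' Haplotype spectrum over a variant window
#'
#' @param panel a [haplotype_panel()].
#' @param window integer vector of variant columns (default: all).
#' @return a `haplotype_spectrum`: data frame `haplotype`, `count`, `freq`,
#'   `carrier_fraction` (fraction of the chromosomes with that haplotype that
#'   carry the deletion allele), sorted by decreasing count; attribute
#'   `"n_chromosomes"`.
#' @export
haplotype_spectrum <- function(panel, window = seq_along(panel$variant_ids)) {
  assert_that(length(window) >= 1, "window must be non-empty")
  a <- panel$alleles[, window, drop = FALSE]
  strings <- apply(a, 1, paste0, collapse = "")
  del <- panel$alleles[, panel$del_index]
  cnt <- table(strings)
  carrier <- tapply(del, strings, mean)
  out <- data.frame(haplotype = names(cnt), count = as.integer(cnt),
                    freq = as.integer(cnt) / length(strings),
                    carrier_fraction = as.numeric(carrier[names(cnt)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_chromosomes") <- length(strings)
  class(out) <- c("haplotype_spectrum", "data.frame")
  out
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased haplotype diversity `Hd = n (1 - sum p_i^2) / (n - 1)` for
#' `n` chromosomes with distinct-haplotype frequencies `p_i`.
#'
#' @param spectrum a [haplotype_spectrum()].
#' @return diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(spectrum) {
  n <- attr(spectrum, "n_chromosomes")
  assert_that(!is.null(n) && n >= 2, "need at least 2 chromosomes")
  n * (1 - sum(spectrum$freq^2)) / (n - 1)
}

#' Tajima's D over a variant window
#'
#' Standard formulation: pairwise nucleotide diversity `pi` versus Watterson's
#' estimator from the number of segregating sites `S`, normalised with the
#' usual a1, a2, b1, b2, c1, c2, e1, e2 constants.
#'
#' @param panel a [haplotype_panel()].
#' @param window variant columns to use (default: all).
#' @return Tajima's D.
#' @export
tajimas_d <- function(panel, window = seq_along(panel$variant_ids)) {
  a <- panel$alleles[, window, drop = FALSE]
  n <- nrow(a)
  assert_that(n >= 4, "need at least 4 chromosomes")
  p <- colMeans(a)
  seg <- p > 0 & p < 1
  s <- sum(seg)
  if (s == 0) stop_delcall("Tajima's D undefined: no segregating sites",
                           class = "delcall_undefined_stat")
  # mean pairwise difference: sum over sites of 2 * k * (n - k) / (n(n-1))
  k <- colSums(a[, seg, drop = FALSE])
  pi_hat <- sum(2 * k * (n - k)) / (n * (n - 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Agglomerative clustering of distinct haplotypes
#'
#' Clusters the distinct haplotype strings of a spectrum on Hamming distance.
#' Each leaf is annotated with its deletion-carrier fraction.
#'
#' @param spectrum a [haplotype_spectrum()].
#' @param linkage_method linkage passed to [stats::hclust()].
#' @return a `haplotype_dendrogram` list: `hclust` (or `NULL` for a single
#'   distinct haplotype), `leaves` (the spectrum), `linkage`, `distance`.
#' @export
cluster_haplotypes <- function(spectrum, linkage_method = "complete") {
  k <- nrow(spectrum)
  if (k < 2) {
    return(structure(list(hclust = NULL, leaves = spectrum,
                          linkage = linkage_method, distance = "hamming"),
                     class = "haplotype_dendrogram"))
  }
  mat <- do.call(rbind, lapply(strsplit(spectrum$haplotype, ""), as.integer))
  dmat <- as.matrix(stats::dist(mat, method = "manhattan"))  # Hamming on 0/1
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage_method)
  hc$labels <- spectrum$haplotype
  structure(list(hclust = hc, leaves = spectrum,
                 linkage = linkage_method, distance = "hamming"),
            class = "haplotype_dendrogram")
}

#' @export
print.haplotype_dendrogram <- function(x, ...) {
  cat("haplotype_dendrogram:", nrow(x$leaves), "distinct haplotypes,",
      x$linkage, "linkage on", x$distance, "distance\n")
  invisible(x)
}
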