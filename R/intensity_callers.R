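# Callers operating directly on summed probe intensities s = x + y, plus the
# group-difference statistics used to demonstrate dosage dependence.

#' Automatic density cut-offs for a summed-intensity distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule by default) and takes the
#' two most prominent interior local minima as the class cut-offs C1 < C2
#' (deletion homozygote / heterozygote / wild type). When fewer than two
#' minima exist, shoulder detection via sign changes of the numerical second
#' derivative is used as a fallback. Returns a not-found object when neither
#' yields two points.
#'
#' @param s_values summed intensities for one probe (>= 50 samples).
#' @param bandwidth_rule bandwidth passed to [stats::density()] (`"nrd0"` is
#'   Silverman's rule).
#' @return a `density_cutoffs` list: `found`, `c1`, `c2`, `method`
#'   (`"minima"`, `"shoulder"` or `"none"`).
#' @export
density_cutoffs <- function(s_values, bandwidth_rule = "nrd0") {
  assert_that(length(s_values) >= 50, "need at least 50 samples")
  not_found <- structure(list(found = FALSE, c1 = NA_real_, c2 = NA_real_,
                              method = "none"), class = "density_cutoffs")
  if (stats::sd(s_values) == 0) return(not_found)
  d <- stats::density(s_values, bw = bandwidth_rule, n = 1024)
  y <- d$y; x <- d$x
  dx <- x[2] - x[1]

  # Mixture components appear as concave segments of the KDE (negative second
  # derivative, i.e. the regions between sign changes of y''). Sampling noise
  # fractures a single mode into adjacent concave fragments, so fragments
  # separated by less than two bandwidths are merged, and merged bumps holding
  # under 5% of the probability mass are discarded. Troughs fall out as the
  # density minimum between two bump peaks; a shoulder is the same cut point
  # when the density is monotone between the peaks.
  d2 <- diff(y, differences = 2)
  r <- rle(d2 < 0)
  seg_end <- cumsum(r$lengths) + 1L
  seg_start <- seg_end - r$lengths + 1L
  segs <- cbind(start = seg_start[r$values], end = seg_end[r$values])
  if (nrow(segs) == 0) return(not_found)
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) for (i in 2:nrow(segs)) {
    gap_x <- (segs[i, "start"] - merged[nrow(merged), "end"]) * dx
    if (gap_x < 2 * d$bw) {
      merged[nrow(merged), "end"] <- segs[i, "end"]
    } else {
      merged <- rbind(merged, segs[i, , drop = FALSE])
    }
  }
  mass <- apply(merged, 1, function(sg) sum(y[sg[1]:sg[2]])) / sum(y)
  bumps <- merged[mass >= 0.05, , drop = FALSE]
  if (nrow(bumps) < 3) return(not_found)
  if (nrow(bumps) > 3) {
    bumps <- bumps[order(-mass[mass >= 0.05])[1:3], , drop = FALSE]
    bumps <- bumps[order(bumps[, "start"]), , drop = FALSE]
  }
  peaks <- apply(bumps, 1, function(sg) sg[1] - 1L + which.max(y[sg[1]:sg[2]]))
  dy <- diff(y)
  cut_idx <- vapply(1:2, function(i) {
    span <- (peaks[i] + 1L):(peaks[i + 1] - 1L)
    j <- span[which.min(y[span])]
    # a trough (interior local minimum of the density) is the cut point
    if (y[j] <= y[j - 1] && y[j] <= y[j + 1] &&
        j > min(span) && j < max(span)) return(j)
    # monotone stretch: the shoulder sits between the inflection closing the
    # smaller bump and the interior slope extremum (a dip while rising, a
    # bump while falling); their midpoint tracks the visual kink well
    inner <- span[span > min(span) + 2 & span < max(span) - 2]
    rising <- y[max(span)] > y[min(span)]
    ext <- if (rising) {
      inner[dy[inner - 1] > dy[inner] & dy[inner + 1] > dy[inner]]
    } else {
      inner[dy[inner - 1] < dy[inner] & dy[inner + 1] < dy[inner]]
    }
    slope_pt <- if (!length(ext)) NA_integer_
                else if (rising) ext[which.min(dy[ext])]
                else ext[which.max(dy[ext])]
    inflection <- if (rising) bumps[i, "end"] else bumps[i + 1, "start"]
    as.integer(round(mean(c(inflection, slope_pt), na.rm = TRUE)))
  }, 0L)
  is_local_min <- vapply(cut_idx, function(i) {
    y[i] <= y[i - 1] && y[i] <= y[i + 1]
  }, TRUE)
  structure(list(found = TRUE, c1 = x[cut_idx[1]], c2 = x[cut_idx[2]],
                 method = if (all(is_local_min)) "minima" else "shoulder"),
            class = "density_cutoffs")
}

#' Genotype call from summed intensity and two cut-offs
#'
#' Exact mapping: deletion homozygote for `s <= C1`; heterozygote for
#' `C1 < s < C2`; wild type for `s >= C2`. Boundary values go to the
#' homozygote (at C1) and wild type (at C2) respectively, and every real `s`
#' maps to exactly one genotype.
#'
#' @param s numeric summed intensities.
#' @param cutoffs a `density_cutoffs` (or list with `c1 < c2`).
#' @return integer genotypes: 0 = WT, 1 = het, 2 = deletion homozygote.
#' @export
call_by_cutoffs <- function(s, cutoffs) {
  assert_that(is.finite(cutoffs$c1) && is.finite(cutoffs$c2) &&
                cutoffs$c1 < cutoffs$c2, "invalid cut-offs (need c1 < c2)")
  ifelse(s <= cutoffs$c1, 2L, ifelse(s < cutoffs$c2, 1L, 0L))
}

#' Hierarchical-clustering genotype caller
#'
#' Standardises each probe's summed intensity, clusters samples
#' agglomeratively (complete linkage, Euclidean distance, heatmap-style
#' defaults), cuts the tree into `n_clusters` groups and labels clusters by
#' ascending cluster-mean summed intensity: lowest = deletion homozygote,
#' highest = wild type.
#'
#' @param intens an `intensity_table`.
#' @param probes probe ids (or column indices) to use; defaults to all probes
#'   inside the deletion.
#' @param n_clusters number of clusters (3 genotype classes).
#' @param linkage_method linkage for [stats::hclust()].
#' @return list `calls` (integer vector 0/1/2), `hclust`, `probes`, `linkage`.
#' @export
hierarchical_call <- function(intens, probes = NULL, n_clusters = 3,
                              linkage_method = "complete") {
  cols <- if (is.null(probes)) deletion_probe_cols(intens)
          else if (is.numeric(probes)) probes
          else match(probes, intens$probes$probe_id)
  assert_that(!anyNA(cols), "unknown probe id")
  assert_that(length(cols) >= 2, "need at least 2 probes")
  s <- intens$s[, cols, drop = FALSE]
  assert_that(nrow(s) >= n_clusters, "need at least ", n_clusters, " samples")
  z <- scale(s)
  z[, attr(z, "scaled:scale") == 0] <- 0
  hc <- stats::hclust(stats::dist(z), method = linkage_method)
  grp <- stats::cutree(hc, k = n_clusters)
  mean_s <- tapply(rowMeans(s), grp, mean)
  # ascending mean s -> genotypes 2 (hom del), 1 (het), 0 (WT)
  ord <- order(mean_s)
  relabel <- integer(n_clusters)
  relabel[ord] <- rev(seq_len(n_clusters)) - 1L  # lowest mean -> highest code
  calls <- relabel[grp]
  list(calls = as.integer(calls), hclust = hc,
       probes = intens$probes$probe_id[cols], linkage = linkage_method)
}

#' Per-probe genotype-group intensity statistics
#'
#' Kruskal-Wallis test (tie corrected) across genotype groups, Dunn's pairwise
#' z tests with pooled tie-corrected rank variance (unadjusted and
#' Bonferroni-adjusted p values), and Cohen's d / Hedges' g per pair:
#' `d = (m1 - m2) / s_pooled`, `g = d * (1 - 3 / (4 (n1 + n2) - 9))`.
#'
#' @param s_values summed intensities for one probe.
#' @param true_genotypes integer genotypes 0/1/2 (groups with n = 0 dropped
#'   with a warning).
#' @return an `intensity_group_stats` list: `kruskal` (statistic, p),
#'   `pairwise` data frame (group1, group2, z, p, p_bonferroni, cohens_d,
#'   hedges_g).
#' @export
group_difference_tests <- function(s_values, true_genotypes) {
  g <- if (is.factor(true_genotypes)) true_genotypes
       else factor(true_genotypes, levels = sort(unique(true_genotypes)))
  present <- levels(g)[table(g) > 0]
  if (length(present) < length(levels(g))) {
    warning("dropping empty genotype group(s)")
    g <- factor(as.character(g), levels = present)
  }
  assert_that(nlevels(g) >= 2, "need at least 2 non-empty groups")
  kw <- stats::kruskal.test(s_values, g)

  n_tot <- length(s_values)
  rk <- rank(s_values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pooled_var <- n_tot * (n_tot + 1) / 12 - tie_corr
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)

  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pp) {
    i <- pp[1]; j <- pp[2]
    z <- (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt(pooled_var * (1 / n_g[[i]] + 1 / n_g[[j]]))
    p <- 2 * stats::pnorm(-abs(z))
    xi <- s_values[g == i]; xj <- s_values[g == j]
    sp <- sqrt(((length(xi) - 1) * stats::var(xi) +
                  (length(xj) - 1) * stats::var(xj)) /
                 (length(xi) + length(xj) - 2))
    d <- (mean(xi) - mean(xj)) / sp
    gg <- d * (1 - 3 / (4 * (length(xi) + length(xj)) - 9))
    data.frame(group1 = i, group2 = j, z = z, p = p,
               cohens_d = d, hedges_g = gg, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- pmin(1, pw$p * nrow(pw))
  structure(list(kruskal = list(statistic = unname(kw$statistic),
                                p = kw$p.value),
                 pairwise = pw),
            class = "intensity_group_stats")
}
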