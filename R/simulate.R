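# Synthetic cohort generator. Emulates the statistical structure of a SNP-array
# case-control study around a recurrent short deletion: phased flanking
# haplotypes with low deletion LD (the deletion arises on several founder
# backgrounds), dosage-dependent two-channel probe intensities with heavily
# overlapping class distributions, and a protective case-control association
# confounded by sex, ethnicity and an independent strongly protective locus.

#' Simulation configuration
#'
#' Builds and validates the configuration driving [simulate_dataset()] and its
#' component generators. Defaults reproduce the study-scale cohort: 3036
#' individuals, 178 flanking SNPs, 6 probes inside the deletion, deletion
#' allele frequency 2320/6072, and the deletion present on 8 independent
#' founder backgrounds so that max r^2 with any flanking SNP stays low.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_flank_snps number of flanking SNPs in the haplotype panel.
#' @param n_del_probes number of array probes inside the deletion.
#' @param n_control_probes number of flanking control probes (intensities
#'   independent of deletion genotype).
#' @param del_freq deletion allele frequency in `[0, 1]`.
#' @param n_del_origins number of independent founder backgrounds carrying the
#'   deletion; 1 gives a single-origin (high-LD) variant, 8 the recurrent
#'   low-LD regime.
#' @param n_founders number of founder haplotypes for the mosaic-copying
#'   simulator.
#' @param n_generations scales mosaic switch probability per Morgan; larger
#'   values break up founder haplotypes faster.
#' @param site_noise per-site allele flip probability emulating array/phasing
#'   error (never applied to the deletion column).
#' @param recomb_rate_cM_per_Mb uniform recombination rate used to build the
#'   default map when `recomb_map` is `NULL`.
#' @param recomb_map optional [recomb_map()] overriding the uniform default.
#' @param region_bp 2-vector, physical span of the simulated region.
#' @param del_position_bp physical position of the deletion variant.
#' @param intensity_params list with `mean_s`, `sd_s` (length-3 vectors indexed
#'   by copy number 0, 1, 2: means must be strictly increasing), `split_sd`
#'   (noise on the X/Y channel split) and `control_mean_s`, `control_sd_s`.
#' @param pheno_params list with `baseline_case_prob` (case probability for a
#'   WT reference individual), `or_het`, `or_hom` (per-genotype odds ratios),
#'   `or_sex`, `or_ethnicity` (named, first entry is the reference), `or_rs334`
#'   (per allele), `male_freq`, `ethnicity_freq` (named), `rs334_freq`.
#' @param seed integer master seed; all randomness flows from it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 3036,
                       n_flank_snps = 178,
                       n_del_probes = 6,
                       n_control_probes = 3,
                       del_freq = 2320 / 6072,
                       n_del_origins = 8,
                       n_founders = 60,
                       n_generations = 300,
                       site_noise = 0.002,
                       recomb_rate_cM_per_Mb = 1.5,
                       recomb_map = NULL,
                       region_bp = c(84870, 398421),
                       del_position_bp = 225818,
                       intensity_params = NULL,
                       pheno_params = NULL,
                       seed = 1L) {
  intensity_params <- utils::modifyList(list(
    mean_s = c(0.12, 0.40, 0.75),  # copy number 0 (hom del), 1 (het), 2 (WT)
    sd_s = c(0.10, 0.12, 0.14),
    split_sd = 0.08,
    control_mean_s = 0.90,
    control_sd_s = 0.12,
    control_maf = 0.30
  ), intensity_params %||% list())
  pheno_params <- utils::modifyList(list(
    baseline_case_prob = 0.55,
    or_het = 0.79,
    or_hom = 0.59,
    or_sex = 1.1,
    or_ethnicity = c(Giriama = 1, Chonyi = 0.9, Kauma = 1.1, Other = 1.0),
    or_rs334 = 0.25,
    male_freq = 0.508,
    ethnicity_freq = c(Giriama = 0.492, Chonyi = 0.312, Kauma = 0.089,
                       Other = 0.107),
    rs334_freq = 0.054
  ), pheno_params %||% list())

  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_flank_snps = as.integer(n_flank_snps),
    n_del_probes = as.integer(n_del_probes),
    n_control_probes = as.integer(n_control_probes),
    del_freq = del_freq,
    n_del_origins = as.integer(n_del_origins),
    n_founders = as.integer(n_founders),
    n_generations = n_generations,
    site_noise = site_noise,
    recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    recomb_map = recomb_map,
    region_bp = as.numeric(region_bp),
    del_position_bp = as.numeric(del_position_bp),
    intensity_params = intensity_params,
    pheno_params = pheno_params,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_individuals >= 1, "n_individuals must be >= 1")
  assert_prob(cfg$del_freq, "del_freq")
  assert_that(cfg$n_del_origins >= 1, "n_del_origins must be >= 1")
  assert_that(cfg$n_del_origins <= cfg$n_founders,
              "invalid config: n_del_origins (", cfg$n_del_origins,
              ") exceeds n_founders (", cfg$n_founders, ")",
              class = "delcall_invalid_config")
  assert_that(cfg$n_flank_snps >= cfg$n_founders,
              "n_flank_snps must be >= n_founders (one tag SNP per founder)")
  ip <- cfg$intensity_params
  assert_that(length(ip$mean_s) == 3 && all(diff(ip$mean_s) > 0),
              "invalid config: intensity mean_s must be strictly increasing ",
              "with copy number", class = "delcall_invalid_config")
  assert_that(all(ip$sd_s >= 0), "intensity sd_s must be non-negative")
  pp <- cfg$pheno_params
  assert_that(all(c(pp$or_het, pp$or_hom, pp$or_rs334) > 0),
              "odds ratios must be > 0")
  assert_prob(pp$baseline_case_prob, "baseline_case_prob")
  assert_that(abs(sum(pp$ethnicity_freq) - 1) < 1e-8,
              "ethnicity_freq must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "individuals,",
      x$n_flank_snps, "flanking SNPs + deletion,",
      x$n_del_origins, "deletion origin(s), del_freq =",
      signif(x$del_freq, 4), "\n")
  invisible(x)
}

#' Recombination map
#'
#' @param positions_bp physical positions (strictly increasing).
#' @param rate_cM_per_Mb non-negative local rates.
#' @param cumulative_cM non-decreasing cumulative map; computed from the rates
#'   when omitted.
#' @return a `recomb_map` data frame.
#' @export
recomb_map <- function(positions_bp, rate_cM_per_Mb, cumulative_cM = NULL) {
  assert_that(all(diff(positions_bp) > 0),
              "recomb map positions must be strictly increasing")
  assert_that(all(rate_cM_per_Mb >= 0), "recombination rates must be >= 0")
  assert_that(length(positions_bp) == length(rate_cM_per_Mb),
              "recomb map field lengths differ")
  if (is.null(cumulative_cM)) {
    d_mb <- diff(positions_bp) / 1e6
    cumulative_cM <- c(0, cumsum(d_mb * rate_cM_per_Mb[-length(rate_cM_per_Mb)]))
  }
  assert_that(length(cumulative_cM) == length(positions_bp),
              "recomb map field lengths differ")
  assert_that(all(diff(cumulative_cM) >= -1e-12),
              "cumulative_cM must be non-decreasing")
  structure(data.frame(positions_bp = positions_bp,
                       rate_cM_per_Mb = rate_cM_per_Mb,
                       cumulative_cM = cumulative_cM),
            class = c("recomb_map", "data.frame"))
}

#' Phased haplotype panel
#'
#' @param alleles 0/1 matrix, rows = chromosomes (two consecutive rows per
#'   individual), columns = variants.
#' @param variant_ids unique variant identifiers.
#' @param positions_bp strictly increasing 1-based physical positions.
#' @param del_index column index of the deletion variant (allele 1 = deletion).
#' @return a `haplotype_panel` object.
#' @export
haplotype_panel <- function(alleles, variant_ids, positions_bp, del_index) {
  alleles <- as.matrix(alleles)
  assert_that(nrow(alleles) %% 2 == 0, "chromosome count must be even")
  assert_that(all(alleles %in% c(0L, 1L)), "alleles must be 0/1")
  assert_that(ncol(alleles) == length(variant_ids) &&
                ncol(alleles) == length(positions_bp),
              "panel dimensions disagree with variant metadata")
  assert_that(!anyDuplicated(variant_ids), "variant_ids must be unique")
  assert_that(all(diff(positions_bp) > 0),
              "positions must be strictly increasing")
  assert_that(del_index >= 1 && del_index <= ncol(alleles),
              "del_index out of range")
  storage.mode(alleles) <- "integer"
  colnames(alleles) <- variant_ids
  structure(list(alleles = alleles,
                 variant_ids = as.character(variant_ids),
                 positions_bp = as.numeric(positions_bp),
                 del_index = as.integer(del_index)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "chromosomes (",
      nrow(x$alleles) / 2, "individuals ) x", ncol(x$alleles),
      "variants; deletion at column", x$del_index, "(",
      x$variant_ids[x$del_index], ")\n")
  invisible(x)
}

n_chromosomes <- function(panel) nrow(panel$alleles)
n_individuals_panel <- function(panel) nrow(panel$alleles) %/% 2L

# Variant positions for the simulated region: flanking SNPs spread evenly (with
# jitter) over the region, deletion inserted at its stated position.
simulate_positions <- function(cfg) {
  span <- cfg$region_bp
  raw <- seq(span[1], span[2], length.out = cfg$n_flank_snps + 2)[-c(1, cfg$n_flank_snps + 2)]
  jitter_bp <- diff(span) / (cfg$n_flank_snps + 1) * 0.3
  pos <- sort(round(raw + stats::runif(cfg$n_flank_snps, -jitter_bp, jitter_bp)))
  pos <- pos[abs(pos - cfg$del_position_bp) > 1]  # keep deletion position free
  while (any(diff(pos) <= 0)) pos[which(diff(pos) <= 0) + 1] <- pos[which(diff(pos) <= 0) + 1] + 1
  pos
}

default_recomb_map <- function(cfg, positions_bp) {
  if (!is.null(cfg$recomb_map)) return(cfg$recomb_map)
  recomb_map(positions_bp, rep(cfg$recomb_rate_cM_per_Mb, length(positions_bp)))
}

# Founder haplotypes: neutral-ish frequency spectrum P(k) ~ 1/k over founder
# carrier counts, plus one private "tag" SNP per founder at the SNPs nearest
# the deletion. Tags make founder identity locally recoverable, which is what
# gives a single-origin deletion near-perfect flanking LD while a recurrent
# deletion (8 origins) structurally caps max r^2 near
# p(1-q) / (q(1-p)) for per-origin frequency p and deletion frequency q.
simulate_founders <- function(cfg, snp_positions) {
  nf <- cfg$n_founders
  m <- length(snp_positions)
  k_probs <- (1 / seq_len(nf - 1))
  k_probs <- k_probs / sum(k_probs)
  founders <- matrix(0L, nf, m)
  for (j in seq_len(m)) {
    k <- sample.int(nf - 1, 1, prob = k_probs)
    founders[sample.int(nf, k), j] <- 1L
  }
  # private tags on the SNPs closest to the deletion, one per founder
  tag_cols <- order(abs(snp_positions - cfg$del_position_bp))[seq_len(nf)]
  for (f in seq_len(nf)) {
    founders[, tag_cols[f]] <- 0L
    founders[f, tag_cols[f]] <- 1L
  }
  list(alleles = founders, tag_cols = tag_cols)
}

#' Simulate a phased haplotype panel carrying a recurrent deletion
#'
#' Chromosomes are mosaics of founder haplotypes with switch probability
#' `1 - exp(-n_generations * d)` per inter-marker map distance `d` (Morgans).
#' The deletion allele rides on `n_del_origins` founder backgrounds whose
#' combined copying weight equals `del_freq`, so the expected allele frequency
#' is `del_freq` while flanking LD is controlled by the number of origins.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()]; attribute `"map"` holds the recombination
#'   map used.
#' @export
simulate_haplotype_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    snp_pos <- simulate_positions(cfg)
    fnd <- simulate_founders(cfg, snp_pos)

    # splice deletion column into the variant grid
    del_at <- findInterval(cfg$del_position_bp, snp_pos) + 1L
    positions <- append(snp_pos, cfg$del_position_bp, after = del_at - 1L)
    m <- length(positions)
    founder_all <- matrix(0L, cfg$n_founders, m)
    founder_all[, -del_at] <- fnd$alleles
    carriers <- seq_len(cfg$n_del_origins)
    founder_all[carriers, del_at] <- 1L

    # founder copying weights: carriers share del_freq, the rest share 1 - del_freq
    w <- rep((1 - cfg$del_freq) / (cfg$n_founders - cfg$n_del_origins),
             cfg$n_founders)
    if (cfg$n_del_origins == cfg$n_founders) w <- rep(0, cfg$n_founders)
    w[carriers] <- cfg$del_freq / cfg$n_del_origins

    map <- default_recomb_map(cfg, positions)
    c_morgans <- diff(map$cumulative_cM) / 100
    p_switch <- 1 - exp(-cfg$n_generations * c_morgans)

    n_chr <- 2L * cfg$n_individuals
    state <- sample.int(cfg$n_founders, n_chr, replace = TRUE, prob = w)
    alleles <- matrix(0L, n_chr, m)
    alleles[, 1] <- founder_all[state, 1]
    for (j in 2:m) {
      sw <- stats::runif(n_chr) < p_switch[j - 1]
      if (any(sw)) {
        state[sw] <- sample.int(cfg$n_founders, sum(sw), replace = TRUE, prob = w)
      }
      alleles[, j] <- founder_all[state, j]
    }

    if (cfg$site_noise > 0) {
      flip <- matrix(stats::runif(n_chr * m) < cfg$site_noise, n_chr, m)
      flip[, del_at] <- FALSE
      alleles[flip] <- 1L - alleles[flip]
    }

    ids <- character(m)
    ids[-del_at] <- sprintf("snp%03d", seq_len(m - 1L))
    ids[del_at] <- "DEL3.7"
    panel <- haplotype_panel(alleles, ids, positions, del_at)
    attr(panel, "map") <- map
    panel
  })
}

#' Collapse phased chromosomes into diploid genotypes
#'
#' Consecutive chromosome pairs (2i-1, 2i) form individual i; the genotype is
#' the allele sum, so the deletion column counts deletion alleles (0/1/2).
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix individuals x variants with attribute
#'   `"del_index"`.
#' @export
pair_into_diploids <- function(panel) {
  assert_that(inherits(panel, "haplotype_panel"), "panel must be a haplotype_panel")
  a <- panel$alleles
  g <- a[seq(1, nrow(a), by = 2), , drop = FALSE] +
    a[seq(2, nrow(a), by = 2), , drop = FALSE]
  rownames(g) <- sprintf("ind%04d", seq_len(nrow(g)))
  attr(g, "del_index") <- panel$del_index
  g
}

#' Extract the deletion-genotype column from a diploid genotype matrix
#'
#' @param genotypes matrix from [pair_into_diploids()] (carries a
#'   `del_index` attribute).
#' @return integer vector of deletion genotypes 0/1/2.
#' @export
deletion_genotypes <- function(genotypes) {
  di <- attr(genotypes, "del_index")
  assert_that(!is.null(di), "genotype matrix lacks a del_index attribute")
  genotypes[, di]
}

#' Simulate two-channel probe intensities
#'
#' Probes inside the deletion draw the summed intensity `s = x + y` from a
#' normal whose mean/sd depend on copy number `2 - genotype` (means strictly
#' increasing with copy number); `s` is split into channels by a noisy
#' per-sample allele ratio. Flanking control probes get genotype-independent
#' three-cluster SNP intensities. Negative draws are truncated at zero.
#'
#' @param genotypes matrix from [pair_into_diploids()], or an integer vector of
#'   deletion genotypes.
#' @param config a [sim_config()].
#' @return an `intensity_table`: list with `probes` (data frame: `probe_id`,
#'   `in_deletion`), matrices `x`, `y`, `s` (individuals x probes) and
#'   `individual_id`.
#' @export
simulate_intensities <- function(genotypes, config) {
  validate_sim_config(config)
  cfg <- config
  g_del <- if (is.matrix(genotypes)) deletion_genotypes(genotypes) else as.integer(genotypes)
  assert_that(all(g_del %in% 0:2), "deletion genotypes must be 0/1/2")
  n <- length(g_del)
  ip <- cfg$intensity_params
  copy_number <- 2L - g_del

  with_seed(cfg$seed + 1L, {
    np <- cfg$n_del_probes + cfg$n_control_probes
    probe_id <- c(sprintf("delprobe%02d", seq_len(cfg$n_del_probes)),
                  sprintf("ctrlprobe%02d", seq_len(cfg$n_control_probes)))
    in_deletion <- rep(c(TRUE, FALSE), c(cfg$n_del_probes, cfg$n_control_probes))
    x <- y <- s <- matrix(0, n, np, dimnames = list(
      sprintf("ind%04d", seq_len(n)), probe_id))

    # truncated-normal draws on [0, Inf): intensities are non-negative and a
    # clamp would put a spurious point mass at exactly zero
    rnorm_pos <- function(n, mean, sd) {
      lo <- stats::pnorm(0, mean, sd)
      stats::qnorm(stats::runif(n, lo, 1), mean, sd)
    }
    for (k in seq_len(cfg$n_del_probes)) {
      sk <- rnorm_pos(n, ip$mean_s[copy_number + 1L], ip$sd_s[copy_number + 1L])
      frac <- pmin(pmax(stats::rnorm(n, 0.5, ip$split_sd), 0), 1)
      x[, k] <- sk * frac
      y[, k] <- sk * (1 - frac)
      s[, k] <- sk
    }
    for (k in seq_len(cfg$n_control_probes)) {
      col <- cfg$n_del_probes + k
      gg <- stats::rbinom(n, 2, ip$control_maf)  # probe's own SNP genotype
      sk <- rnorm_pos(n, ip$control_mean_s, ip$control_sd_s)
      frac <- pmin(pmax(gg / 2 + stats::rnorm(n, 0, ip$split_sd / 2), 0), 1)
      x[, col] <- sk * frac
      y[, col] <- sk * (1 - frac)
      s[, col] <- sk
    }
    structure(list(individual_id = rownames(x),
                   probes = data.frame(probe_id = probe_id,
                                       in_deletion = in_deletion,
                                       stringsAsFactors = FALSE),
                   x = x, y = y, s = s),
              class = "intensity_table")
  })
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x$s), "individuals x", ncol(x$s), "probes (",
      sum(x$probes$in_deletion), "inside the deletion )\n")
  invisible(x)
}

# Subset of columns for probes inside the deletion.
deletion_probe_cols <- function(intens) which(intens$probes$in_deletion)

#' Simulate case-control phenotypes and covariates
#'
#' Case status follows a logistic model: logit(baseline) + log-OR(het) I(g=1) +
#' log-OR(hom) I(g=2) + covariate effects for sex, ethnicity and an
#' independently segregating strongly protective biallelic locus (an rs334-like
#' confounder, coded as allele dosage).
#'
#' @inheritParams simulate_intensities
#' @return a `phenotype_table` data frame: `individual_id`, `status` (1 =
#'   case), `sex` (1 = male), `ethnicity` (factor), `rs334_genotype` (0/1/2).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  cfg <- config
  g_del <- if (is.matrix(genotypes)) deletion_genotypes(genotypes) else as.integer(genotypes)
  n <- length(g_del)
  pp <- cfg$pheno_params

  with_seed(cfg$seed + 2L, {
    sex <- stats::rbinom(n, 1, pp$male_freq)
    eth <- factor(sample(names(pp$ethnicity_freq), n, replace = TRUE,
                         prob = pp$ethnicity_freq),
                  levels = names(pp$ethnicity_freq))
    rs334 <- stats::rbinom(n, 2, pp$rs334_freq)
    lp <- stats::qlogis(pp$baseline_case_prob) +
      log(pp$or_het) * (g_del == 1) +
      log(pp$or_hom) * (g_del == 2) +
      log(pp$or_sex) * sex +
      log(pp$or_ethnicity)[as.integer(eth)] +
      log(pp$or_rs334) * rs334
    status <- stats::rbinom(n, 1, stats::plogis(lp))
    structure(data.frame(individual_id = sprintf("ind%04d", seq_len(n)),
                         status = status, sex = sex, ethnicity = eth,
                         rs334_genotype = rs334, stringsAsFactors = FALSE),
              class = c("phenotype_table", "data.frame"))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper generating the haplotype panel, diploid genotypes,
#' probe intensities and phenotypes from one configuration.
#'
#' @param config a [sim_config()].
#' @return a `delcall_dataset` list: `config`, `panel`, `map`, `genotypes`,
#'   `intensities`, `phenotypes`.
#' @export
simulate_dataset <- function(config) {
  panel <- simulate_haplotype_panel(config)
  genotypes <- pair_into_diploids(panel)
  structure(list(config = config,
                 panel = panel,
                 map = attr(panel, "map"),
                 genotypes = genotypes,
                 intensities = simulate_intensities(genotypes, config),
                 phenotypes = simulate_phenotypes(genotypes, config)),
            class = "delcall_dataset")
}

#' @export
print.delcall_dataset <- function(x, ...) {
  print(x$panel)
  print(x$intensities)
  cat("phenotypes:", sum(x$phenotypes$status), "cases /",
      nrow(x$phenotypes), "individuals\n")
  invisible(x)
}
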