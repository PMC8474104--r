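# LD, EHH, haplotype spectra, Tajima's D, clustering: frozen oracle values and
# property-style invariants.

test_that("pairwise_ld matches the haplotype-counting oracle", {
  # counts AB=4, Ab=1, aB=1, ab=4 over 10 chromosomes: frozen from direct
  # counting: D = 0.4 - 0.25 = 0.15, r = 0.15/0.25 = 0.6, D' = 0.15/0.25
  p <- two_locus_panel(c(AB = 4, Ab = 1, aB = 1, ab = 4))
  ld <- pairwise_ld(p, 1, 2)
  expect_equal(ld$r, 0.6, tolerance = 1e-12)
  expect_equal(ld$r2, 0.36, tolerance = 1e-12)
  expect_equal(ld$dprime, 0.6, tolerance = 1e-12)

  # identical columns -> perfect LD
  p2 <- two_locus_panel(c(AB = 5, Ab = 0, aB = 0, ab = 5))
  ld2 <- pairwise_ld(p2, 1, 2)
  expect_equal(unlist(ld2[c("r", "r2", "dprime")]), c(r = 1, r2 = 1, dprime = 1))

  # a missing gamete class with D > 0 pins |D'| = 1
  p3 <- two_locus_panel(c(AB = 4, Ab = 3, aB = 0, ab = 3))
  expect_equal(abs(pairwise_ld(p3, 1, 2)$dprime), 1, tolerance = 1e-12)

  # monomorphic variant is an explicit error, not NaN
  p4 <- two_locus_panel(c(AB = 5, Ab = 5, aB = 0, ab = 0))
  expect_error(pairwise_ld(p4, 1, 2), class = "delcall_undefined_ld")
})

test_that("r2 equals squared Pearson correlation of the allele columns (property)", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      a <- rbind(matrix(rbinom(40, 1, 0.5), 20, 2))
      if (length(unique(a[, 1])) < 2 || length(unique(a[, 2])) < 2) next
      p <- haplotype_panel(a, c("A", "B"), c(1, 2), 1L)
      expect_equal(pairwise_ld(p, 1, 2)$r2, cor(a[, 1], a[, 2])^2,
                   tolerance = 1e-10)
    }
  })
})

test_that("D' and |r| are invariant under joint allele relabelling", {
  p <- two_locus_panel(c(AB = 6, Ab = 2, aB = 3, ab = 9))
  flipped <- haplotype_panel(1L - p$alleles, p$variant_ids, p$positions_bp, 1L)
  ld <- pairwise_ld(p, 1, 2)
  ldf <- pairwise_ld(flipped, 1, 2)
  expect_equal(ld$dprime, ldf$dprime, tolerance = 1e-12)
  expect_equal(ld$r, ldf$r, tolerance = 1e-12)
})

test_that("ld_profile covers all other variants and flags monomorphic ones", {
  p <- simulate_haplotype_panel(small_config(n = 150, seed = 13))
  prof <- ld_profile(p)
  expect_identical(nrow(prof), length(p$variant_ids) - 1L)
  mono <- prof$reason == "monomorphic" & !is.na(prof$reason)
  expect_true(all(is.na(prof$r2[mono])))
  expect_true(all(prof$r2[!mono] >= 0 & prof$r2[!mono] <= 1))
})

test_that("EHH: frozen pair-counting values and monotone decay", {
  # 4 carriers splitting 2/2 at the first flanking variant:
  # EHH = (C(2,2)+C(2,2))/C(4,2) = 2/6 = 1/3
  alleles <- rbind(
    c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
    c(0, 0, 0), c(0, 0, 0))
  p <- haplotype_panel(alleles, c("DEL", "v2", "v3"), c(1, 2, 3), 1L)
  curve <- ehh(p, focal_index = 1, allele = 1)
  expect_equal(curve$ehh[1], 1)
  expect_equal(curve$ehh[2], 1 / 3, tolerance = 1e-12)
  # all four extended haplotypes distinct at v3 -> EHH 0
  expect_equal(curve$ehh[3], 0)

  # identical carriers keep EHH at 1 everywhere
  ident <- haplotype_panel(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 0)),
                           c("DEL", "v2", "v3"), c(1, 2, 3), 1L)
  expect_true(all(ehh(ident, 1, 1)$ehh == 1))

  expect_error(ehh(ident, focal_index = 3, allele = 1), "fewer than 2")

  # property: non-increasing away from the focal variant on simulated panels
  for (s in 1:3) {
    ps <- simulate_haplotype_panel(small_config(n = 120, seed = 500 + s))
    cv <- ehh(ps)$ehh
    di <- ps$del_index
    expect_true(all(diff(cv[di:length(cv)]) <= 1e-12))
    expect_true(all(diff(rev(cv[1:di])) <= 1e-12))
  }
})

test_that("haplotype spectrum and diversity follow the frequency formula", {
  # counts (3, 1) over 4 chromosomes: Hd = 4 (1 - 10/16) / 3 = 0.5
  alleles <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1))
  p <- haplotype_panel(alleles, c("a", "b"), c(1, 2), 1L)
  sp <- haplotype_spectrum(p)
  expect_identical(sp$count, c(3L, 1L))
  expect_equal(sum(sp$freq), 1)
  expect_equal(haplotype_diversity(sp), 0.5, tolerance = 1e-12)

  # all identical -> 0; all distinct -> 1
  same <- haplotype_panel(matrix(1, 4, 2), c("a", "b"), c(1, 2), 1L)
  expect_equal(haplotype_diversity(haplotype_spectrum(same)), 0)
  dist4 <- haplotype_panel(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                           c("a", "b"), c(1, 2), 1L)
  expect_equal(haplotype_diversity(haplotype_spectrum(dist4)), 1)
})

test_that("Tajima's D matches an independent re-implementation", {
  # oracle: direct pairwise-difference scan, constants recomputed separately
  oracle_tajima <- function(a) {
    n <- nrow(a)
    diffs <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      diffs <- diffs + sum(a[i, ] != a[j, ])
    }
    pi_hat <- diffs / choose(n, 2)
    s <- sum(apply(a, 2, function(v) length(unique(v)) > 1))
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi_hat - s / a1) /
      sqrt((c1 / a1) * s + (c2 / (a1^2 + a2)) * s * (s - 1))
  }
  withr::with_seed(19, {
    a <- matrix(rbinom(12 * 8, 1, 0.4), 12, 8)
    a[, 3] <- 1  # include a monomorphic column
    p <- haplotype_panel(a, sprintf("v%d", 1:8), 1:8, 1L)
    expect_equal(tajimas_d(p), oracle_tajima(a), tolerance = 1e-12)
    # duplicating every chromosome changes D deterministically; both
    # implementations must agree on the duplicated panel too
    dup <- a[rep(1:12, each = 2), ]
    pd <- haplotype_panel(dup, sprintf("v%d", 1:8), 1:8, 1L)
    expect_equal(tajimas_d(pd), oracle_tajima(dup), tolerance = 1e-12)
  })
  mono <- haplotype_panel(matrix(1, 4, 3), c("a", "b", "c"), 1:3, 1L)
  expect_error(tajimas_d(mono), class = "delcall_undefined_stat")
})

test_that("near-neutral panmictic panels keep mean Tajima's D in a sane band", {
  vals <- sapply(1:10, function(s) {
    p <- simulate_haplotype_panel(small_config(n = 100, seed = 700 + s))
    tajimas_d(p)
  })
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("haplotype clustering annotates carriers and counts leaves", {
  p <- simulate_haplotype_panel(small_config(n = 80, seed = 23))
  sp <- haplotype_spectrum(p)
  dend <- cluster_haplotypes(sp)
  expect_identical(length(dend$hclust$order), nrow(sp))
  expect_true(all(sp$carrier_fraction >= 0 & sp$carrier_fraction <= 1))

  # two groups of identical haplotypes merge at height 0 within groups
  a <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), c(1, 1, 0), c(0, 1, 0))
  pg <- haplotype_panel(a, c("x", "y", "z"), 1:3, 1L)
  d2 <- cluster_haplotypes(haplotype_spectrum(pg))
  expect_identical(nrow(d2$leaves), 4L)

  # one distinct haplotype -> single-leaf tree, no hclust object
  one <- haplotype_panel(matrix(0, 4, 3), c("x", "y", "z"), 1:3, 1L)
  d1 <- cluster_haplotypes(haplotype_spectrum(one))
  expect_null(d1$hclust)
  expect_identical(nrow(d1$leaves), 1L)
})

test_that("carrier haplotypes occupy multiple subtrees under recurrent origins", {
  p <- simulate_haplotype_panel(small_config(n = 400, seed = 29,
                                             n_del_origins = 8))
  # cluster flanking haplotypes only (exclude the deletion column itself)
  win <- setdiff(seq_along(p$variant_ids), p$del_index)
  sp <- haplotype_spectrum(p, win)
  dend <- cluster_haplotypes(sp)
  grp <- stats::cutree(dend$hclust, k = 8)
  carrier_groups <- unique(grp[sp$carrier_fraction > 0.5])
  expect_gte(length(carrier_groups), 4)
})
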