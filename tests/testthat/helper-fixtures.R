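# Shared fixtures, built in code.

# tiny hand-written panel: 6 chromosomes x 4 variants, deletion at column 2
tiny_panel <- function() {
  alleles <- rbind(
    c(0, 1, 1, 0),
    c(0, 1, 1, 0),
    c(1, 0, 0, 1),
    c(0, 0, 0, 1),
    c(1, 1, 1, 0),
    c(0, 0, 1, 1))
  haplotype_panel(alleles, c("v1", "DEL", "v3", "v4"),
                  c(100, 200, 300, 400), del_index = 2L)
}

# panel from explicit haplotype count layout at two variants:
# counts named AB, Ab, aB, ab where allele "A"/"B" = 1
two_locus_panel <- function(ab_counts) {
  rows <- rbind(
    matrix(rep(c(1, 1), ab_counts[["AB"]]), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), ab_counts[["Ab"]]), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), ab_counts[["aB"]]), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), ab_counts[["ab"]]), ncol = 2, byrow = TRUE))
  if (nrow(rows) %% 2 == 1) rows <- rbind(rows, c(0, 0))
  haplotype_panel(rows, c("A", "B"), c(10, 20), del_index = 1L)
}

small_config <- function(n = 300, seed = 11, ...) {
  sim_config(n_individuals = n, seed = seed, ...)
}

small_dataset <- function(n = 300, seed = 11, ...) {
  simulate_dataset(small_config(n, seed, ...))
}

# three cleanly separated class-conditional intensity blobs
blob_intensities <- function(n_per_class = 40, seed = 42, gap = 10) {
  withr::with_seed(seed, {
    g <- rep(0:2, each = n_per_class)
    mu <- (2 - g) * gap + 5
    x <- cbind(stats::rnorm(length(g), mu, 0.3),
               stats::rnorm(length(g), mu + 1, 0.3))
    y <- cbind(stats::rnorm(length(g), mu, 0.3),
               stats::rnorm(length(g), mu - 1, 0.3))
    list(x = x, y = y, labels = g)
  })
}
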