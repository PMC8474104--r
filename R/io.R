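# File dialects: SHAPEIT v2 HAPS/SAMPLE, IMPUTE-style 3-probability GEN,
# and plain TSV tables for intensities, phenotypes and recombination maps.
# Coordinates are 1-based physical bp throughout; alleles are abstract 0/1.

#' Write a haplotype panel as SHAPEIT-style HAPS + SAMPLE files
#'
#' HAPS rows: chromosome, variant id, position, allele0, allele1, then two 0/1
#' columns per individual (space separated). SAMPLE has the standard two header
#' lines.
#'
#' @param panel a [haplotype_panel()].
#' @param haps_path,sample_path output paths.
#' @param chrom chromosome label.
#' @return invisibly, the two paths.
#' @export
write_haps_sample <- function(panel, haps_path, sample_path, chrom = "16") {
  a <- panel$alleles
  n_ind <- nrow(a) %/% 2L
  body <- t(a)  # variants x chromosomes
  meta <- cbind(chrom, panel$variant_ids, format(panel$positions_bp, scientific = FALSE, trim = TRUE),
                "A", "B")
  lines <- apply(cbind(meta, body), 1, paste, collapse = " ")
  writeLines(lines, haps_path)
  ids <- sprintf("ind%04d", seq_len(n_ind))
  writeLines(c("ID_1 ID_2 missing", "0 0 0", paste(ids, ids, "0")), sample_path)
  invisible(c(haps_path, sample_path))
}

#' Read SHAPEIT-style HAPS + SAMPLE files into a haplotype panel
#'
#' @param haps_path,sample_path input paths.
#' @param del_id variant id flagged as the deletion; defaults to the id
#'   containing `"DEL"`, else errors.
#' @return a [haplotype_panel()].
#' @export
read_haps_sample <- function(haps_path, sample_path, del_id = NULL) {
  assert_that(file.exists(haps_path), "HAPS file not found: ", haps_path)
  assert_that(file.exists(sample_path), "SAMPLE file not found: ", sample_path)
  lines <- readLines(haps_path)
  assert_that(length(lines) > 0, "empty HAPS file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  width <- lengths(toks)
  if (length(unique(width)) != 1) {
    bad <- which(width != width[1])[1]
    stop_delcall("ragged HAPS row at line ", bad, " (", width[bad],
                 " fields, expected ", width[1], ")",
                 class = "delcall_parse_error")
  }
  sample_lines <- readLines(sample_path)
  assert_that(length(sample_lines) >= 3, "SAMPLE file lacks header/body")
  n_ind <- length(sample_lines) - 2L
  assert_that(width[1] == 5 + 2L * n_ind,
              "HAPS column count (", width[1], ") disagrees with SAMPLE (",
              n_ind, " individuals)", class = "delcall_parse_error")

  mat <- do.call(rbind, toks)
  ids <- mat[, 2]
  pos <- as.numeric(mat[, 3])
  if (any(diff(pos) <= 0)) {
    stop_delcall("HAPS positions not strictly increasing at line ",
                 which(diff(pos) <= 0)[1] + 1, class = "delcall_order_error")
  }
  body <- mat[, -(1:5), drop = FALSE]
  if (!all(body %in% c("0", "1"))) {
    bad <- which(apply(body, 1, function(r) !all(r %in% c("0", "1"))))[1]
    stop_delcall("non-0/1 allele code in HAPS body at line ", bad,
                 class = "delcall_parse_error")
  }
  alleles <- t(matrix(as.integer(body), nrow = nrow(body)))
  if (is.null(del_id)) {
    hit <- grep("DEL", ids)
    assert_that(length(hit) == 1,
                "cannot identify the deletion variant; pass del_id")
    del_id <- ids[hit]
  }
  haplotype_panel(alleles, ids, pos, match(del_id, ids))
}

#' Write IMPUTE-style GEN genotype probabilities
#'
#' One row per variant; three fixed 6-decimal probability columns per
#' individual.
#'
#' @param probs matrix (individuals x 3) for a single variant, or a list of
#'   such matrices (one per variant).
#' @param path output path.
#' @param variant_ids,positions_bp variant metadata recycled across rows.
#' @param chrom chromosome label.
#' @return invisibly, `path`.
#' @export
write_gen <- function(probs, path, variant_ids = NULL, positions_bp = NULL,
                      chrom = "16") {
  if (is.matrix(probs)) probs <- list(probs)
  m <- length(probs)
  variant_ids <- variant_ids %||% sprintf("var%03d", seq_len(m))
  positions_bp <- positions_bp %||% seq_len(m)
  lines <- character(m)
  for (j in seq_len(m)) {
    p <- probs[[j]]
    assert_that(is.matrix(p) && ncol(p) == 3, "probabilities must be n x 3")
    if (any(p < 0 | p > 1)) {
      stop_delcall("genotype probabilities outside [0, 1]",
                   class = "delcall_validation_error")
    }
    if (any(rowSums(p) > 1 + 1e-6)) {
      stop_delcall("genotype probabilities sum above 1",
                   class = "delcall_validation_error")
    }
    lines[j] <- paste(chrom, variant_ids[j], variant_ids[j], positions_bp[j],
                      "A", "B",
                      paste(sprintf("%.6f", t(p)), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read IMPUTE-style GEN genotype probabilities
#'
#' @param path input path.
#' @return list of (individuals x 3) probability matrices, one per variant,
#'   named by variant id.
#' @export
read_gen <- function(path) {
  toks <- strsplit(trimws(readLines(path)), "[ \t]+")
  out <- lapply(toks, function(tk) {
    vals <- as.numeric(tk[-(1:6)])
    matrix(vals, ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("WT", "het", "hom")))
  })
  names(out) <- vapply(toks, `[`, "", 2)
  out
}

#' Write / read the long-format intensity TSV
#'
#' Columns: `individual_id`, `probe_id`, `x`, `y`.
#'
#' @param intens an `intensity_table` (see [simulate_intensities()]).
#' @param path file path.
#' @return `write_intensity_tsv()` returns `path` invisibly;
#'   `read_intensity_tsv()` an `intensity_table`.
#' @export
write_intensity_tsv <- function(intens, path) {
  long <- data.frame(
    individual_id = rep(rownames(intens$x), ncol(intens$x)),
    probe_id = rep(colnames(intens$x), each = nrow(intens$x)),
    x = as.vector(intens$x), y = as.vector(intens$y))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @param in_deletion_pattern regex marking probes inside the deletion.
#' @export
read_intensity_tsv <- function(path, in_deletion_pattern = "^delprobe") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "probe_id", "x", "y")
  assert_that(all(need %in% names(df)),
              "intensity TSV must have columns ", paste(need, collapse = ", "))
  assert_that(!anyNA(df$x) && !anyNA(df$y), "missing intensity values")
  if (any(df$x < 0 | df$y < 0)) {
    stop_delcall("negative intensity values", class = "delcall_validation_error")
  }
  inds <- unique(df$individual_id)
  probes <- unique(df$probe_id)
  x <- matrix(NA_real_, length(inds), length(probes),
              dimnames = list(inds, probes))
  y <- x
  x[cbind(match(df$individual_id, inds), match(df$probe_id, probes))] <- df$x
  y[cbind(match(df$individual_id, inds), match(df$probe_id, probes))] <- df$y
  assert_that(!anyNA(x), "incomplete individual x probe intensity grid")
  structure(list(individual_id = inds,
                 probes = data.frame(probe_id = probes,
                                     in_deletion = grepl(in_deletion_pattern, probes),
                                     stringsAsFactors = FALSE),
                 x = x, y = y, s = x + y),
            class = "intensity_table")
}

#' Write / read the phenotype TSV
#'
#' Columns: `individual_id`, `status`, `sex`, `ethnicity`, `rs334_genotype`.
#' Unknown ethnicity labels (not in `levels`) are kept as their own category
#' with a warning.
#'
#' @param pheno a `phenotype_table`.
#' @param path file path.
#' @param levels declared ethnicity label set.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path,
                               levels = c("Giriama", "Chonyi", "Kauma", "Other")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "status", "sex", "ethnicity", "rs334_genotype")
  assert_that(all(need %in% names(df)),
              "phenotype TSV must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$individual_id)) {
    stop_delcall("duplicated individual_id: ",
                 df$individual_id[duplicated(df$individual_id)][1],
                 class = "delcall_validation_error")
  }
  assert_that(!anyNA(df[need]), "missing values in required phenotype fields")
  assert_that(all(df$status %in% 0:1) && all(df$sex %in% 0:1) &&
                all(df$rs334_genotype %in% 0:2),
              "phenotype codes out of range")
  extra <- setdiff(unique(df$ethnicity), levels)
  if (length(extra)) {
    warning("unknown ethnicity label(s) retained as their own category: ",
            paste(extra, collapse = ", "))
  }
  df$ethnicity <- factor(df$ethnicity, levels = c(levels, extra))
  structure(df, class = c("phenotype_table", "data.frame"))
}

#' Write / read a 3-column recombination map TSV
#'
#' Columns: `positions_bp`, `rate_cM_per_Mb`, `cumulative_cM`.
#'
#' @param map a [recomb_map()].
#' @param path file path.
#' @export
write_recomb_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("positions_bp", "rate_cM_per_Mb", "cumulative_cM")
  assert_that(all(need %in% names(df)),
              "recomb map TSV must have columns ", paste(need, collapse = ", "))
  recomb_map(df$positions_bp, df$rate_cM_per_Mb, df$cumulative_cM)
}
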