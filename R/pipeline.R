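# Configuration, orchestration and the command-line entry point. A single
# JSON config with per-stage sections drives the end-to-end run
# (simulate -> stats -> call -> impute -> associate -> evaluate); CLI flags
# override config values and everything is deterministic under one seed.

default_pipeline_config <- function() {
  list(
    simulate = list(n_individuals = 3036, n_flank_snps = 178,
                    n_del_probes = 6, del_freq = 2320 / 6072,
                    n_del_origins = 8),
    ld = list(enabled = TRUE),
    ehh = list(enabled = TRUE, allele = 1),
    call_intensity = list(enabled = TRUE, method = "cutoffs"),
    train = list(enabled = FALSE, method = "mrm", train_size = 100,
                 sizes = c(50, 100), reps = 5),
    impute = list(enabled = TRUE, n_ref = 100, Ne = 20000,
                  thresholds = c(0.7, 0.9), runs = 3),
    assoc = list(enabled = TRUE, model = "genotypic",
                 covariates = c("sex", "ethnicity", "rs334")),
    evaluate = list(enabled = TRUE,
                    methods = c("truth", "cutoffs", "hclust", "mrm", "cart")),
    seed = 1
  )
}

#' Read and validate a pipeline configuration
#'
#' JSON with per-stage sections; unknown top-level keys are a validation
#' error. Missing sections fall back to defaults.
#'
#' @param path JSON config path, or `NULL` for the defaults.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    assert_that(file.exists(path), "config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    assert_that(length(unknown) == 0,
                "invalid config key(s): ", paste(unknown, collapse = ", "),
                class = "delcall_invalid_config")
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        utils::modifyList(cfg[[k]], user[[k]])
      } else user[[k]]
    }
  }
  cfg
}

digest_file <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline
#'
#' Executes simulate, LD/EHH statistics, intensity calling, imputation
#' cross-validation, association and evaluation in order, writing artifacts
#' and a run manifest (config snapshot, seed, per-stage outputs with md5
#' digests) under `out_dir`. Stages are skippable via config
#' (`<stage>$enabled`); a stage failure is recorded in the manifest and
#' downstream stages are skipped.
#'
#' @param config_path JSON config path or `NULL` for defaults.
#' @param seed integer seed overriding the config's.
#' @param out_dir output directory (created if needed).
#' @param config optional pre-built config list (overrides `config_path`).
#' @return the manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config_path = NULL, seed = NULL, out_dir = tempfile("delcall_run_"),
                         config = NULL) {
  cfg <- config %||% read_pipeline_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "delcall",
                   version = as.character(utils::packageVersion("delcall")),
                   seed = cfg$seed, config = cfg, stages = list())
  outputs <- character(0)
  failed <- FALSE

  add_stage <- function(name, status, files = character(0), note = NULL) {
    manifest$stages[[name]] <<- list(
      status = status,
      outputs = lapply(files, function(f) list(path = basename(f),
                                               md5 = digest_file(f))),
      note = note)
    outputs <<- c(outputs, files)
  }
  run_stage <- function(name, enabled, fn) {
    if (failed) {
      add_stage(name, "skipped", note = "upstream failure")
      return(invisible(NULL))
    }
    if (!isTRUE(enabled)) {
      add_stage(name, "disabled")
      return(invisible(NULL))
    }
    tryCatch(fn(), error = function(e) {
      failed <<- TRUE
      add_stage(name, "failed", note = conditionMessage(e))
      NULL
    })
  }

  dataset <- NULL
  run_stage("simulate", TRUE, function() {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
    dataset <<- simulate_dataset(sc)
    haps <- file.path(out_dir, "panel.haps")
    samp <- file.path(out_dir, "panel.sample")
    write_haps_sample(dataset$panel, haps, samp)
    itsv <- file.path(out_dir, "intensities.tsv")
    write_intensity_tsv(dataset$intensities, itsv)
    ptsv <- file.path(out_dir, "phenotypes.tsv")
    write_phenotype_tsv(dataset$phenotypes, ptsv)
    mtsv <- file.path(out_dir, "recomb_map.tsv")
    write_recomb_map(dataset$map, mtsv)
    add_stage("simulate", "ok", c(haps, samp, itsv, ptsv, mtsv))
  })

  run_stage("ld", cfg$ld$enabled, function() {
    prof <- ld_profile(dataset$panel)
    f <- file.path(out_dir, "ld_profile.tsv")
    utils::write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("ld", "ok", f)
  })

  run_stage("ehh", cfg$ehh$enabled, function() {
    curve <- ehh(dataset$panel, allele = cfg$ehh$allele)
    f <- file.path(out_dir, "ehh.tsv")
    utils::write.table(curve, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("ehh", "ok", f)
  })

  run_stage("call_intensity", cfg$call_intensity$enabled, function() {
    intens <- dataset$intensities
    cls <- deletion_probe_cols(intens)
    calls <- if (cfg$call_intensity$method == "hclust") {
      hierarchical_call(intens)$calls
    } else {
      co <- density_cutoffs(intens$s[, cls[1]])
      assert_that(co$found, "no cut-offs found for the first deletion probe")
      call_by_cutoffs(intens$s[, cls[1]], co)
    }
    f <- file.path(out_dir, "intensity_calls.tsv")
    utils::write.table(
      data.frame(individual_id = intens$individual_id, call = calls),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("call_intensity", "ok", f)
  })

  run_stage("impute", cfg$impute$enabled, function() {
    icfg <- imputation_config(n_ref_individuals = cfg$impute$n_ref,
                              Ne = cfg$impute$Ne,
                              thresholds = cfg$impute$thresholds,
                              runs = cfg$impute$runs, seed = cfg$seed)
    cv <- imputation_cross_validation(dataset$panel, dataset$map, icfg)
    f <- file.path(out_dir, "imputation_runs.tsv")
    utils::write.table(cv$per_run, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fs <- file.path(out_dir, "imputation_summary.json")
    jsonlite::write_json(lapply(cv$summary, function(m) as.data.frame(t(m))),
                         fs, digits = NA, pretty = TRUE)
    add_stage("impute", "ok", c(f, fs))
  })

  run_stage("assoc", cfg$assoc$enabled, function() {
    truth <- deletion_genotypes(dataset$genotypes)
    res <- genetic_association(truth, dataset$phenotypes,
                               covariates = cfg$assoc$covariates,
                               model = cfg$assoc$model)
    f <- file.path(out_dir, "associations.tsv")
    utils::write.table(as.data.frame(res), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_stage("assoc", "ok", f)
  })

  run_stage("evaluate", cfg$evaluate$enabled, function() {
    cmp <- compare_methods(dataset, methods = cfg$evaluate$methods,
                           seed = cfg$seed)
    f1 <- file.path(out_dir, "performance.tsv")
    utils::write.table(cmp$performance, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(out_dir, "method_associations.tsv")
    utils::write.table(cmp$associations, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_stage("evaluate", "ok", c(f1, f2))
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# CLI

cli_usage <- function() {
  paste(
    "usage: delcall <subcommand> [options]",
    "subcommands: simulate ld ehh call-intensity train impute assoc evaluate run",
    "global options: --seed INT --config FILE --out-dir DIR --verbose",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    assert_that(startsWith(a, "--"), "unexpected argument: ", a)
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      flags[[key]] <- args[i + 1]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `delcall` subcommands (`simulate`, `ld`, `ehh`,
#' `call-intensity`, `train`, `impute`, `assoc`, `evaluate`, `run`). Meant to
#' be driven by the `inst/exec/delcall` Rscript wrapper, but callable
#' in-process for testing.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
delcall_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  flags <- parse_cli_flags(args[-1])
  seed <- as.integer(flags$seed %||% 1L)
  out_dir <- flags$out_dir %||% "."
  verbose <- isTRUE(flags$verbose)
  log <- function(...) if (verbose) message("[delcall] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- read_pipeline_config(flags$config)
  cfg$seed <- seed

  dataset_from_flags <- function() {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
    simulate_dataset(sc)
  }

  switch(sub,
    simulate = {
      log("simulating dataset")
      ds <- dataset_from_flags()
      write_haps_sample(ds$panel, file.path(out_dir, "panel.haps"),
                        file.path(out_dir, "panel.sample"))
      write_intensity_tsv(ds$intensities, file.path(out_dir, "intensities.tsv"))
      write_phenotype_tsv(ds$phenotypes, file.path(out_dir, "phenotypes.tsv"))
      write_recomb_map(ds$map, file.path(out_dir, "recomb_map.tsv"))
    },
    ld = {
      ds <- dataset_from_flags()
      utils::write.table(ld_profile(ds$panel),
                         file.path(out_dir, "ld_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    ehh = {
      ds <- dataset_from_flags()
      allele <- as.integer(flags$allele %||% 1L)
      utils::write.table(ehh(ds$panel, allele = allele),
                         file.path(out_dir, "ehh.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    `call-intensity` = {
      assert_that(!is.null(flags$`in`), "--in intensities.tsv required")
      intens <- read_intensity_tsv(flags$`in`)
      method <- flags$method %||% "cutoffs"
      cls <- deletion_probe_cols(intens)
      calls <- if (method == "hclust") hierarchical_call(intens)$calls
      else {
        co <- density_cutoffs(intens$s[, cls[1]])
        assert_that(co$found, "no density cut-offs found")
        call_by_cutoffs(intens$s[, cls[1]], co)
      }
      utils::write.table(
        data.frame(individual_id = intens$individual_id, call = calls),
        flags$out %||% file.path(out_dir, "calls.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    },
    train = {
      ds <- dataset_from_flags()
      method <- flags$method %||% "mrm"
      reps <- as.integer(flags$reps %||% 5L)
      sizes <- as.integer(strsplit(flags$sizes %||% "50,100", ",")[[1]])
      curve <- bootstrap_training_curve(ds$intensities,
                                        deletion_genotypes(ds$genotypes),
                                        method = method, sizes = sizes,
                                        reps = reps, seed = seed)
      utils::write.table(as.data.frame(curve),
                         file.path(out_dir, "training_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    impute = {
      ds <- dataset_from_flags()
      icfg <- imputation_config(
        n_ref_individuals = as.integer(flags$n_ref %||% cfg$impute$n_ref),
        Ne = as.numeric(flags$ne %||% cfg$impute$Ne),
        thresholds = as.numeric(strsplit(flags$thresholds %||% "0.7,0.9", ",")[[1]]),
        runs = as.integer(flags$runs %||% cfg$impute$runs), seed = seed)
      cv <- imputation_cross_validation(ds$panel, ds$map, icfg)
      utils::write.table(cv$per_run, file.path(out_dir, "imputation_runs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    assoc = {
      assert_that(!is.null(flags$`in`) && !is.null(flags$pheno),
                  "--in genotypes.tsv and --pheno pheno.tsv required")
      gdf <- utils::read.table(flags$`in`, header = TRUE, sep = "\t")
      ph <- read_phenotype_tsv(flags$pheno)
      covs <- strsplit(flags$covariates %||% "sex,ethnicity,rs334", ",")[[1]]
      res <- genetic_association(gdf$call %||% gdf$genotype, ph,
                                 covariates = covs,
                                 model = flags$model %||% "genotypic")
      utils::write.table(as.data.frame(res),
                         flags$out %||% file.path(out_dir, "assoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    evaluate = {
      ds <- dataset_from_flags()
      cmp <- compare_methods(ds, methods = cfg$evaluate$methods, seed = seed)
      utils::write.table(cmp$performance,
                         file.path(out_dir, "performance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cmp$associations,
                         file.path(out_dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    run = {
      run_pipeline(flags$config, seed = seed, out_dir = out_dir)
    },
    stop_delcall("unknown subcommand: ", sub)
  )
  invisible(0L)
}
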