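#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter. The configuration is serialized into
#' the run directory so a run can be reproduced from its own output.
#'
#' @param out_dir run directory (created if missing).
#' @param seed master seed; deterministic stages reproduce byte-identically
#'   under the same configuration.
#' @param stages which stages to run, in pipeline order; `classify`
#'   requires `zscore`, which requires `normalize`, which requires
#'   `simulate` (or externally supplied MA tables, not handled here).
#' @param sim a [sim_config()] for the synthetic stages; its `seed` is
#'   overridden by `seed`.
#' @param class_counts,effect_size planted truth, see [simulate_universe()].
#' @param min_intensity,span preprocessing parameters, see
#'   [preprocess_array()].
#' @param window_size z-score window, see [sliding_window_zscore()].
#' @param cutoff_shift,cutoff_total classifier cutoffs, see
#'   [classify_shifts()].
#' @param utr_n,utr_plan synthetic UTR stage, see [simulate_utr_set()].
#' @param dg_threshold UTR stability threshold (kcal/mol, builtin engine).
#' @param qpcr_genes number of genes (sampled from the planted groups) to
#'   carry through the qPCR stage.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = c("simulate", "normalize", "zscore",
                                  "classify", "utr", "qpcr", "validate"),
                       sim = sim_config(),
                       class_counts = c(group_I = 50, group_II = 30),
                       effect_size = 1.5,
                       min_intensity = NULL,
                       span = 0.4,
                       window_size = 50,
                       cutoff_shift = 1.5,
                       cutoff_total = 2.0,
                       utr_n = 40,
                       utr_plan = c(uaug = 10, uorf = 8, hairpin_stable = 10,
                                    long = 12, short = 20),
                       dg_threshold = -20,
                       qpcr_genes = 4) {
  known <- c("simulate", "normalize", "zscore", "classify", "utr", "qpcr",
             "validate")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sim$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         sim = sim, class_counts = class_counts, effect_size = effect_size,
         min_intensity = min_intensity, span = span,
         window_size = window_size, cutoff_shift = cutoff_shift,
         cutoff_total = cutoff_total, utr_n = utr_n, utr_plan = utr_plan,
         dg_threshold = dg_threshold, qpcr_genes = qpcr_genes),
    class = "run_config"
  )
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  substr(digest::digest(cfg, algo = "sha1"), 1, 8)
}

# every output table carries the tool version and configuration hash so a
# table can be traced back to the run that produced it
write_stage_tsv <- function(tab, path, hash) {
  header <- sprintf("# polyshift %s config=%s",
                    as.character(packageVersion("polyshift")), hash)
  writeLines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' @param path a TSV written by [run_pipeline()] (header comment line
#'   starting with `#` is skipped).
#' @return A tibble.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the configured stages in order — simulate arrays, normalize,
#' z-score and combine replicates, classify concomitant shifts, annotate a
#' synthetic UTR set, quantify simulated qPCR profiles, and score the
#' packaged validation table — writing every intermediate table, a log, the
#' serialized configuration and a machine-readable summary into the run
#' directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#'   Fails with a stage-named error when a required upstream stage was not
#'   run.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  on.exit(writeLines(log_lines, log_path), add = TRUE)

  cfg_out <- config[setdiff(names(config), "out_dir")]
  cfg_out$sim <- unclass(cfg_out$sim)
  jsonlite::write_json(
    cfg_out,
    file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  summary <- list(version = as.character(packageVersion("polyshift")),
                  config_hash = hash, stages = list())
  stages <- config$stages
  state <- new.env(parent = emptyenv())

  require_stage <- function(needed, for_stage) {
    if (!exists(needed, envir = state)) {
      stop("stage '", for_stage, "' requires stage '", needed,
           "' to have run", call. = FALSE)
    }
    get(needed, envir = state)
  }

  if ("simulate" %in% stages) {
    say("simulate: ", config$sim$n_genes, " genes, ",
        config$sim$n_replicates, " replicates, fractions ",
        paste(config$sim$fractions, collapse = "/"))
    truth <- simulate_universe(config$sim, config$class_counts,
                               config$effect_size)
    write_stage_tsv(truth, file.path(config$out_dir, "truth.tsv"), hash)
    arrays <- list()
    for (f in config$sim$fractions) {
      for (r in seq_len(config$sim$n_replicates)) {
        spot <- simulate_array(truth, f, r, config$sim)
        arrays[[paste(f, r, sep = "_")]] <- spot
        write_stage_tsv(
          spot, file.path(config$out_dir, sprintf("spots_%s_%d.tsv", f, r)),
          hash
        )
      }
    }
    assign("truth", truth, envir = state)
    assign("arrays", arrays, envir = state)
    summary$stages$simulate <- list(n_genes = nrow(truth),
                                    n_arrays = length(arrays))
  }

  if ("normalize" %in% stages) {
    arrays <- require_stage("arrays", "normalize")
    say("normalize: ", length(arrays), " arrays, span ", config$span)
    ma <- lapply(arrays, preprocess_array,
                 min_intensity = config$min_intensity, span = config$span)
    for (nm in names(ma)) {
      write_stage_tsv(ma[[nm]],
                      file.path(config$out_dir, paste0("ma_", nm, ".tsv")),
                      hash)
    }
    assign("ma", ma, envir = state)
    summary$stages$normalize <- list(
      n_genes_retained = vapply(ma, nrow, integer(1))
    )
  }

  if ("zscore" %in% stages) {
    ma <- require_stage("ma", "zscore")
    say("zscore: window ", config$window_size)
    ztabs <- lapply(names(ma), function(nm) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      sliding_window_zscore(ma[[nm]], config$window_size,
                            fraction = parts[1],
                            replicate = as.integer(parts[2]))
    })
    combined <- combine_replicates(ztabs)
    write_stage_tsv(combined, file.path(config$out_dir, "zscores.tsv"),
                    hash)
    assign("z", combined, envir = state)
    summary$stages$zscore <- list(n_rows = nrow(combined))
  }

  if ("classify" %in% stages) {
    z <- require_stage("z", "classify")
    say("classify: cutoffs ", config$cutoff_shift, "/", config$cutoff_total)
    wide <- tidyr::pivot_wider(z[, c("gene_id", "fraction", "z")],
                               names_from = "fraction", values_from = "z",
                               names_prefix = "z_")
    if (!"z_T" %in% names(wide)) wide$z_T <- NA_real_
    calls <- classify_shifts(wide, config$cutoff_shift, config$cutoff_total)
    write_stage_tsv(calls, file.path(config$out_dir, "calls.tsv"), hash)
    counts <- summarize_counts(calls, config$cutoff_shift)
    assign("calls", calls, envir = state)
    summary$stages$classify <- list(
      call_counts = as.list(counts$call_counts),
      one_fraction_only = as.list(counts$one_fraction_only)
    )
  }

  if ("utr" %in% stages) {
    say("utr: ", config$utr_n, " synthetic records")
    sim <- simulate_utr_set(config$utr_n, config$utr_plan,
                            seed = config$seed)
    feats <- annotate_utrs(sim$records, dg_threshold = config$dg_threshold)
    write_stage_tsv(feats, file.path(config$out_dir, "utr_features.tsv"),
                    hash)
    summary$stages$utr <- list(
      n_records = nrow(feats),
      pct_stable = 100 * mean(feats$stable),
      pct_uaug = 100 * mean(feats$n_uaug > 0)
    )
  }

  if ("qpcr" %in% stages) {
    truth <- require_stage("truth", "qpcr")
    planted_ids <- truth$gene_id[truth$true_class %in%
                                   c("group_I", "group_II")]
    n_take <- min(config$qpcr_genes, length(planted_ids))
    say("qpcr: ", n_take, " genes over the fine gradient")
    genes <- head(planted_ids, n_take)
    ct <- simulate_ct_table(truth, genes = genes, seed = config$seed)
    profiles <- fraction_profiles(ct)
    write_stage_tsv(profiles,
                    file.path(config$out_dir, "fraction_profiles.tsv"),
                    hash)
    summary$stages$qpcr <- list(n_profiles =
                                  nrow(unique(profiles[, c("gene_id",
                                                           "line")])))
  }

  if ("validate" %in% stages) {
    say("validate: packaged platform-comparison table")
    report <- confidence_level(load_table1_fixture())
    write_stage_tsv(report$records,
                    file.path(config$out_dir, "validation.tsv"), hash)
    summary$stages$validate <- list(
      n_validated = report$n_validated,
      n_total = report$n_total,
      confidence_percent = report$confidence_percent
    )
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done")
  invisible(summary)
}
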