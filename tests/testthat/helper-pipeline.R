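# Shared end-to-end helper: simulate arrays under `cfg`, run the
# preprocessing and z-score stages, and classify. Returns calls joined to
# the planted truth.
run_synthetic_classification <- function(cfg,
                                         class_counts = c(group_I = 50,
                                                          group_II = 30),
                                         effect_size = 1.5,
                                         window_size = 50,
                                         cutoff_shift = 1.5,
                                         cutoff_total = 2.0,
                                         min_intensity = NULL) {
  truth <- simulate_universe(cfg, class_counts, effect_size)
  ztabs <- list()
  for (f in cfg$fractions) {
    for (r in seq_len(cfg$n_replicates)) {
      ma <- preprocess_array(simulate_array(truth, f, r, cfg),
                             min_intensity = min_intensity)
      ztabs[[paste(f, r)]] <- sliding_window_zscore(
        ma, min(window_size, nrow(ma)), fraction = f, replicate = r
      )
    }
  }
  combined <- combine_replicates(ztabs)
  wide <- tidyr::pivot_wider(combined[, c("gene_id", "fraction", "z")],
                             names_from = "fraction", values_from = "z",
                             names_prefix = "z_")
  if (!"z_T" %in% names(wide)) wide$z_T <- NA_real_
  calls <- classify_shifts(wide, cutoff_shift, cutoff_total)
  # keep every planted gene: genes dropped upstream get call = NA
  dplyr::left_join(truth, calls, by = "gene_id")
}

recovery_rates <- function(joined, truth_classes = c("group_I", "group_II")) {
  called <- !is.na(joined$call) & joined$call %in% truth_classes
  exact <- !is.na(joined$call) & joined$call == joined$true_class
  n_planted <- sum(joined$true_class %in% truth_classes)
  c(
    sensitivity = sum(called & exact) / n_planted,
    fdp = if (sum(called) > 0) sum(called & !exact) / sum(called) else 0
  )
}
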