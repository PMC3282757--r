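#' Classify genes by concomitant NP/P shift
#'
#' Applies the concomitant-shift rule to combined z-scores of the
#' non-polysomal (NP), polysomal (P) and total (T) pools:
#'
#' * `group_I` (translationally inhibited): `z_P <= -cutoff_shift` and
#'   `z_NP >= +cutoff_shift` while the total is unchanged — the transcript
#'   leaves polysomes and accumulates in the non-polysomal pool.
#' * `group_II` (translationally enhanced): the mirror image,
#'   `z_P >= +cutoff_shift` and `z_NP <= -cutoff_shift` with total
#'   unchanged.
#' * `transcriptional_up` / `transcriptional_down`: `|z_T| > cutoff_total` —
#'   a steady-state change, which overrides a concomitant shift: a gene
#'   firing both rules is `indeterminate` with reasons
#'   `concomitant_shift` and `total_changed`.
#' * otherwise `unchanged`.
#'
#' "Total unchanged" means `|z_T| <= cutoff_total` or `z_T` missing (a gene
#' not detected on the total-RNA array cannot be excluded on its account).
#' Cutoff comparisons for the shift rule are inclusive, so a z of exactly
#' +/-1.5 counts as significant. Non-finite `z_NP` or `z_P` gives
#' `indeterminate` with reason `nonfinite_z`.
#'
#' @param z a tibble with columns `gene_id`, `z_NP`, `z_P` and optionally
#'   `z_T` (NA allowed).
#' @param cutoff_shift z-score cutoff for the NP/P shift rule (default 1.5
#'   standard deviations).
#' @param cutoff_total z-score cutoff beyond which the total-RNA level
#'   counts as transcriptionally changed (default 2.0).
#' @return A `ShiftCall` tibble: `gene_id`, `z_NP`, `z_P`, `z_T`, `call`,
#'   `reasons`.
#' @export
#' @examples
#' classify_shifts(tibble::tibble(gene_id = "PHO1",
#'                                z_NP = 1.58, z_P = -2.3, z_T = 0.59))
classify_shifts <- function(z, cutoff_shift = 1.5, cutoff_total = 2.0) {
  stopifnot(all(c("gene_id", "z_NP", "z_P") %in% names(z)),
            cutoff_shift > 0, cutoff_total > 0)
  z_T <- if ("z_T" %in% names(z)) z$z_T else rep(NA_real_, nrow(z))

  ok <- is.finite(z$z_NP) & is.finite(z$z_P)
  total_changed <- is.finite(z_T) & abs(z_T) > cutoff_total
  conc_i <- ok & z$z_P <= -cutoff_shift & z$z_NP >= cutoff_shift
  conc_ii <- ok & z$z_P >= cutoff_shift & z$z_NP <= -cutoff_shift
  conc <- conc_i | conc_ii

  call <- rep("unchanged", nrow(z))
  reasons <- rep("", nrow(z))
  call[total_changed & z_T > 0] <- "transcriptional_up"
  call[total_changed & z_T < 0] <- "transcriptional_down"
  reasons[total_changed] <- "total_changed"
  call[conc_i & !total_changed] <- "group_I"
  call[conc_ii & !total_changed] <- "group_II"
  reasons[conc & !total_changed] <- "concomitant_shift"
  both <- conc & total_changed
  call[both] <- "indeterminate"
  reasons[both] <- "concomitant_shift;total_changed"
  call[!ok] <- "indeterminate"
  reasons[!ok] <- "nonfinite_z"

  tibble::tibble(
    gene_id = z$gene_id,
    z_NP = z$z_NP, z_P = z$z_P, z_T = z_T,
    call = call, reasons = reasons
  )
}

#' Summarize shift calls
#'
#' Tallies the classification and, in the shape of the per-fraction report
#' (how many genes moved up or down in NP and in P, regardless of the
#' concomitance rule), the single-fraction exceedance counts.
#'
#' @param calls a `ShiftCall` tibble from [classify_shifts()].
#' @param cutoff_shift cutoff used for the per-fraction tallies (default
#'   1.5, matching [classify_shifts()]).
#' @return A list: `call_counts` (named integer vector over all call
#'   levels), `fraction_counts` (tibble `fraction`, `direction`, `n`), and
#'   `one_fraction_only` (genes beyond the cutoff in exactly one of NP, P).
#' @export
summarize_counts <- function(calls, cutoff_shift = 1.5) {
  call_counts <- vapply(CALL_LEVELS,
                        function(l) sum(calls$call == l), integer(1))
  np_up <- sum(calls$z_NP >= cutoff_shift, na.rm = TRUE)
  np_down <- sum(calls$z_NP <= -cutoff_shift, na.rm = TRUE)
  p_up <- sum(calls$z_P >= cutoff_shift, na.rm = TRUE)
  p_down <- sum(calls$z_P <= -cutoff_shift, na.rm = TRUE)
  np_hit <- !is.na(calls$z_NP) & abs(calls$z_NP) >= cutoff_shift
  p_hit <- !is.na(calls$z_P) & abs(calls$z_P) >= cutoff_shift
  list(
    call_counts = call_counts,
    fraction_counts = tibble::tibble(
      fraction = c("NP", "NP", "P", "P"),
      direction = c("up", "down", "up", "down"),
      n = c(np_up, np_down, p_up, p_down)
    ),
    one_fraction_only = c(NP = sum(np_hit & !p_hit),
                          P = sum(p_hit & !np_hit))
  )
}
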