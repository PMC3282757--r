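#' Intensity-dependent sliding-window z-score
#'
#' Standardizes each gene's normalized log-ratio by the mean and sample
#' standard deviation of the log-ratios in a window of neighbouring genes in
#' A (mean log2 intensity) order:
#' `z_i = (M_i - mean(window)) / sd(window)`, the window containing the
#' focal gene itself. This is the intensity-local analogue of a global
#' z-score: a ratio is judged against spots of comparable brightness, where
#' the ratio variance is comparable.
#'
#' The window is the `window_size` genes of nearest A-rank: centered in the
#' interior and slid inward at the edges so that every gene is scored
#' against a full-size window (no wraparound, no reflection). Genes whose
#' window could not be centered are flagged `edge_window`. With
#' `window_size = n` every z equals the global standardization of M. Ties in
#' A are broken by `gene_id` lexical order for reproducibility.
#'
#' @param ma a normalized `MATable` (see [lowess_normalize()]).
#' @param window_size number of genes per window, between 5 and `nrow(ma)`;
#'   default 50.
#' @param fraction,replicate optional labels stamped into the output.
#' @return A `ZScoreTable` tibble: `gene_id`, `fraction`, `replicate`, `A`,
#'   `M`, `z`, `window_mean`, `window_sd`, `flags`. Windows with (numerically)
#'   zero standard deviation give `z = 0` and the flag `degenerate_window`.
#' @export
#' @examples
#' ma <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
#'                      A = 1:4, M = c(0, 0, 0, 10), normalized = TRUE)
#' sliding_window_zscore(ma, window_size = 4)$z
sliding_window_zscore <- function(ma, window_size = 50,
                                  fraction = NA_character_,
                                  replicate = NA_integer_) {
  stopifnot(all(c("gene_id", "A", "M") %in% names(ma)))
  if ("normalized" %in% names(ma) && !all(ma$normalized)) {
    stop("`ma` must be Lowess-normalized before z-scoring", call. = FALSE)
  }
  n <- nrow(ma)
  if (window_size < 2 || window_size > n) {
    stop("`window_size` must be between 2 and the number of genes (", n, ")",
         call. = FALSE)
  }
  w <- as.integer(window_size)
  ord <- order(ma$A, ma$gene_id)
  s <- ma[ord, ]

  half_left <- (w - 1L) %/% 2L
  centered_start <- seq_len(n) - half_left
  start <- pmin(pmax(centered_start, 1L), n - w + 1L)
  end <- start + w - 1L

  stats <- vapply(seq_len(n), function(r) {
    win <- s$M[start[r]:end[r]]
    mu <- sum(win) / w
    c(mu, sqrt(sum((win - mu)^2) / (w - 1)))
  }, numeric(2))
  wmean <- stats[1, ]
  wsd <- stats[2, ]

  # a window whose spread is at floating-point level relative to the M scale
  # carries no ratio variation to standardize against; treating it as
  # degenerate stops rounding noise from being amplified into large z
  degenerate <- wsd <= 1e-10 * max(1, max(abs(s$M)))
  z <- ifelse(degenerate, 0, (s$M - wmean) / wsd)
  flags <- add_flag(rep("", n), "edge_window", start != centered_start)
  flags <- add_flag(flags, "degenerate_window", degenerate)

  out <- tibble::tibble(
    gene_id = s$gene_id,
    fraction = fraction,
    replicate = replicate,
    A = s$A, M = s$M, z = z,
    window_mean = wmean, window_sd = wsd,
    flags = flags
  )
  out[order(out$gene_id), ]
}

#' Combine replicate z-score tables
#'
#' The combined z for a gene in a fraction is the arithmetic mean of its
#' replicate z-scores. Genes measured in only one replicate keep that value
#' and are flagged `single_replicate`; genes whose replicates disagree in
#' sign are flagged `discordant` but still averaged.
#'
#' @param tables a list of `ZScoreTable`s (one per replicate), or a single
#'   table already holding several replicates.
#' @return A `ZScoreTable` with `replicate = "combined"`, one row per
#'   (gene, fraction), columns `gene_id`, `fraction`, `replicate`, `z`,
#'   `n_replicates`, `flags`.
#' @export
combine_replicates <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) {
    stop("no replicate tables supplied", call. = FALSE)
  }
  all_z <- dplyr::bind_rows(tables)
  stopifnot(all(c("gene_id", "fraction", "z") %in% names(all_z)))
  out <- dplyr::summarise(
    dplyr::group_by(all_z, .data$gene_id, .data$fraction),
    n_replicates = dplyr::n(),
    discordant = .data$n_replicates > 1 &&
      any(.data$z > 0) && any(.data$z < 0),
    z = mean(.data$z),
    .groups = "drop"
  )
  flags <- add_flag(rep("", nrow(out)), "single_replicate",
                    out$n_replicates == 1)
  flags <- add_flag(flags, "discordant", out$discordant)
  tibble::tibble(
    gene_id = out$gene_id,
    fraction = out$fraction,
    replicate = "combined",
    z = out$z,
    n_replicates = out$n_replicates,
    flags = flags
  )
}
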