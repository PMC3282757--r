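#' Background-correct a spot table
#'
#' Subtracts the local per-spot background from each channel's foreground.
#' Spots where either channel is non-positive after subtraction are flagged
#' `negative_after_bg` and excluded from M/A computation rather than clamped
#' to a floor: a fabricated small intensity would fabricate a ratio.
#'
#' @param raw a `SpotTable` tibble with columns `gene_id`, `ch1_fg`,
#'   `ch1_bg`, `ch2_fg`, `ch2_bg` (channel 1 = mutant, channel 2 = wild
#'   type).
#' @return The table with corrected intensities `I1`, `I2` (NA where
#'   flagged) and a `flags` column.
#' @export
#' @examples
#' spots <- tibble::tibble(gene_id = c("a", "b"),
#'                         ch1_fg = c(1000, 50), ch1_bg = c(100, 100),
#'                         ch2_fg = c(800, 500), ch2_bg = c(100, 100))
#' subtract_background(spots)
subtract_background <- function(raw) {
  stopifnot(all(c("gene_id", "ch1_fg", "ch1_bg", "ch2_fg", "ch2_bg")
                %in% names(raw)))
  if (any(raw$ch1_fg < 0 | raw$ch2_fg < 0 | raw$ch1_bg < 0 | raw$ch2_bg < 0)) {
    stop("foreground and background intensities must be non-negative",
         call. = FALSE)
  }
  i1 <- raw$ch1_fg - raw$ch1_bg
  i2 <- raw$ch2_fg - raw$ch2_bg
  neg <- i1 <= 0 | i2 <= 0
  out <- raw
  out$I1 <- ifelse(neg, NA_real_, i1)
  out$I2 <- ifelse(neg, NA_real_, i2)
  out$flags <- add_flag(existing_flags(raw), "negative_after_bg", neg)
  out
}

#' Filter spots by intensity
#'
#' A spot is dropped only when *both* channels fall below the threshold: a
#' spot that is dim in one channel but bright in the other can be a genuine
#' strong ratio and must survive. The default threshold is twice the median
#' background of the array.
#'
#' @param corrected output of [subtract_background()].
#' @param min_intensity threshold in fluorescence units, or `NULL` for the
#'   2 x median-background default. `0` retains everything.
#' @return The table with low spots flagged `low_intensity` (intensities set
#'   to NA).
#' @export
intensity_filter <- function(corrected, min_intensity = NULL) {
  stopifnot(all(c("I1", "I2", "flags") %in% names(corrected)))
  if (is.null(min_intensity)) {
    min_intensity <- 2 * stats::median(
      c(corrected$ch1_bg, corrected$ch2_bg), na.rm = TRUE
    )
  }
  stopifnot(min_intensity >= 0)
  low <- !is.na(corrected$I1) & !is.na(corrected$I2) &
    corrected$I1 < min_intensity & corrected$I2 < min_intensity
  out <- corrected
  out$flags <- add_flag(out$flags, "low_intensity", low)
  out$I1[low] <- NA_real_
  out$I2[low] <- NA_real_
  out
}

#' Compute per-gene M/A values
#'
#' For retained spots, `M = log2(I1/I2)` (mutant over wild type) and
#' `A = (log2 I1 + log2 I2)/2`. Duplicate spots of a gene are averaged on
#' the M/A scale, after the log transform, because the log-ratio is the
#' modeled quantity.
#'
#' @param filtered output of [intensity_filter()] (or
#'   [subtract_background()] when no filter is wanted).
#' @return An `MATable` tibble: `gene_id`, `A`, `M`, `n_spots`,
#'   `normalized = FALSE`.
#' @export
compute_ma <- function(filtered) {
  stopifnot(all(c("gene_id", "I1", "I2") %in% names(filtered)))
  keep <- filtered[!is.na(filtered$I1) & !is.na(filtered$I2), ]
  if (any(keep$I1 <= 0 | keep$I2 <= 0)) {
    stop("non-positive intensity reached M/A computation; ",
         "spots must be flagged upstream", call. = FALSE)
  }
  ma <- tibble::tibble(
    gene_id = keep$gene_id,
    M = log2(keep$I1 / keep$I2),
    A = (log2(keep$I1) + log2(keep$I2)) / 2
  )
  out <- dplyr::summarise(
    dplyr::group_by(ma, .data$gene_id),
    A = mean(.data$A), M = mean(.data$M), n_spots = dplyr::n(),
    .groups = "drop"
  )
  out$normalized <- FALSE
  out[, c("gene_id", "A", "M", "n_spots", "normalized")]
}

#' Lowess-normalize log-ratios against intensity
#'
#' Removes intensity-dependent dye bias by subtracting a robust locally
#' weighted regression of M on A: `M' = M - lowess(A, M)`. A is left
#' untouched.
#'
#' @param ma an `MATable` from [compute_ma()].
#' @param span lowess smoother span in `(0, 1]`; default 0.4, a common
#'   two-color choice.
#' @param iter robustness iterations (default 3).
#' @return The table with `M` replaced by the normalized residual and
#'   `normalized = TRUE`.
#' @export
lowess_normalize <- function(ma, span = 0.4, iter = 3) {
  stopifnot(all(c("A", "M") %in% names(ma)), span > 0, span <= 1)
  if (nrow(ma) < 10) {
    stop("need at least 10 points to fit the lowess trend; ",
         "consider a global-median correction for tiny tables",
         call. = FALSE)
  }
  fit <- stats::lowess(ma$A, ma$M, f = span, iter = iter)
  trend <- stats::approx(fit$x, fit$y, xout = ma$A, rule = 2, ties = mean)$y
  out <- ma
  out$M <- ma$M - trend
  out$normalized <- TRUE
  out
}

#' Run the full spot-to-MA preprocessing chain
#'
#' Convenience wrapper: [subtract_background()], [intensity_filter()],
#' [compute_ma()], [lowess_normalize()].
#'
#' @inheritParams intensity_filter
#' @inheritParams lowess_normalize
#' @param raw a raw `SpotTable`.
#' @return A normalized `MATable`.
#' @export
preprocess_array <- function(raw, min_intensity = NULL, span = 0.4,
                             iter = 3) {
  raw |>
    subtract_background() |>
    intensity_filter(min_intensity = min_intensity) |>
    compute_ma() |>
    lowess_normalize(span = span, iter = iter)
}

# flags are kept as a single ';'-separated character column so tables stay
# plain TSV
existing_flags <- function(tab) {
  if ("flags" %in% names(tab)) tab$flags else rep("", nrow(tab))
}

add_flag <- function(flags, code, where) {
  ifelse(where, ifelse(flags == "", code, paste(flags, code, sep = ";")),
         flags)
}

has_flag <- function(flags, code) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) code %in% f, logical(1))
}
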