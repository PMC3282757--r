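#' Load the packaged microarray-vs-qPCR validation table
#'
#' A 23-gene table of combined microarray z-scores (total, NP and P pools)
#' side by side with eIF4A-normalized qRT-PCR signed fold changes for NP and
#' P, measured on an independent biological sample, plus the printed change
#' label (`Decrease` for Group I, `Increase` for Group II, `l.c.` for lack
#' of correspondence between the two platforms). Missing total-RNA z-scores
#' (transcripts not detected on the total array) are NA.
#'
#' @return A `ValidationRecord` tibble: `accession`, `name`, `micro_T`,
#'   `micro_NP`, `micro_P`, `qpcr_NP`, `qpcr_P`, `change`. Structural
#'   integrity (row count, label set, spot values) is enforced at load.
#' @export
#' @examples
#' v <- load_table1_fixture()
#' table(v$change)
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_validation.tsv",
                      package = "polyshift", mustWork = TRUE)
  v <- readr::read_tsv(
    path,
    col_types = readr::cols(
      accession = "c", name = "c", change = "c", .default = "d"
    ),
    progress = FALSE
  )
  pho1 <- v[grepl("PHO1", v$name), ]
  cobl4 <- v[grepl("COBL4", v$name), ]
  ok <- nrow(v) == 23 &&
    all(v$change %in% c("Decrease", "Increase", "l.c.")) &&
    nrow(pho1) == 1 &&
    isTRUE(all.equal(unlist(pho1[, c("micro_T", "micro_NP", "micro_P",
                                     "qpcr_NP", "qpcr_P")], use.names = FALSE),
                     c(0.59, 1.58, -2.3, 1.9, -15.8))) &&
    nrow(cobl4) == 1 && cobl4$change == "l.c."
  if (!ok) {
    stop("validation fixture failed its integrity check; ",
         "reinstall the package", call. = FALSE)
  }
  v
}

#' Score microarray-vs-qPCR concordance
#'
#' A record validates when the qPCR signed fold change in the polysomal (P)
#' fraction agrees in sign with the microarray z-score in P. The P pool
#' alone carries the decision: the polysomal shift is the biologically
#' operative direction, and NP fold changes disagree with the array for
#' several records the platform comparison nevertheless accepts, while
#' every discordant record disagrees in P.
#'
#' @param records a `ValidationRecord` tibble (see [load_table1_fixture()])
#'   or any tibble with `micro_P` and `qpcr_P` columns.
#' @return The tibble with a logical `validated` column (NA, flagged
#'   `indeterminate` in `flags`, when either P value is zero or missing).
#' @export
concordance <- function(records) {
  stopifnot(all(c("micro_P", "qpcr_P") %in% names(records)))
  s_micro <- sign(records$micro_P)
  s_qpcr <- sign(records$qpcr_P)
  indeterminate <- is.na(s_micro) | is.na(s_qpcr) |
    s_micro == 0 | s_qpcr == 0
  out <- records
  out$validated <- ifelse(indeterminate, NA, s_micro == s_qpcr)
  out$flags <- add_flag(rep("", nrow(out)), "indeterminate", indeterminate)
  out
}

#' Validation report with confidence level
#'
#' Counts validated records and reports the raw proportion as a percentage
#' (rounded to the nearest integer), the "confidence level" of the
#' microarray analysis.
#'
#' @param records a `ValidationRecord` tibble; [concordance()] is applied
#'   if the `validated` column is absent.
#' @return A list: `records` (with `validated`), `n_validated`, `n_total`,
#'   `confidence_percent`.
#' @export
#' @examples
#' confidence_level(load_table1_fixture())$confidence_percent
confidence_level <- function(records) {
  if (nrow(records) == 0) {
    stop("no validation records supplied", call. = FALSE)
  }
  if (!"validated" %in% names(records)) {
    records <- concordance(records)
  }
  n_validated <- sum(records$validated, na.rm = TRUE)
  n_total <- nrow(records)
  list(
    records = records,
    n_validated = n_validated,
    n_total = n_total,
    confidence_percent = round(100 * n_validated / n_total)
  )
}
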