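#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' `R = E_target^dCt_target / E_ref^dCt_ref`, where each `dCt` is
#' `Ct(control) - Ct(sample)` (e.g. WT minus mutant) for the target gene and
#' the housekeeping reference, and `E` is the primer amplification
#' efficiency in `(1, 2]` (2 = perfect doubling per cycle). With both
#' efficiencies equal to 2 this reduces to the familiar `2^-ddCt`.
#'
#' @param e_target,e_ref primer efficiencies, each in `(1, 2]`.
#' @param dct_target,dct_ref Ct differences, control minus sample (cycles).
#' @return The relative expression ratio (dimensionless), vectorized.
#' @export
#' @examples
#' relative_expression(2, 2, 2, 0)      # 4
#' relative_expression(1.9, 2, 2, 1)    # 1.9^2 / 2 = 1.805
relative_expression <- function(e_target, dct_target, e_ref, dct_ref) {
  check_efficiency(c(e_target, e_ref))
  e_target^dct_target / e_ref^dct_ref
}

check_efficiency <- function(e) {
  if (anyNA(e) || any(e <= 1) || any(e > 2)) {
    stop("amplification efficiencies must lie in (1, 2]", call. = FALSE)
  }
  invisible(e)
}

#' Relative quantity by the 2^-dCt method
#'
#' @param ct threshold cycle(s) of the sample.
#' @param ct_ref threshold cycle of the reference condition.
#' @return `2^-(ct - ct_ref)`, vectorized.
#' @export
#' @examples
#' quantity_2_delta_ct(11, 10)  # 0.5
quantity_2_delta_ct <- function(ct, ct_ref) {
  2^-(ct - ct_ref)
}

#' Signed fold change from a ratio
#'
#' The reporting convention for fold changes: a ratio of at least 1 is
#' reported as-is with positive sign, a ratio below 1 as the negative
#' reciprocal, so a halving is -2 rather than 0.5.
#'
#' @param ratio positive ratio(s).
#' @return Signed fold change(s); never in `(-1, 1)`.
#' @export
#' @examples
#' signed_fold_change(c(4, 0.25, 1))  # 4, -4, 1
signed_fold_change <- function(ratio) {
  if (anyNA(ratio) || any(ratio <= 0)) {
    stop("`ratio` must be strictly positive", call. = FALSE)
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Percentage distribution of a transcript over gradient fractions
#'
#' Converts a gene's Ct values across sucrose-gradient fractions to the
#' percentage of its RNA in each fraction, taking the sum over all assayed
#' fractions as the total: `q_f = E^-Ct_f`, replicates averaged on the
#' linear quantity scale, then `percent_f = 100 q_f / sum(q)`. Optionally
#' each fraction's quantity is first divided by the same-fraction quantity
#' of an unaffected control transcript (e.g. eIF4A), correcting for
#' per-fraction recovery differences.
#'
#' @param records `CtRecord` tibble for a single gene and line: columns
#'   `gene_id`, `line`, `fraction`, `replicate`, `ct`, `efficiency`.
#'   Missing efficiencies default to 2 and flag the profile
#'   `default_efficiency`.
#' @param reference optional `CtRecord` tibble of the control gene, same
#'   line, covering at least the same fractions.
#' @return A `FractionProfile` tibble: `gene_id`, `line`, `fraction`,
#'   `quantity`, `percent`, `flags`; percentages sum to 100.
#' @export
#' @examples
#' ct <- tibble::tibble(gene_id = "PHO1", line = "WT",
#'                      fraction = c("NP", "P"), replicate = 1,
#'                      ct = c(10, 11), efficiency = 2)
#' fraction_distribution(ct)
fraction_distribution <- function(records, reference = NULL) {
  stopifnot(all(c("gene_id", "line", "fraction", "ct") %in% names(records)))
  if (dplyr::n_distinct(records$gene_id) != 1 ||
      dplyr::n_distinct(records$line) != 1) {
    stop("`records` must cover exactly one gene and one line; ",
         "split first", call. = FALSE)
  }
  if (dplyr::n_distinct(records$fraction) < 2) {
    stop("need at least two fractions to compute a distribution",
         call. = FALSE)
  }
  eff <- if ("efficiency" %in% names(records)) records$efficiency
         else rep(NA_real_, nrow(records))
  defaulted <- anyNA(eff)
  eff[is.na(eff)] <- 2
  check_efficiency(eff)
  if (dplyr::n_distinct(eff) != 1) {
    stop("mixed efficiencies across fractions of one primer pair",
         call. = FALSE)
  }

  q <- mean_quantity_by_fraction(records$fraction, eff^-records$ct)
  if (!is.null(reference)) {
    reff <- if ("efficiency" %in% names(reference)) reference$efficiency
            else rep(2, nrow(reference))
    reff[is.na(reff)] <- 2
    check_efficiency(reff)
    rq <- mean_quantity_by_fraction(reference$fraction, reff^-reference$ct)
    if (!all(names(q) %in% names(rq))) {
      stop("reference gene does not cover all fractions of the target",
           call. = FALSE)
    }
    q <- q / rq[names(q)]
  }

  flags <- if (defaulted) "default_efficiency" else ""
  tibble::tibble(
    gene_id = records$gene_id[1],
    line = records$line[1],
    fraction = names(q),
    quantity = unname(q),
    percent = unname(100 * q / sum(q)),
    flags = flags
  )
}

mean_quantity_by_fraction <- function(fraction, quantity) {
  m <- tapply(quantity, fraction, mean)
  # keep gradient order where known, appearance order otherwise
  ord <- c(intersect(FRACTIONS_ALL, names(m)),
           setdiff(unique(fraction), FRACTIONS_ALL))
  setNames(as.numeric(m[ord]), ord)
}

#' Fraction profiles for every gene/line in a Ct table
#'
#' Applies [fraction_distribution()] to each (gene, line) slice of a Ct
#' table, optionally normalizing against a control gene measured in the
#' same table.
#'
#' @param ct a `CtRecord` tibble.
#' @param ref_gene optional gene id of the control transcript (e.g.
#'   `"eIF4A"`); its own profile is also reported.
#' @return A `FractionProfile` tibble over all genes and lines.
#' @export
fraction_profiles <- function(ct, ref_gene = NULL) {
  slices <- split(ct, interaction(ct$gene_id, ct$line, drop = TRUE))
  dplyr::bind_rows(lapply(slices, function(s) {
    ref <- NULL
    if (!is.null(ref_gene) && s$gene_id[1] != ref_gene) {
      ref <- ct[ct$gene_id == ref_gene & ct$line == s$line[1], ]
      if (nrow(ref) == 0) {
        stop("control gene '", ref_gene, "' not measured for line ",
             s$line[1], call. = FALSE)
      }
    }
    fraction_distribution(s, reference = ref)
  }))
}
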