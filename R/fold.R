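#' Minimum free energy of nested RNA secondary structure (built-in model)
#'
#' Computes the minimum free energy over all nested (pseudoknot-free)
#' structures under a deliberately simple base-pair energy model: GC pairs
#' score -3.0, AU pairs -2.0, GU wobble pairs -1.0 kcal/mol, every hairpin
#' loop costs +4.0 kcal/mol, and hairpin loops must span at least 3
#' unpaired bases. Stacking, bulge and multiloop terms are ignored. The
#' optimum is found by dynamic programming over subsequences (Nussinov-style
#' with an energy objective); the open structure (no pairs, energy 0) is
#' always admissible, so the result is `min(0, best)`.
#'
#' This model is a thresholding surrogate, not a thermodynamic predictor:
#' its energies are on a different scale from nearest-neighbour programs
#' such as mfold or RNAfold, so a stability threshold (e.g. -20 kcal/mol)
#' is meaningful only relative to the engine that produced the energies.
#' Every annotation row therefore records the engine used
#' (see [annotate_utrs()]).
#'
#' @param sequence character vector of RNA/DNA sequences (A, C, G, U/T).
#' @param engine `"builtin"` for the model above, or a function
#'   `function(sequence) -> delta_g` wrapping an external folding program.
#' @return Numeric vector of free energies in kcal/mol (0 for sequences
#'   shorter than 8 nt under the builtin engine).
#' @export
#' @examples
#' fold_mfe("GGGGGAAAACCCCC")  # 5 GC pairs and one hairpin loop: -11
#' fold_mfe("AAAAAAAA")        # nothing can pair: 0
fold_mfe <- function(sequence, engine = "builtin") {
  if (is.function(engine)) {
    return(vapply(sequence, engine, numeric(1), USE.NAMES = FALSE))
  }
  if (!identical(engine, "builtin")) {
    stop("`engine` must be \"builtin\" or a function", call. = FALSE)
  }
  vapply(sequence, fold_mfe_one, numeric(1), USE.NAMES = FALSE)
}

PAIR_ENERGY <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2,
                 "GU" = -1, "UG" = -1)
HAIRPIN_PENALTY <- 4
MIN_LOOP <- 3

fold_bases <- function(sequence) {
  b <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  if (!all(b %in% c("A", "C", "G", "U"))) {
    stop("invalid alphabet in sequence (expected A, C, G, U/T): ",
         substr(sequence, 1, 30), call. = FALSE)
  }
  b
}

fold_mfe_one <- function(sequence) {
  b <- fold_bases(sequence)
  n <- length(b)
  if (n < 8) return(0)

  # pairwise energies; NA = not pairable
  e <- matrix(PAIR_ENERGY[outer(b, b, paste0)], n, n)

  # wp[i, j] = min energy of structures on b[i..j] containing >= 1 pair
  # v[i, j]  = min energy of structures where i pairs j
  inf <- Inf
  wp <- matrix(inf, n, n)
  v <- matrix(inf, n, n)
  min_span <- MIN_LOOP + 1L # j - i for the smallest closable pair

  for (span in seq(min_span, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      if (!is.na(e[i, j])) {
        inner <- if (span - 2L >= min_span) wp[i + 1L, j - 1L] else inf
        v[i, j] <- e[i, j] + min(HAIRPIN_PENALTY, inner)
      }
      best <- wp[i + 1L, j] # i unpaired
      ks <- seq(i + min_span, j)
      vik <- v[i, ks]
      usable <- is.finite(vik)
      if (any(usable)) {
        ks <- ks[usable]
        rest <- rep(inf, length(ks))
        lt <- ks < j
        rest[lt] <- wp[cbind(ks[lt] + 1L, j)]
        best <- min(best, vik[usable] + pmin(0, rest))
      }
      wp[i, j] <- best
    }
  }
  min(0, wp[1L, n])
}
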