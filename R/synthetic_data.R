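#' Simulation configuration for synthetic polysome-profiling arrays
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a desk-scale experiment: 1000 genes, two biological replicates per
#' fraction, lognormal intensity noise of 0.25 on the log2 scale, a linear
#' intensity-dependent dye bias added to the log-ratio, and a constant
#' additive background per array.
#'
#' @param n_genes number of genes on the array.
#' @param n_replicates biological replicates per fraction.
#' @param fractions RNA pools to simulate; the coarse scheme is
#'   `c("NP", "P", "T")` (non-polysomal, polysomal, total), the fine gradient
#'   scheme `c("NP", "M", "LP", "HP")`.
#' @param noise_sd per-channel lognormal noise, standard deviation in log2
#'   units. Must be >= 0.
#' @param dye_bias numeric length-2 `(intercept, slope)`; the bias
#'   `intercept + slope * A` (log2 units) is added to the mutant channel so
#'   that the raw log-ratio M carries an intensity-dependent trend for Lowess
#'   to remove. `A` is the gene's noise-free mean log2 intensity,
#'   `log2(base_abundance)`.
#' @param background_level additive background fluorescence per channel,
#'   constant within an array. The default (50, against a median signal of
#'   2^10) keeps ~99% of spots above the downstream intensity filter,
#'   matching the detection rate of a typical two-color experiment.
#' @param abundance_log2_mean,abundance_log2_sd location and spread of the
#'   per-gene base abundance distribution, `2^rnorm(mean, sd)`.
#' @param seed integer; fully determines all generator output.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 42)
sim_config <- function(n_genes = 1000,
                       n_replicates = 2,
                       fractions = c("NP", "P", "T"),
                       noise_sd = 0.25,
                       dye_bias = c(0.5, 0.1),
                       background_level = 50,
                       abundance_log2_mean = 10,
                       abundance_log2_sd = 1.5,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, n_replicates >= 1,
    length(dye_bias) == 2, is.numeric(dye_bias),
    background_level >= 0
  )
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a non-negative number", call. = FALSE)
  }
  bad <- setdiff(fractions, FRACTIONS_ALL)
  if (length(bad) > 0) {
    stop("unknown fraction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_replicates = as.integer(n_replicates),
      fractions = fractions,
      noise_sd = noise_sd,
      dye_bias = as.numeric(dye_bias),
      background_level = background_level,
      abundance_log2_mean = abundance_log2_mean,
      abundance_log2_sd = abundance_log2_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Log2 shift applied to the mutant channel for a gene of `class` in
# `fraction`. Group I = translationally inhibited (P down, NP/M up);
# Group II = translationally enhanced (P/LP/HP up, NP/M down);
# transcriptional classes move every pool, including total, the same way.
class_shift <- function(class, fraction, effect) {
  n <- max(length(class), length(fraction))
  class <- rep_len(class, n)
  effect <- rep_len(effect, n)
  pool <- rep_len(fraction %in% c("P", "LP", "HP"), n) -
    rep_len(fraction %in% c("NP", "M"), n)  # +1 polysomal, -1 non-polysomal
  sgn <- numeric(n)
  sgn[class == "group_I"] <- -pool[class == "group_I"]
  sgn[class == "group_II"] <- pool[class == "group_II"]
  sgn[class == "transcriptional_up"] <- 1
  sgn[class == "transcriptional_down"] <- -1
  sgn * effect
}

#' Plant a gene universe with known translational classes
#'
#' Assigns each gene a true class (Group I, Group II, transcriptional up or
#' down, or unchanged), a base abundance drawn from a lognormal distribution,
#' and a positive shift effect in log2 units. Group I genes get the effect
#' applied as NP up / P down in [simulate_array()], Group II the reverse;
#' transcriptional genes shift every fraction, total included.
#'
#' @param config a [sim_config()].
#' @param class_counts named integer vector over
#'   `c("group_I", "group_II", "transcriptional_up", "transcriptional_down")`;
#'   genes not covered are labeled `unchanged`.
#' @param effect_size planted shift in log2 units; must be > 0.
#'
#' @return A tibble (`TruthTable`) with columns `gene_id`, `true_class`,
#'   `base_abundance`, `shift_effect`.
#' @export
#' @examples
#' truth <- simulate_universe(sim_config(n_genes = 100, seed = 1),
#'                            c(group_I = 5, group_II = 3))
#' table(truth$true_class)
simulate_universe <- function(config,
                              class_counts = c(group_I = 50, group_II = 30),
                              effect_size = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(effect_size) || effect_size <= 0) {
    stop("`effect_size` must be > 0: a planted shift of zero is not a shift",
         call. = FALSE)
  }
  class_counts <- class_counts[class_counts > 0]
  bad <- setdiff(names(class_counts), setdiff(SHIFT_CLASSES, "unchanged"))
  if (length(bad) > 0) {
    stop("unknown class(es) in `class_counts`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- config$n_genes
  if (sum(class_counts) > n) {
    stop("sum of `class_counts` (", sum(class_counts),
         ") exceeds n_genes (", n, ")", call. = FALSE)
  }
  set.seed(config$seed)
  gene_id <- sprintf("G%05d", seq_len(n))
  base_abundance <- 2^rnorm(n, config$abundance_log2_mean,
                            config$abundance_log2_sd)
  true_class <- rep("unchanged", n)
  planted <- sample.int(n, sum(class_counts))
  true_class[planted] <- rep(names(class_counts), times = class_counts)
  shift_effect <- ifelse(true_class == "unchanged", 0, effect_size)
  tibble::tibble(gene_id, true_class, base_abundance, shift_effect)
}

#' Simulate one two-color array (mutant vs wild type, one fraction)
#'
#' Each array compares mutant against wild-type RNA for a single gradient
#' pool; the mutant sample is in channel 1 and the wild type in channel 2.
#' Per gene, the wild-type signal is `base_abundance * 2^noise` and the
#' mutant signal `base_abundance * 2^(shift + dye_bias(A) + noise)`, with
#' independent N(0, `noise_sd`) draws per channel and the constant array
#' background added to both foregrounds.
#'
#' @param truth a `TruthTable` from [simulate_universe()].
#' @param fraction one of `config$fractions`.
#' @param replicate replicate index (1-based); together with the fraction it
#'   offsets the seed so each array is distinct yet reproducible.
#' @param config the [sim_config()] used to build `truth`.
#'
#' @return A tibble (`SpotTable`) with columns `gene_id`, `ch1_fg`, `ch1_bg`,
#'   `ch2_fg`, `ch2_bg`.
#' @export
simulate_array <- function(truth, fraction, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!fraction %in% config$fractions) {
    stop("fraction '", fraction, "' is not in the configured fractions (",
         paste(config$fractions, collapse = ", "), ")", call. = FALSE)
  }
  stopifnot(replicate >= 1)
  set.seed(config$seed +
             1000L * match(fraction, FRACTIONS_ALL) +
             as.integer(replicate))
  n <- nrow(truth)
  a0 <- log2(truth$base_abundance)
  bias <- config$dye_bias[1] + config$dye_bias[2] * a0
  shift <- class_shift(truth$true_class, fraction, truth$shift_effect)
  noise_wt <- rnorm(n, 0, config$noise_sd)
  noise_mut <- rnorm(n, 0, config$noise_sd)
  bg <- config$background_level
  tibble::tibble(
    gene_id = truth$gene_id,
    ch1_fg = bg + truth$base_abundance * 2^(shift + bias + noise_mut),
    ch1_bg = bg,
    ch2_fg = bg + truth$base_abundance * 2^noise_wt,
    ch2_bg = bg
  )
}

#' Simulate a qPCR Ct table over gradient fractions
#'
#' Plants per-fraction transcript abundances and converts them to threshold
#' cycles via `Ct = ct_intercept - log_E(abundance) + noise`, where `E` is
#' the primer amplification efficiency. In the wild type each gene's base
#' abundance is split evenly over the fractions; mutant lines multiply each
#' fraction by `2^shift` with the class-dependent sign pattern of
#' [simulate_array()] (NP/M vs LP/HP/P sides).
#'
#' @param truth a `TruthTable`.
#' @param genes gene ids to assay (default: all genes in `truth`).
#' @param fractions gradient pools, default the fine scheme
#'   `c("NP", "M", "LP", "HP")`.
#' @param lines sample lines; `"WT"` carries no shift, any other line carries
#'   the planted class shift.
#' @param efficiency primer efficiency in `(1, 2]`: a single number or a
#'   vector named by gene id.
#' @param ct_intercept cycle count corresponding to unit abundance.
#' @param noise_sd technical noise on the Ct scale (cycles).
#' @param n_replicates technical replicates per (gene, line, fraction).
#' @param seed integer seed.
#'
#' @return A tibble of `CtRecord` rows (`gene_id`, `line`, `fraction`,
#'   `replicate`, `ct`, `efficiency`) with the planted per-fraction
#'   abundances attached as `attr(, "planted")` (columns `gene_id`, `line`,
#'   `fraction`, `abundance`, `percent`).
#' @export
simulate_ct_table <- function(truth,
                              genes = truth$gene_id,
                              fractions = c("NP", "M", "LP", "HP"),
                              lines = c("WT", "iso4E_1"),
                              efficiency = 2,
                              ct_intercept = 35,
                              noise_sd = 0,
                              n_replicates = 3,
                              seed = 1L) {
  stopifnot(all(genes %in% truth$gene_id), length(fractions) >= 1,
            n_replicates >= 1, noise_sd >= 0)
  bad <- setdiff(fractions, FRACTIONS_ALL)
  if (length(bad) > 0) {
    stop("unknown fraction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  eff <- if (length(efficiency) == 1 && is.null(names(efficiency))) {
    setNames(rep(efficiency, length(genes)), genes)
  } else {
    efficiency[genes]
  }
  if (anyNA(eff) || any(eff <= 1) || any(eff > 2)) {
    stop("primer efficiencies must all lie in (1, 2]", call. = FALSE)
  }

  tr <- truth[match(genes, truth$gene_id), ]
  grid <- expand.grid(gene_id = genes, line = lines, fraction = fractions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$gene_id, tr$gene_id)
  shift <- ifelse(
    grid$line == "WT", 0,
    class_shift(tr$true_class[i], grid$fraction, tr$shift_effect[i])
  )
  grid$abundance <- tr$base_abundance[i] / length(fractions) * 2^shift
  if (any(grid$abundance <= 0)) {
    stop("planted abundances must be strictly positive", call. = FALSE)
  }
  planted <- tibble::as_tibble(grid)
  planted <- dplyr::mutate(
    dplyr::group_by(planted, .data$gene_id, .data$line),
    percent = 100 * .data$abundance / sum(.data$abundance)
  )
  planted <- dplyr::ungroup(planted)

  set.seed(seed)
  ct <- planted[rep(seq_len(nrow(planted)), each = n_replicates), ]
  ct$replicate <- rep(seq_len(n_replicates), nrow(planted))
  e <- unname(eff[ct$gene_id])
  ct$ct <- unname(ct_intercept - log(ct$abundance) / log(e) +
                    rnorm(nrow(ct), 0, noise_sd))
  ct$efficiency <- e
  out <- ct[, c("gene_id", "line", "fraction", "replicate", "ct",
                "efficiency")]
  attr(out, "planted") <- planted
  out
}

# Feature cassettes planted into synthetic UTRs. The background alphabet is
# {A, G}, which can form no base pair and no start/stop codon, so a feature
# is present iff it was planted.
UORF_CASSETTE <- "AUGAAAUAA"       # AUG-AAA-UAA: one internal codon
UAUG_CASSETTE <- "AUG"
HAIRPIN_CASSETTE <- paste0(strrep("G", 10), "AAAA", strrep("C", 10))

#' Simulate 5'UTR sequences with planted features
#'
#' Builds RNA sequences over an A/G background (which admits no base pairs,
#' no AUG and no stop codon) and plants feature cassettes into seeded random
#' subsets of the records: an upstream AUG, a complete uORF
#' (AUG-AAA-UAA), or a GC stem hairpin (10 G, 4-nt loop, 10 C) whose
#' built-in folding energy is at most -26 kcal/mol, well below the -20
#' stability threshold. Length classes are planted disjointly: `long`
#' records are 150 nt, `short` 60 nt, the rest 80 nt.
#'
#' @param n number of records.
#' @param plan named counts over
#'   `c("uaug", "uorf", "hairpin_stable", "long", "short")`; each count must
#'   be `<= n`, and `long + short <= n`. A record planted with a uORF also
#'   counts as carrying a uAUG (the uORF start).
#' @param seed integer seed.
#'
#' @return A list with `records` (a `UTRRecord` tibble: `accession`, `side`,
#'   `sequence`, `length`) and `truth` (per-record logicals `has_uaug`,
#'   `has_uorf`, `has_hairpin`, `is_long`).
#' @export
#' @examples
#' sim <- simulate_utr_set(6, plan = c(uaug = 3, hairpin_stable = 2), seed = 1)
#' sim$truth
simulate_utr_set <- function(n,
                             plan = c(uaug = 0, uorf = 0, hairpin_stable = 0,
                                      long = 0, short = 0),
                             seed = 1L) {
  known <- c("uaug", "uorf", "hairpin_stable", "long", "short")
  bad <- setdiff(names(plan), known)
  if (length(bad) > 0) {
    stop("unknown feature(s) in `plan`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  plan <- setNames(
    vapply(known, function(k) if (k %in% names(plan)) plan[[k]] else 0L, 0),
    known
  )
  if (any(plan < 0) || any(plan[c("uaug", "uorf", "hairpin_stable")] > n) ||
      plan[["long"]] + plan[["short"]] > n) {
    stop("contradictory plan: feature counts must fit in n = ", n,
         " records (long + short <= n)", call. = FALSE)
  }
  empty <- tibble::tibble(
    accession = character(), side = character(),
    sequence = character(), length = integer()
  )
  if (n == 0) {
    return(list(
      records = empty,
      truth = tibble::tibble(accession = character(), length = integer(),
                             has_uaug = logical(), has_uorf = logical(),
                             has_hairpin = logical(), is_long = logical())
    ))
  }

  set.seed(seed)
  accession <- sprintf("SYN%04d", seq_len(n))
  len <- rep(80L, n)
  idx_long <- if (plan[["long"]] > 0) sample.int(n, plan[["long"]]) else integer()
  remaining <- setdiff(seq_len(n), idx_long)
  idx_short <- if (plan[["short"]] > 0) {
    remaining[sample.int(length(remaining), plan[["short"]])]
  } else {
    integer()
  }
  len[idx_long] <- 150L
  len[idx_short] <- 60L
  has <- function(k) {
    picked <- if (plan[[k]] > 0) sample.int(n, plan[[k]]) else integer()
    seq_len(n) %in% picked
  }
  uaug <- has("uaug")
  uorf <- has("uorf")
  hairpin <- has("hairpin_stable")

  seqs <- vapply(seq_len(n), function(i) {
    cassettes <- c(
      if (uaug[i]) UAUG_CASSETTE,
      if (uorf[i]) UORF_CASSETTE,
      if (hairpin[i]) HAIRPIN_CASSETTE
    )
    n_bg <- len[i] - sum(nchar(cassettes))
    if (n_bg < length(cassettes) + 1) {
      stop("contradictory plan: planted cassettes do not fit in a ",
           len[i], " nt record", call. = FALSE)
    }
    # split background around the cassettes at seeded random cut points
    cuts <- sort(sample.int(n_bg, length(cassettes)))
    bg <- paste(sample(c("A", "G"), n_bg, replace = TRUE), collapse = "")
    pieces <- character()
    prev <- 0L
    for (j in seq_along(cassettes)) {
      pieces <- c(pieces, substr(bg, prev + 1L, cuts[j]), cassettes[j])
      prev <- cuts[j]
    }
    paste0(paste(pieces, collapse = ""), substr(bg, prev + 1L, n_bg))
  }, character(1))

  list(
    records = tibble::tibble(
      accession = accession, side = "five_prime",
      sequence = seqs, length = nchar(seqs)
    ),
    truth = tibble::tibble(
      accession = accession, length = len,
      has_uaug = uaug | uorf,   # a uORF starts at a uAUG
      has_uorf = uorf,
      has_hairpin = hairpin,
      is_long = len >= 100L
    )
  )
}

#' Write synthetic UTR records as FASTA
#'
#' @param records a `UTRRecord` tibble.
#' @param path output file; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(records, path) {
  set <- Biostrings::RNAStringSet(setNames(records$sequence,
                                           records$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read UTR records from a FASTA file
#'
#' @param path FASTA file (RNA or DNA alphabet; U and T are interchangeable).
#' @param side `"five_prime"` or `"three_prime"`; UTR scans are
#'   side-specific, so the side must be declared at load time.
#' @return A `UTRRecord` tibble.
#' @export
read_utr_fasta <- function(path, side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  set <- Biostrings::readBStringSet(path)
  seqs <- unname(toupper(as.character(set)))
  tibble::tibble(
    accession = names(set), side = side,
    sequence = chartr("T", "U", seqs), length = nchar(seqs)
  )
}
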