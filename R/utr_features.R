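#' Filter UTR records against a full-length accession list
#'
#' 5'UTR sets assembled from expressed sequence tags can contain truncated
#' 5' ends; a curated full-length ORF list (e.g. the Salk-Stanford-PGEC
#' Arabidopsis set) is used as the membership filter. Whether the list is
#' used to retain or to remove accessions is a mode, since usage differs
#' between resources.
#'
#' @param records a `UTRRecord` tibble.
#' @param reference_list character vector of accessions.
#' @param mode `"keep_listed"` (default: retain verified full-length
#'   accessions) or `"drop_listed"`.
#' @return The filtered tibble, input order preserved.
#' @export
filter_full_length <- function(records, reference_list,
                               mode = c("keep_listed", "drop_listed")) {
  mode <- match.arg(mode)
  if (mode == "keep_listed" && length(reference_list) == 0) {
    warning("empty reference list with mode = \"keep_listed\": ",
            "no record can be retained", call. = FALSE)
  }
  listed <- records$accession %in% reference_list
  records[if (mode == "keep_listed") listed else !listed, ]
}

#' Length class of a UTR
#'
#' @param length nucleotide length(s).
#' @param threshold class boundary; `>= threshold` (inclusive) is long.
#' @return `"ge_100"` or `"lt_100"` (labels follow the default threshold).
#' @export
classify_length <- function(length, threshold = 100) {
  ifelse(length >= threshold, "ge_100", "lt_100")
}

# normalize to RNA uppercase and validate the alphabet
as_rna <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  if (any(grepl("[^ACGU]", s))) {
    stop("invalid alphabet in sequence (expected A, C, G, U/T)",
         call. = FALSE)
  }
  s
}

require_side <- function(side, wanted, what) {
  if (any(side != wanted)) {
    stop(what, " is defined on ", wanted, " UTRs only", call. = FALSE)
  }
}

#' Find upstream AUGs in 5'UTR sequences
#'
#' Reports the 1-based start position of every AUG trinucleotide; because
#' the whole record is 5'UTR, every AUG is upstream of the main start.
#' Overlapping occurrences are all reported.
#'
#' @param sequence character vector of sequences.
#' @param side must be `"five_prime"`; passing a 3'UTR is an error, not an
#'   empty result, to catch swapped files.
#' @return A list (one element per sequence) of integer position vectors.
#' @export
#' @examples
#' find_uaugs("CCCAUGCC")  # list(4L)
find_uaugs <- function(sequence, side = "five_prime") {
  require_side(side, "five_prime", "the uAUG scan")
  s <- as_rna(sequence)
  lapply(s, function(x) {
    hits <- gregexpr("(?=AUG)", x, perl = TRUE)[[1]]
    if (hits[1] == -1) integer() else as.integer(hits)
  })
}

#' Find upstream ORFs in 5'UTR sequences
#'
#' From each upstream AUG, in-frame triplets are read until the first stop
#' codon (UAA, UAG, UGA) lying wholly within the UTR. An AUG without such a
#' stop is not a uORF. The ORF is reported when it has at least
#' `min_internal_codons` codons between start and stop.
#'
#' @inheritParams find_uaugs
#' @param min_internal_codons minimum number of codons between the AUG and
#'   the stop (default 1, i.e. `AUG UAA` alone does not qualify).
#' @return A list of tibbles with columns `start` (AUG position), `stop_end`
#'   (last base of the stop codon) and `n_codons` (internal codons).
#' @export
#' @examples
#' find_uorfs("CCAUGAAAUAGCC")  # start 3, stop_end 11, 1 internal codon
find_uorfs <- function(sequence, side = "five_prime",
                       min_internal_codons = 1) {
  require_side(side, "five_prime", "the uORF scan")
  starts <- find_uaugs(sequence, side)
  s <- as_rna(sequence)
  stops <- c("UAA", "UAG", "UGA")
  mapply(function(x, st) {
    rows <- lapply(st, function(p) {
      q <- p + 3L
      n_codons <- 0L
      while (q + 2L <= nchar(x)) {
        codon <- substr(x, q, q + 2L)
        if (codon %in% stops) {
          if (n_codons >= min_internal_codons) {
            return(tibble::tibble(start = p, stop_end = q + 2L,
                                  n_codons = n_codons))
          }
          return(NULL)
        }
        n_codons <- n_codons + 1L
        q <- q + 3L
      }
      NULL
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      tibble::tibble(start = integer(), stop_end = integer(),
                     n_codons = integer())
    } else {
      out
    }
  }, s, starts, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Default UTR motif registry
#'
#' Ships two side-specific patterns:
#' * `cpe` (3'UTR): the canonical cytoplasmic polyadenylation element
#'   consensus `UUUUUAU`, matched literally (overridable with any regex).
#' * `ires_like` (5'UTR): a stand-in descriptor — any window of at least
#'   25 nt with at least 80% pyrimidine (C/U) content, the classic
#'   polypyrimidine signature of cellular IRES candidates. The published
#'   UTRScan/RegRNA descriptors are not reproduced here; both parameters
#'   are configurable.
#'
#' @return A named list of pattern definitions usable by [scan_motifs()].
#' @export
default_pattern_registry <- function() {
  list(
    cpe = list(side = "three_prime", type = "regex", pattern = "UUUUUAU"),
    ires_like = list(side = "five_prime", type = "pyrimidine_window",
                     min_width = 25L, min_frac = 0.8)
  )
}

#' Scan UTR sequences for registered motifs
#'
#' Each pattern applies only to records of its declared side; patterns for
#' the other side are skipped silently, so a mixed registry can be used on
#' any record.
#'
#' @param sequence character vector of sequences.
#' @param side `"five_prime"` or `"three_prime"`, length 1 or one per
#'   sequence.
#' @param patterns a registry as returned by [default_pattern_registry()]:
#'   a named list of `list(side=, type=, ...)` where `type` is `"regex"`
#'   (field `pattern`) or `"pyrimidine_window"` (fields `min_width`,
#'   `min_frac`).
#' @return A list (one element per sequence) of named lists of hit tibbles
#'   (`start`, `end`, 1-based inclusive).
#' @export
scan_motifs <- function(sequence, side, patterns = default_pattern_registry()) {
  s <- as_rna(sequence)
  side <- rep_len(side, length(s))
  for (p in patterns) {
    if (!is.list(p) || is.null(p$type) || is.null(p$side) ||
        (p$type == "regex" && is.null(p$pattern)) ||
        !p$type %in% c("regex", "pyrimidine_window")) {
      stop("malformed pattern definition in registry", call. = FALSE)
    }
  }
  lapply(seq_along(s), function(i) {
    hits <- lapply(patterns, function(p) {
      if (p$side != side[i]) return(NULL)
      if (p$type == "regex") {
        m <- gregexpr(p$pattern, s[i], perl = TRUE)[[1]]
        if (m[1] == -1) {
          tibble::tibble(start = integer(), end = integer())
        } else {
          tibble::tibble(start = as.integer(m),
                         end = as.integer(m) + attr(m, "match.length") - 1L)
        }
      } else {
        pyrimidine_windows(s[i], p$min_width, p$min_frac)
      }
    })
    hits[!vapply(hits, is.null, logical(1))]
  })
}

# maximal runs of width-`w` windows whose pyrimidine content >= min_frac,
# merged into intervals
pyrimidine_windows <- function(seq, w, min_frac) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (n < w) return(tibble::tibble(start = integer(), end = integer()))
  py <- cumsum(c(0L, b %in% c("C", "U")))
  starts <- seq_len(n - w + 1L)
  frac <- (py[starts + w] - py[starts]) / w
  hit <- frac >= min_frac
  if (!any(hit)) return(tibble::tibble(start = integer(), end = integer()))
  r <- rle(hit)
  pos <- cumsum(c(1L, r$lengths))
  runs <- which(r$values)
  tibble::tibble(
    start = starts[pos[runs]],
    end = starts[pos[runs + 1L] - 1L] + w - 1L
  )
}

#' Annotate UTR records with the full feature set
#'
#' Runs every scanner appropriate to a record's side: length class for
#' both sides; folding stability, uAUGs, uORFs and 5'-side motifs for
#' 5'UTRs; 3'-side motifs (CPE by default) for 3'UTRs.
#'
#' @param records a `UTRRecord` tibble (`accession`, `side`, `sequence`,
#'   `length`).
#' @param dg_threshold stability threshold in kcal/mol; a record is
#'   `stable` when `delta_g < dg_threshold` (strict). Interpret only
#'   relative to the folding engine recorded in the output.
#' @param length_threshold boundary of the length classes (inclusive
#'   upper class).
#' @param min_internal_codons see [find_uorfs()].
#' @param patterns motif registry, see [scan_motifs()].
#' @param engine folding engine, see [fold_mfe()].
#' @return A `UTRFeatureSet` tibble: `accession`, `side`, `length`,
#'   `length_class`, `delta_g`, `stable`, `engine`, `n_uaug`, `n_uorf`,
#'   and one `n_<pattern>` column per registered motif (NA where a feature
#'   does not apply to the record's side).
#' @export
annotate_utrs <- function(records,
                          dg_threshold = -20,
                          length_threshold = 100,
                          min_internal_codons = 1,
                          patterns = default_pattern_registry(),
                          engine = "builtin") {
  stopifnot(all(c("accession", "side", "sequence") %in% names(records)))
  len <- nchar(records$sequence)
  is5 <- records$side == "five_prime"

  delta_g <- fold_mfe(records$sequence, engine = engine)
  n_uaug <- rep(NA_integer_, nrow(records))
  n_uorf <- rep(NA_integer_, nrow(records))
  if (any(is5)) {
    n_uaug[is5] <- lengths(find_uaugs(records$sequence[is5]))
    n_uorf[is5] <- vapply(
      find_uorfs(records$sequence[is5],
                 min_internal_codons = min_internal_codons),
      nrow, integer(1)
    )
  }
  motif_hits <- scan_motifs(records$sequence, records$side, patterns)

  out <- tibble::tibble(
    accession = records$accession,
    side = records$side,
    length = len,
    length_class = classify_length(len, length_threshold),
    delta_g = delta_g,
    stable = delta_g < dg_threshold,
    engine = if (is.function(engine)) "external" else engine,
    n_uaug = n_uaug,
    n_uorf = n_uorf
  )
  for (pname in names(patterns)) {
    out[[paste0("n_", pname)]] <- vapply(motif_hits, function(h) {
      if (pname %in% names(h)) nrow(h[[pname]]) else NA_integer_
    }, integer(1))
  }
  out
}

#' Group-level UTR feature percentage table
#'
#' For each gene group and each feature, the percentage of records carrying
#' the feature, by UTR side — the layout of a published UTR characteristics
#' table: length classes and folding stability for both sides, uAUG / uORF /
#' IRES-like percentages for the 5' side, CPE for the 3' side. A baseline
#' column is computed from a seeded random sample of accessions drawn from a
#' background pool (length and stability rows only; motif baselines are
#' reported as NA, mirroring the usual presentation).
#'
#' @param features_by_group named list of `UTRFeatureSet` tibbles (see
#'   [annotate_utrs()]), one per gene group; each may contain records of
#'   both sides.
#' @param random_pool optional `UTRRecord` tibble of background sequences
#'   for the baseline column.
#' @param n_random number of accessions to sample from the pool (default
#'   80).
#' @param seed seed for the baseline sample.
#' @param ... annotation parameters passed to [annotate_utrs()] for the
#'   random pool.
#' @return A tibble with columns `side`, `feature`, one percentage column
#'   per group, and `random` when a pool was supplied. Length-class rows
#'   within a (group, side) sum to 100.
#' @export
summarize_utr_table <- function(features_by_group, random_pool = NULL,
                                n_random = 80, seed = 1L, ...) {
  stopifnot(length(features_by_group) > 0,
            !is.null(names(features_by_group)))
  if (any(vapply(features_by_group, nrow, integer(1)) == 0)) {
    stop("every group must contain at least one annotated record",
         call. = FALSE)
  }

  feature_rows <- function(f) {
    pct <- function(x) 100 * mean(x, na.rm = TRUE)
    by_side <- function(side, value) {
      sub <- f[f$side == side, ]
      if (nrow(sub) == 0) return(NA_real_)
      pct(value(sub))
    }
    c(
      five_ge_100 = by_side("five_prime", function(s) s$length_class == "ge_100"),
      five_lt_100 = by_side("five_prime", function(s) s$length_class == "lt_100"),
      five_stable = by_side("five_prime", function(s) s$stable),
      five_uaug = by_side("five_prime", function(s) s$n_uaug > 0),
      five_uorf = by_side("five_prime", function(s) s$n_uorf > 0),
      five_ires_like = by_side("five_prime", function(s) {
        if ("n_ires_like" %in% names(s)) s$n_ires_like > 0 else NA
      }),
      three_ge_100 = by_side("three_prime", function(s) s$length_class == "ge_100"),
      three_lt_100 = by_side("three_prime", function(s) s$length_class == "lt_100"),
      three_cpe = by_side("three_prime", function(s) {
        if ("n_cpe" %in% names(s)) s$n_cpe > 0 else NA
      })
    )
  }

  cols <- lapply(features_by_group, feature_rows)
  out <- tibble::tibble(
    side = c(rep("five_prime", 6), rep("three_prime", 3)),
    feature = c("ge_100", "lt_100", "stable", "uaug", "uorf", "ires_like",
                "ge_100", "lt_100", "cpe")
  )
  for (g in names(features_by_group)) out[[g]] <- unname(cols[[g]])

  if (!is.null(random_pool)) {
    pool_acc <- unique(random_pool$accession)
    if (n_random > length(pool_acc)) {
      stop("n_random (", n_random, ") exceeds the pool size (",
           length(pool_acc), ")", call. = FALSE)
    }
    set.seed(seed)
    picked <- sample(pool_acc, n_random)
    baseline <- annotate_utrs(
      random_pool[random_pool$accession %in% picked, ], ...
    )
    rnd <- feature_rows(baseline)
    # motif baselines are not reported, as in the standard presentation
    rnd[c("five_uaug", "five_uorf", "five_ires_like", "three_cpe")] <- NA_real_
    out$random <- unname(rnd)
  }
  out
}
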