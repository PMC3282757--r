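# Independent oracles, implemented from the definitions rather than by
# calling the package's engines.

# Sliding-window z-score, recomputed gene by gene from the stated policy:
# sort by (A, gene_id); the window is the window_size nearest ranks,
# centered where possible and slid inward at the edges; sample sd.
oracle_window_zscore <- function(ma, window_size) {
  ord <- order(ma$A, ma$gene_id)
  a <- ma$A[ord]
  m <- ma$M[ord]
  ids <- ma$gene_id[ord]
  n <- length(m)
  z <- numeric(n)
  for (r in seq_len(n)) {
    lo <- r - (window_size - 1L) %/% 2L
    if (lo < 1L) lo <- 1L
    if (lo + window_size - 1L > n) lo <- n - window_size + 1L
    win <- m[lo:(lo + window_size - 1L)]
    mu <- sum(win) / window_size
    sdev <- sqrt(sum((win - mu)^2) / (window_size - 1))
    z[r] <- if (sdev == 0) 0 else (m[r] - mu) / sdev
  }
  data.frame(gene_id = ids, z = z)[order(ids), ]
}

# Exhaustive enumeration of every nested structure (pseudoknot-free pair
# set, minimum loop 3) and direct scoring: pair energies plus a hairpin
# penalty per pair that encloses no other pair. Feasible for length <= 12.
oracle_fold_mfe <- function(sequence) {
  pair_e <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2,
              "GU" = -1, "UG" = -1)
  b <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  n <- length(b)

  enumerate <- function(i, j) {
    # all nested pair sets on [i, j], each a list of c(i, k) pairs
    if (j - i < 4L) return(list(list()))
    out <- enumerate(i + 1L, j)              # i unpaired
    for (k in seq(i + 4L, j)) {
      if (is.na(pair_e[paste0(b[i], b[k])])) next
      inner <- enumerate(i + 1L, k - 1L)
      rest <- if (k < j) enumerate(k + 1L, j) else list(list())
      for (s1 in inner) for (s2 in rest) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), s1, s2)
      }
    }
    out
  }

  score <- function(pairs) {
    if (length(pairs) == 0) return(0)
    e <- sum(vapply(pairs, function(p) pair_e[paste0(b[p[1]], b[p[2]])],
                    numeric(1)))
    hairpins <- sum(vapply(pairs, function(p) {
      !any(vapply(pairs, function(q) q[1] > p[1] && q[2] < p[2],
                  logical(1)))
    }, logical(1)))
    e + 4 * hairpins
  }

  if (n < 8) return(0)
  min(0, vapply(enumerate(1L, n), score, numeric(1)))
}

random_rna <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rev_complement_rna <- function(sequence) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", sequence), "")[[1]]),
        collapse = "")
}
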