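test_that("full-length filtering keeps or drops listed accessions, order preserved", {
  recs <- tibble::tibble(accession = c("a", "b", "c", "d", "e"),
                         side = "five_prime",
                         sequence = "AAAA", length = 4L)
  keep <- filter_full_length(recs, c("b", "d"))
  expect_equal(keep$accession, c("b", "d"))
  drop <- filter_full_length(recs, c("b", "d"), mode = "drop_listed")
  expect_equal(drop$accession, c("a", "c", "e"))
  expect_equal(filter_full_length(recs, c("x", "y"),
                                  mode = "drop_listed")$accession,
               recs$accession)
  expect_warning(filter_full_length(recs, character()), "empty reference")
})

test_that("length classes use an inclusive 100 nt boundary", {
  expect_equal(classify_length(c(100, 99, 1, 250)),
               c("ge_100", "lt_100", "lt_100", "ge_100"))
})

test_that("uAUG scanning reports all (and only) AUG starts, 5' side only", {
  expect_equal(find_uaugs("CCCAUGCC")[[1]], 4L)
  expect_equal(find_uaugs("AUGAUG")[[1]], c(1L, 4L))
  expect_equal(find_uaugs("CCCCCC")[[1]], integer())
  expect_equal(find_uaugs("CATGC")[[1]], 2L)  # DNA input accepted
  expect_error(find_uaugs("AUG", side = "three_prime"), "five_prime")
})

test_that("uORF detection requires an in-frame stop within the UTR", {
  orf <- find_uorfs("CCAUGAAAUAGCC")[[1]]
  expect_equal(orf$start, 3L)
  expect_equal(orf$stop_end, 11L)
  expect_equal(orf$n_codons, 1L)

  expect_equal(nrow(find_uorfs("CCAUGAAACC")[[1]]), 0)   # no stop
  expect_equal(nrow(find_uorfs("AUGUAA")[[1]]), 0)        # no internal codon
  expect_equal(nrow(find_uorfs("AUGUAA", min_internal_codons = 0)[[1]]), 1)
  # out-of-frame stop does not terminate the ORF
  expect_equal(nrow(find_uorfs("AUGAUAAAA")[[1]]), 0)
})

test_that("uORF starts are always a subset of uAUG positions (fuzz)", {
  set.seed(71)
  for (i in 1:50) {
    s <- random_rna(sample(20:120, 1))
    orfs <- find_uorfs(s)[[1]]
    augs <- find_uaugs(s)[[1]]
    expect_true(all(orfs$start %in% augs))
  }
})

test_that("builtin fold reproduces hand-scored structures", {
  expect_equal(fold_mfe("AAAAAAAA"), 0)
  # 5 GC pairs (-15) closing one hairpin loop (+4)
  expect_equal(fold_mfe("GGGGGAAAACCCCC"), -11)
  expect_equal(fold_mfe("GGGGGAAAACCCCC"), oracle_fold_mfe("GGGGGAAAACCCCC"))
  expect_equal(fold_mfe("CCCCC"), 0)  # below the 8 nt minimum
  expect_error(fold_mfe("ACGX"), "alphabet")
})

test_that("builtin fold equals exhaustive enumeration for short sequences", {
  set.seed(72)
  for (i in 1:60) {
    s <- random_rna(sample(8:12, 1))
    expect_equal(fold_mfe(s), oracle_fold_mfe(s), info = s)
  }
})

test_that("MFE is reverse-complement invariant without wobble-capable bases", {
  # Watson-Crick pairs map one-to-one under reverse complement (GC <-> GC,
  # AU <-> UA) but GU wobble maps to the unpairable AC, so the symmetry
  # holds exactly on alphabets where no GU pair can arise on either strand:
  # pure {G, C} and pure {A, U}
  set.seed(73)
  for (alphabet in list(c("G", "C"), c("A", "U"))) {
    for (i in 1:15) {
      s <- random_rna(sample(10:40, 1), alphabet = alphabet)
      expect_equal(fold_mfe(s), fold_mfe(rev_complement_rna(s)), info = s)
    }
  }
  # and GU wobble does break it: witness sequence (values confirmed by the
  # enumeration oracle)
  w <- "GGGGGGAAAAUUUUUU"
  expect_equal(fold_mfe(w), oracle_fold_mfe(w))
  expect_equal(fold_mfe(rev_complement_rna(w)),
               oracle_fold_mfe(rev_complement_rna(w)))
  expect_equal(fold_mfe(w), -3)
  expect_equal(fold_mfe(rev_complement_rna(w)), -2)
})

test_that("motif scanning finds CPE literally and IRES-like pyrimidine windows", {
  hits <- scan_motifs("AAAUUUUUAUGG", "three_prime")[[1]]
  expect_equal(hits$cpe$start, 4L)
  expect_equal(hits$cpe$end, 10L)
  expect_false("ires_like" %in% names(hits))

  py <- scan_motifs(strrep("CU", 15), "five_prime")[[1]]
  expect_gte(nrow(py$ires_like), 1)
  expect_false("cpe" %in% names(py))

  none <- scan_motifs("AAAA", "three_prime", patterns = list())[[1]]
  expect_equal(length(none), 0)
  expect_error(
    scan_motifs("AAAA", "three_prime",
                patterns = list(bad = list(type = "regex"))),
    "malformed pattern"
  )
})

test_that("annotation assembles side-appropriate features", {
  recs <- tibble::tibble(
    accession = c("u5", "u3"),
    side = c("five_prime", "three_prime"),
    sequence = c("CCAUGAAAUAGCC", "AAAUUUUUAUGG"),
    length = c(13L, 12L)
  )
  f <- annotate_utrs(recs)
  expect_equal(f$n_uaug, c(1L, NA))
  expect_equal(f$n_uorf, c(1L, NA))
  expect_equal(f$n_cpe, c(NA, 1L))
  expect_equal(f$length_class, c("lt_100", "lt_100"))
  expect_true(all(f$engine == "builtin"))
  expect_equal(f$stable, c(FALSE, FALSE))
})

test_that("group summaries recover planted fractions and percentages are coherent", {
  simA <- simulate_utr_set(20, plan = c(uaug = 10, hairpin_stable = 5,
                                        long = 8, short = 12), seed = 81)
  simB <- simulate_utr_set(10, plan = c(uorf = 4, long = 10), seed = 82)
  fA <- annotate_utrs(simA$records)
  fB <- annotate_utrs(simB$records)
  tab <- summarize_utr_table(list(group_I = fA, group_II = fB))

  pick <- function(tab, side, feature, col) {
    tab[[col]][tab$side == side & tab$feature == feature]
  }
  expect_equal(pick(tab, "five_prime", "uaug", "group_I"),
               100 * mean(simA$truth$has_uaug))
  expect_equal(pick(tab, "five_prime", "stable", "group_I"),
               100 * mean(simA$truth$has_hairpin))
  expect_equal(pick(tab, "five_prime", "ge_100", "group_I"),
               100 * mean(simA$truth$is_long))
  expect_equal(pick(tab, "five_prime", "uorf", "group_II"),
               100 * mean(simB$truth$has_uorf))
  expect_equal(pick(tab, "five_prime", "ge_100", "group_II"), 100)
  expect_equal(pick(tab, "five_prime", "lt_100", "group_II"), 0)

  # length classes partition each group
  expect_equal(pick(tab, "five_prime", "ge_100", "group_I") +
                 pick(tab, "five_prime", "lt_100", "group_I"), 100)
  pcts <- unlist(tab[, c("group_I", "group_II")])
  expect_true(all(pcts[!is.na(pcts)] >= 0 & pcts[!is.na(pcts)] <= 100))
})

test_that("the random baseline is seeded, reproducible and bounded by the pool", {
  pool <- simulate_utr_set(120, plan = c(uaug = 30, hairpin_stable = 40,
                                         long = 50, short = 60),
                           seed = 83)$records
  grp <- annotate_utrs(simulate_utr_set(10, plan = c(uaug = 5),
                                        seed = 84)$records)
  t1 <- summarize_utr_table(list(g = grp), random_pool = pool,
                            n_random = 80, seed = 7)
  t2 <- summarize_utr_table(list(g = grp), random_pool = pool,
                            n_random = 80, seed = 7)
  expect_identical(t1, t2)
  t3 <- summarize_utr_table(list(g = grp), random_pool = pool,
                            n_random = 80, seed = 8)
  expect_false(identical(t1$random, t3$random))
  # motif baselines are not reported
  expect_true(all(is.na(t1$random[t1$feature %in%
                                    c("uaug", "uorf", "ires_like", "cpe")])))
  expect_error(
    summarize_utr_table(list(g = grp), random_pool = pool, n_random = 200),
    "exceeds the pool"
  )
})
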