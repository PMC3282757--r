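test_that("simulate_universe honours class counts, seeding and preconditions", {
  cfg <- sim_config(n_genes = 1000, seed = 1)
  truth <- simulate_universe(cfg, c(group_I = 50, group_II = 30))
  expect_equal(sum(truth$true_class == "group_I"), 50)
  expect_equal(sum(truth$true_class == "group_II"), 30)
  expect_equal(sum(truth$true_class == "unchanged"), 920)
  expect_false(any(duplicated(truth$gene_id)))
  expect_true(all(truth$base_abundance > 0))
  expect_true(all(truth$shift_effect[truth$true_class != "unchanged"] > 0))

  expect_identical(truth, simulate_universe(cfg, c(group_I = 50, group_II = 30)))
  truth2 <- simulate_universe(sim_config(n_genes = 1000, seed = 2),
                              c(group_I = 50, group_II = 30))
  expect_false(identical(truth$base_abundance, truth2$base_abundance))

  expect_error(simulate_universe(cfg, c(group_I = 600, group_II = 600)),
               "exceeds n_genes")
  expect_error(simulate_universe(cfg, c(group_I = 5), effect_size = 0),
               "must be > 0")
  expect_error(simulate_universe(cfg, c(not_a_class = 5)), "unknown class")
})

test_that("simulate_array implements the channel model exactly when noise is off", {
  cfg <- sim_config(n_genes = 10, noise_sd = 0, dye_bias = c(0, 0),
                    background_level = 0, seed = 3)
  truth <- simulate_universe(cfg, c(group_I = 3, group_II = 3),
                             effect_size = 1)
  truth$base_abundance <- rep(500, 10)

  for (f in c("NP", "P", "T")) {
    spot <- simulate_array(truth, f, 1, cfg)
    unchanged <- truth$true_class == "unchanged"
    expect_equal(spot$ch1_fg[unchanged], rep(500, sum(unchanged)))
    expect_equal(spot$ch2_fg, rep(500, 10))
  }
  # sign convention: group I gains in NP, loses in P; total untouched
  g1 <- truth$true_class == "group_I"
  g2 <- truth$true_class == "group_II"
  np <- simulate_array(truth, "NP", 1, cfg)
  p <- simulate_array(truth, "P", 1, cfg)
  tt <- simulate_array(truth, "T", 1, cfg)
  expect_equal(np$ch1_fg[g1] / np$ch2_fg[g1], rep(2, 3))
  expect_equal(p$ch1_fg[g1] / p$ch2_fg[g1], rep(0.5, 3))
  expect_equal(np$ch1_fg[g2] / np$ch2_fg[g2], rep(0.5, 3))
  expect_equal(p$ch1_fg[g2] / p$ch2_fg[g2], rep(2, 3))
  expect_equal(tt$ch1_fg / tt$ch2_fg, rep(1, 10))

  expect_error(simulate_array(truth, "LP", 1, cfg), "not in the configured")
})

test_that("planted dye bias appears in M as its closed form", {
  cfg <- sim_config(n_genes = 20, noise_sd = 0, dye_bias = c(0.5, 0.1),
                    background_level = 0, seed = 4)
  truth <- simulate_universe(cfg, c(group_I = 0, group_II = 0))
  spot <- simulate_array(truth, "NP", 1, cfg)
  a0 <- log2(truth$base_abundance)
  m <- log2(spot$ch1_fg / spot$ch2_fg)
  expect_equal(m, 0.5 + 0.1 * a0, tolerance = 1e-12)
})

test_that("simulate_array is reproducible per (fraction, replicate) and distinct across them", {
  cfg <- sim_config(n_genes = 200, seed = 7)
  truth <- simulate_universe(cfg)
  a <- simulate_array(truth, "NP", 1, cfg)
  expect_identical(a, simulate_array(truth, "NP", 1, cfg))
  expect_false(identical(a$ch2_fg, simulate_array(truth, "NP", 2, cfg)$ch2_fg))
  expect_false(identical(a$ch2_fg, simulate_array(truth, "P", 1, cfg)$ch2_fg))
})

test_that("simulate_ct_table maps abundance to Ct through the efficiency", {
  cfg <- sim_config(n_genes = 4, seed = 5)
  truth <- simulate_universe(cfg, c(group_I = 2))
  ct <- simulate_ct_table(truth, fractions = c("NP", "P"), lines = "WT",
                          efficiency = 2, noise_sd = 0, n_replicates = 1,
                          seed = 9)
  planted <- attr(ct, "planted")
  # closed form: Ct = intercept - log_E(abundance)
  expect_equal(ct$ct, 35 - log2(planted$abundance), tolerance = 1e-12)

  # halving the abundance raises Ct by exactly 1 at E = 2 ...
  g <- truth[1, ]
  g$base_abundance <- 100
  half <- g; half$base_abundance <- 50
  ct_full <- simulate_ct_table(g, fractions = c("NP", "P"), lines = "WT",
                               noise_sd = 0, n_replicates = 1)
  ct_half <- simulate_ct_table(half, fractions = c("NP", "P"), lines = "WT",
                               noise_sd = 0, n_replicates = 1)
  expect_equal(ct_half$ct - ct_full$ct, c(1, 1))
  # ... and by 1/log2(1.9) at E = 1.9
  ct_full19 <- simulate_ct_table(g, fractions = c("NP", "P"), lines = "WT",
                                 efficiency = 1.9, noise_sd = 0,
                                 n_replicates = 1)
  ct_half19 <- simulate_ct_table(half, fractions = c("NP", "P"), lines = "WT",
                                 efficiency = 1.9, noise_sd = 0,
                                 n_replicates = 1)
  expect_equal(ct_half19$ct - ct_full19$ct, rep(log(2) / log(1.9), 2),
               tolerance = 1e-12)

  # equal abundances in all fractions give identical Ct (WT, noise off)
  u <- truth[truth$true_class == "unchanged", ][1, ]
  ct_u <- simulate_ct_table(u, fractions = c("NP", "M", "LP", "HP"),
                            lines = "WT", noise_sd = 0, n_replicates = 1)
  expect_equal(length(unique(ct_u$ct)), 1)

  expect_error(
    simulate_ct_table(truth, lines = "WT", efficiency = 2.5),
    "in \\(1, 2\\]"
  )
})

test_that("simulate_utr_set plants exactly the requested features", {
  sim <- simulate_utr_set(12, plan = c(uaug = 12), seed = 1)
  expect_true(all(lengths(find_uaugs(sim$records$sequence)) >= 1))
  expect_true(all(sim$truth$has_uaug))

  hp <- simulate_utr_set(5, plan = c(hairpin_stable = 5), seed = 2)
  expect_true(all(fold_mfe(hp$records$sequence) < -20))

  # unplanted records carry nothing: no AUG, no uORF, no stable fold
  bare <- simulate_utr_set(10, plan = c(long = 4, short = 3), seed = 3)
  expect_true(all(lengths(find_uaugs(bare$records$sequence)) == 0))
  expect_true(all(fold_mfe(bare$records$sequence) > -20))
  expect_equal(sum(bare$truth$is_long), 4)
  expect_equal(sum(bare$records$length < 100), 6)

  # determinism and the empty case
  expect_identical(simulate_utr_set(8, c(uorf = 4), seed = 9),
                   simulate_utr_set(8, c(uorf = 4), seed = 9))
  empty <- simulate_utr_set(0)
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$truth), 0)

  expect_error(simulate_utr_set(3, plan = c(uaug = 5)), "contradictory plan")
  expect_error(simulate_utr_set(4, plan = c(long = 3, short = 2)),
               "contradictory plan")
})

test_that("planted uORFs are detected with an in-frame stop inside the record", {
  sim <- simulate_utr_set(10, plan = c(uorf = 10), seed = 4)
  orfs <- find_uorfs(sim$records$sequence)
  expect_true(all(vapply(orfs, nrow, integer(1)) >= 1))
  # the uORF start is a reported uAUG position for every record
  augs <- find_uaugs(sim$records$sequence)
  for (i in seq_along(orfs)) {
    expect_true(all(orfs[[i]]$start %in% augs[[i]]))
  }
})

test_that("UTR FASTA round-trips through Biostrings", {
  sim <- simulate_utr_set(6, plan = c(uaug = 2, hairpin_stable = 2), seed = 5)
  path <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(sim$records, path)
  back <- read_utr_fasta(path, side = "five_prime")
  expect_equal(back$accession, sim$records$accession)
  expect_equal(back$sequence, sim$records$sequence)
})
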