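mk_pair <- function(log2fc1, log2fc2, fdr1, fdr2, fpm_c, fpm_t,
                    biotype = "protein_coding") {
  g <- sprintf("G%03d", seq_along(log2fc1))
  list(c1 = data.frame(gene_id = g, biotype = biotype, log2fc = log2fc1,
                       fdr = fdr1, fpm_control = fpm_c,
                       fpm_treated = fpm_t, stringsAsFactors = FALSE),
       c2 = data.frame(gene_id = g, biotype = biotype, log2fc = log2fc2,
                       fdr = fdr2, fpm_control = fpm_c,
                       fpm_treated = fpm_t, stringsAsFactors = FALSE))
}

test_that("each consensus rule acts as specified on boundary cases", {
  tabs <- mk_pair(
    log2fc1 = c(0.7, -1.0, 0.7, 0.5, 0.7, -1.0),
    log2fc2 = c(0.7, -1.0, 0.7, 0.6, -0.7, -1.0),
    fdr1 = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.005),
    fdr2 = c(0.005, 0.005, 0.05, 0.005, 0.005, 0.005),
    fpm_c = c(50, 4, 50, 50, 50, 50),
    fpm_t = c(6, 10, 50, 50, 50, 4))
  kept <- apply_consensus_filter(tabs)
  # G001: up, all rules pass (fpm_treated 6 > 5)
  # G002: down but control FPM 4 <= 5 -> excluded by the side rule
  # G003: FDR 0.05 in the second caller -> excluded (both-tools rule)
  # G004: consensus 0.55 < log2(1.5) -> excluded
  # G005: callers disagree in sign -> excluded, logged as discordant
  # G006: down, control FPM 50 > 5 -> retained (treated FPM irrelevant)
  expect_setequal(kept$gene_id, c("G001", "G006"))
  expect_equal(kept$direction[kept$gene_id == "G001"], "up")
  expect_equal(kept$direction[kept$gene_id == "G006"], "down")
  expect_equal(attr(kept, "discordant")$gene_id, "G005")
})

test_that("filter matches a brute-force oracle on a large synthetic table", {
  truth <- simulate_de_truth(n_genes = 5000, seed = 11)
  tabs <- simulate_de_tables(truth, sd_log2fc = c(0.15, 0.15), seed = 12)
  t1 <- tabs[[1]][tabs[[1]]$contrast == "6h", ]
  t2 <- tabs[[2]][tabs[[2]]$contrast == "6h", ]
  kept <- apply_consensus_filter(list(t1, t2))
  oracle <- brute_force_consensus(t1, t2)
  expect_identical(kept$gene_id, oracle)
})

test_that("filter is monotone in its thresholds and symmetric in callers", {
  truth <- simulate_de_truth(n_genes = 1500, seed = 13)
  tabs <- simulate_de_tables(truth, sd_log2fc = c(0.2, 0.2), seed = 14)
  t1 <- tabs[[1]][tabs[[1]]$contrast == "24h", ]
  t2 <- tabs[[2]][tabs[[2]]$contrast == "24h", ]
  base <- apply_consensus_filter(list(t1, t2))

  for (th in list(consensus_thresholds(fdr_max = 0.001),
                  consensus_thresholds(min_abs_log2fc = 1),
                  consensus_thresholds(min_fpm = 20))) {
    tight <- apply_consensus_filter(list(t1, t2), th)
    expect_true(all(tight$gene_id %in% base$gene_id))
  }

  swapped <- apply_consensus_filter(list(t2, t1))
  expect_identical(swapped$gene_id, base$gene_id)
  expect_equal(swapped$consensus_log2fc, base$consensus_log2fc)

  shuffled <- apply_consensus_filter(
    list(t1[sample(nrow(t1)), ], t2[sample(nrow(t2)), ]))
  expect_identical(shuffled$gene_id, base$gene_id)
})

test_that("temporal classes are recovered exactly at zero caller noise", {
  truth <- simulate_de_truth(n_genes = 3000, fpm_meanlog = log(50),
                             fpm_sdlog = 0, seed = 15)
  tabs <- simulate_de_tables(truth, sd_log2fc = c(0, 0))
  s6 <- apply_consensus_filter(tabs, contrast = "6h")
  s24 <- apply_consensus_filter(tabs, contrast = "24h")
  tc <- classify_temporal(s6, s24)

  planted <- truth$class[match(tc$gene_id, truth$gene_id)]
  expect_identical(tc$class, planted)
  expect_equal(nrow(tc), sum(truth$class != "null"))

  # classes partition the union of the two sets
  expect_equal(sort(tc$gene_id), sort(union(s6$gene_id, s24$gene_id)))
  expect_false(anyDuplicated(tc$gene_id) > 0)

  ov <- attr(tc, "overlap")
  n_both_truth <- sum(truth$class %in% c("prolonged", "biphasic"))
  n24_truth <- sum(truth$class %in% c("late_onset", "prolonged", "biphasic"))
  expect_equal(ov$n_both, n_both_truth)
  expect_equal(ov$fraction_of_24h, n_both_truth / n24_truth)

  # single-timepoint direction cases
  expect_true(all(tc$class[!is.na(tc$log2fc_6h) & is.na(tc$log2fc_24h)] ==
                    "early_transient"))

  empty <- s24[0, ]
  ov0 <- attr(classify_temporal(s6, empty), "overlap")
  expect_true(is.na(ov0$fraction_of_24h))
  expect_equal(ov0$flag, "empty 24 h set")
})

test_that("gene accounting separates recruited, enhanced and lost genes", {
  set_from <- function(ids, lfc) data.frame(
    gene_id = ids, biotype = "protein_coding", consensus_log2fc = lfc,
    stringsAsFactors = FALSE)

  # exact linear case: combined = 1.3 x single on all overlap genes
  a <- set_from(c("g1", "g2", "g3"), c(1, -2, 0.8))
  b <- set_from(c("g3", "g4"), c(0.8, 1.5))
  ab <- set_from(c("g1", "g2", "g3", "g4", "g9"),
                 c(1.3, -2.6, 1.04, 1.95, 2))
  acc <- synergy_gene_accounting(a, b, ab)
  expect_equal(acc$recruited, "g9")
  expect_equal(acc$lost, character(0))
  expect_equal(acc$slope, 1.3)
  expect_equal(acc$n_flipped, 0)

  # combined set equal to the union: nothing recruited
  ab2 <- set_from(c("g1", "g2", "g3", "g4"), c(1, -2, 0.8, 1.5))
  expect_equal(synergy_gene_accounting(a, b, ab2)$recruited, character(0))

  # slope is scale-invariant
  scale_set <- function(s, c) { s$consensus_log2fc <- s$consensus_log2fc * c; s }
  acc2 <- synergy_gene_accounting(scale_set(a, 3), scale_set(b, 3),
                                  scale_set(ab, 3))
  expect_equal(acc2$slope, acc$slope)

  # too little overlap: flagged, no slope
  acc3 <- synergy_gene_accounting(set_from("g1", 1), set_from("g2", 1),
                                  set_from(c("g1", "g8"), c(1.3, 1)))
  expect_true(is.na(acc3$slope))
  expect_match(acc3$flag, "overlap")
})

test_that("planted enhancement slope is recovered within the bootstrap CI", {
  truth <- simulate_synergy_de_truth(n_genes = 4000, slope = 1.4,
                                     fpm_meanlog = log(50), fpm_sdlog = 0.3,
                                     seed = 16)
  tabs <- simulate_de_tables(truth, sd_log2fc = c(0.1, 0.1), seed = 17)
  sets <- lapply(c("A", "B", "AB"), function(cc)
    apply_consensus_filter(tabs, contrast = cc))
  acc <- synergy_gene_accounting(sets[[1]], sets[[2]], sets[[3]],
                                 n_boot = 200, seed = 18)
  expect_gt(length(acc$recruited), 0)
  expect_gte(1.4, acc$slope_ci[1])
  expect_lte(1.4, acc$slope_ci[2])
  expect_lt(abs(acc$slope - 1.4), 0.1)
})

test_that("biotype partition sums to one and matches planted fractions", {
  expect_equal(biotype_partition(data.frame(biotype = rep("protein_coding", 5))),
               c(protein_coding = 1, lncRNA = 0, other = 0))
  expect_equal(biotype_partition(
    data.frame(biotype = c(rep("protein_coding", 9), "lncRNA"))),
    c(protein_coding = 0.9, lncRNA = 0.1, other = 0))
  expect_equal(biotype_partition(
    data.frame(biotype = c("protein_coding", NA, "misc_RNA")))[["other"]],
    2 / 3)

  truth <- simulate_de_truth(n_genes = 4000, fpm_meanlog = log(50),
                             fpm_sdlog = 0, seed = 19)
  tabs <- simulate_de_tables(truth, sd_log2fc = c(0, 0))
  s24 <- apply_consensus_filter(tabs, contrast = "24h")
  frac <- biotype_partition(s24)
  expect_equal(sum(frac), 1)
  n <- nrow(s24)
  expect_lt(abs(frac[["protein_coding"]] - 0.92),
            3 * sqrt(0.92 * 0.08 / n))
})
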