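test_that("haplotype pool has blockwise LD and a rare tail", {
  pool <- simulate_haplotypes(n_founder = 50, n_blocks = 1, vars_per_block = 1,
                              seed = 1)
  expect_equal(ncol(pool$haplotypes), 1)
  expect_equal(pool$variants$block, 1L)

  pool <- fx_pool()
  expect_true(all(pool$haplotypes %in% c(0L, 1L)))
  expect_equal(nrow(pool$variants), 300)
  poly <- pool$ref_freq > 0 & pool$ref_freq < 1
  expect_gt(sum(pmin(pool$ref_freq, 1 - pool$ref_freq)[poly] < 0.01), 5)

  # within-block adjacent r2 exceeds cross-block r2, by direct computation
  H <- pool$haplotypes
  keep <- which(poly & pmin(pool$ref_freq, 1 - pool$ref_freq) > 0.05)
  blk <- pool$variants$block[keep]
  Hs <- scale(H[, keep])
  r <- crossprod(Hs) / (nrow(Hs) - 1)
  adj <- which(diff(keep) == 1 & diff(blk) == 0)
  r2_adj <- vapply(adj, function(i) r[i, i + 1]^2, numeric(1))
  cross <- outer(blk, blk, `!=`)
  r2_cross <- mean(r[cross]^2)
  expect_gt(mean(r2_adj), r2_cross)
  expect_lt(r2_cross, 0.05)
})

test_that("identical copying gives r2 = 1; monomorphic pools refuse", {
  # a pool whose variants are duplicated columns (copy without
  # recombination) is perfectly correlated
  H <- cbind(rbinom(200, 1, 0.4))
  H <- cbind(H, H)
  expect_equal(cor(H[, 1], H[, 2])^2, 1)
  expect_error(
    simulate_haplotypes(n_founder = 5, n_blocks = 1, vars_per_block = 2,
                        maf_shape1 = 0.0001, maf_shape2 = 100, seed = 3),
    "monomorphic")
})

test_that("cohort allele frequencies follow the Balding-Nichols drift law", {
  pool <- fx_pool()
  # F = 0: deviation from pool frequency is binomial sampling only
  coh0 <- simulate_cohort(pool, n = 400, drift_F = 0, seed = 11)
  fr0 <- cohort_freq(coh0)
  poly <- pool$ref_freq > 0.05 & pool$ref_freq < 0.95
  z2 <- (fr0$af[poly] - pool$ref_freq[poly])^2 /
    (pool$ref_freq[poly] * (1 - pool$ref_freq[poly]))
  n2 <- 2 * 400
  # E[z2] = 1/(2n); allow 4 MC SEs
  expect_lt(abs(mean(z2) - 1 / n2), 4 * sd(z2) / sqrt(sum(poly)))

  # F = 0.1: variance matches F p (1 - p) + binomial within 3 MC SEs
  F <- 0.1
  pool_big <- simulate_haplotypes(n_founder = 300, n_blocks = 25,
                                  vars_per_block = 40, seed = 12)
  cohF <- simulate_cohort(pool_big, n = 500, drift_F = F, seed = 13)
  frF <- cohort_freq(cohF)
  polyF <- pool_big$ref_freq > 0.05 & pool_big$ref_freq < 0.95
  zF <- (frF$af[polyF] - pool_big$ref_freq[polyF])^2 /
    (pool_big$ref_freq[polyF] * (1 - pool_big$ref_freq[polyF]))
  expected <- F + (1 - F) / (2 * 500)
  expect_lt(abs(mean(zF) - expected), 3 * sd(zF) / sqrt(sum(polyF)))
})

test_that("pedigree structure and error handling in simulate_cohort", {
  coh <- fx_cohort()
  n <- nrow(coh$dosages)
  expect_true(isSymmetric(coh$kinship_truth))
  expect_true(all(diag(coh$kinship_truth) >= 1 - 1e-9))
  # sib pairs occupy the last 50 slots with truth entry 0.5
  sib_entries <- vapply(seq_len(25), function(f) {
    i <- n - 50 + 2 * f - 1
    coh$kinship_truth[i, i + 1]
  }, numeric(1))
  expect_true(all(sib_entries == 0.5))
  # no-family cohort: off-diagonal truth all zero
  coh0 <- simulate_cohort(fx_pool(), n = 50, n_families = 0, seed = 5)
  expect_equal(max(abs(coh0$kinship_truth[upper.tri(coh0$kinship_truth)])), 0)
  expect_error(simulate_cohort(fx_pool(), n = 10, n_families = 6, seed = 1),
               "n_families")
  # positions strictly increasing within chromosome
  expect_true(all(diff(coh$variants$pos) > 0))
  # allele-frequency conservation: af equals mean dosage / 2 exactly
  fr <- cohort_freq(coh)
  d <- coh$dosages
  expect_equal(unname(fr$af),
               unname(colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))))
})

test_that("protein simulation respects its variance budget and truth table", {
  coh <- fx_cohort()
  fr <- cohort_freq(coh)
  # all effects zero: pure noise, no dosage correlation
  sim0 <- simulate_proteins(coh, effect_config(), n_proteins = 2, seed = 21)
  expect_equal(nrow(sim0$truth), 0)
  v <- fr$id[which.max(fr$maf)]
  expect_lt(abs(cor(sim0$panel$npx[, 1], coh$dosages[, v],
                    use = "complete.obs")), 0.15)

  # single cis effect with vanishing noise: r2 -> 1
  cfg1 <- effect_config(
    cis_effects = tibble::tibble(protein = "X", variant_id = v, beta = 0.3),
    noise_sd = 1e-6)
  sim1 <- simulate_proteins(coh, cfg1, n_proteins = 1, seed = 22)
  expect_gt(cor(sim1$panel$npx[, "X"], coh$dosages[, v],
                use = "complete.obs")^2, 0.999)

  # over-budget config refuses
  cfg_bad <- effect_config(
    cis_effects = tibble::tibble(protein = "X", variant_id = v, beta = 3),
    h2_poly = 0.5)
  expect_error(simulate_proteins(coh, cfg_bad, n_proteins = 1, seed = 1),
               "variance budget")
  # absent causal variant refuses
  cfg_abs <- effect_config(
    cis_effects = tibble::tibble(protein = "X", variant_id = "nope", beta = 0.1))
  expect_error(simulate_proteins(coh, cfg_abs, n_proteins = 1, seed = 1),
               "absent")
})

test_that("LOD censoring fraction and plate shifts are realized", {
  coh <- fx_cohort()
  cfg <- effect_config(lod_quantile = 0.1,
                       covariate_effects = list(plate_sd = 0.5))
  sim <- simulate_proteins(coh, cfg, n_proteins = 3, seed = 23)
  below <- colMeans(sweep(sim$panel$npx, 2, sim$panel$lod, `<`))
  expect_true(all(abs(below - 0.1) < 0.01))
})

test_that("outcome GWAS effects are centered on theta * beta_exp", {
  pool <- fx_pool()
  coh2 <- simulate_cohort(pool, n = 1500, seed = 31)
  fr <- cohort_freq(coh2)
  v <- fr$id[fr$maf > 0.2][1]
  eff <- tibble::tibble(variant_id = v, beta = 0.8)
  # theta = 0: no association expected at the causal variant
  og0 <- simulate_outcome_gwas(coh2, eff, theta = 0, seed = 32)
  expect_gt(og0$p_out[og0$id == v], 1e-4)
  # theta = 0.5: beta_out approx theta * beta_exp = 0.4
  og <- simulate_outcome_gwas(coh2, eff, theta = 0.5, seed = 33)
  row <- og[og$id == v, ]
  expect_lt(abs(row$beta_out - 0.4), 3 * row$se_out)
  expect_true(all(og$se_out > 0))
})

test_that("annotations respect windows, severity and reproducible masks", {
  coh <- fx_cohort()
  gw <- tibble::tibble(gene = c("G1", "G2"), chrom = "1",
                       start = c(2030001, 5030001), end = c(2058001, 5058001))
  ann <- simulate_annotations(coh, gw, seed = 41)
  expect_error(simulate_annotations(coh, gw[c(1, 1), ], seed = 1),
               "duplicated")
  # outside all windows and flanks: no link
  far <- ann[ann$pos < 1e6, ]
  expect_true(all(far$gene_links == ""))
  expect_true(all(far$consequence %in% c("intergenic")))
  # severity ordering: splice donor above missense
  sev <- consequence_severity()
  expect_gt(sev[["splice_donor"]], sev[["missense"]])
  expect_true(all(ann$cadd_phred >= 0 & ann$eigen_phred >= 0))
  # coding consequences only inside coding windows
  coding <- ann$consequence %in% c("synonymous", "missense", "splice_donor",
                                   "stop_gained", "frameshift")
  in_window <- purrr::map_lgl(ann$pos, function(p) {
    any(gw$start <= p & p <= gw$end)
  })
  expect_true(all(in_window[coding]))

  # mask membership matches an independent re-filtering of the table
  masks <- build_masks("G1", ann, coh)
  fr <- cohort_freq(coh)
  ann2 <- dplyr::left_join(ann, fr, by = "id")
  is_g1 <- grepl("(^|,)G1(,|$)", ann2$gene_links)
  rare <- is_g1 & ann2$maf < 0.05 & ann2$miss < 0.01 & ann2$mac > 0
  oracle_severe <- ann2$id[rare & ann2$consequence %in%
                             c("splice_donor", "stop_gained", "frameshift")]
  oracle_coding <- ann2$id[rare & ann2$consequence %in%
                             c("synonymous", "missense", "splice_donor",
                               "stop_gained", "frameshift")]
  oracle_reg <- ann2$id[rare & ann2$consequence == "regulatory"]
  expect_setequal(masks$variant_ids[[which(masks$scheme == "severe")]],
                  oracle_severe)
  expect_setequal(masks$variant_ids[[which(masks$scheme == "coding_cadd")]],
                  oracle_coding)
  expect_setequal(masks$variant_ids[[which(masks$scheme == "reg_only_eigen")]],
                  oracle_reg)
  expect_setequal(masks$variant_ids[[which(masks$scheme == "exon_reg_eigen")]],
                  union(oracle_coding, oracle_reg))
})
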