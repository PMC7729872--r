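# discovery scan + validation cohort with one strong cis effect
pgs_setup <- function() {
  fx("pgs", function() {
    pool <- fx_pool()
    coh_d <- simulate_cohort(pool, n = 700, seed = 171)
    coh_v <- simulate_cohort(pool, n = 500, seed = 172)
    fr <- cohort_freq(coh_d)
    v <- fr$id[fr$maf > 0.25 & fr$miss == 0][3]
    # ~40% of variance from one common cis variant
    beta <- sqrt(0.40 / (2 * fr$maf[fr$id == v] * (1 - fr$maf[fr$id == v])))
    cfg <- effect_config(cis_effects = tibble::tibble(
      protein = "PX", variant_id = v, beta = beta))
    sim_d <- simulate_proteins(coh_d, cfg, n_proteins = 3, seed = 173)
    sim_v <- simulate_proteins(coh_v, cfg, n_proteins = 3, seed = 174)
    prep_d <- adjust_and_transform(censor_below_lod(sim_d$panel),
                                   coh_d$samples)
    prep_v <- adjust_and_transform(censor_below_lod(sim_v$panel),
                                   coh_v$samples)
    px <- prep_d[prep_d$protein == "PX", ]
    vc <- reml_fit(px[, c("id", "value")], compute_grm(coh_d))
    assoc <- score_scan(px, coh_d, vc)
    list(coh_d = coh_d, coh_v = coh_v, assoc = assoc,
         ld = ld_from_cohort(coh_d), prep_v = prep_v, causal = v)
  })
}

test_that("score models honor thresholds, MAF rules and linearity", {
  s <- pgs_setup()
  grid <- pgs_threshold_grid(1e-10, length = 5)
  mods <- fit_scores(s$assoc, s$ld, grid, protein = "PX")
  expect_equal(nrow(mods), 15)
  # threshold below the smallest p: empty model scoring zero
  empty <- fit_scores(s$assoc, s$ld, 1e-300, protein = "PX")
  expect_equal(empty$n_variants, rep(0L, 3))
  sc0 <- score_cohort(empty$weights[[1]], s$coh_v)
  expect_true(all(sc0 == 0))
  # every retained variant passes its threshold and rule
  for (i in seq_len(nrow(mods))) {
    w <- mods$weights[[i]]
    if (nrow(w) == 0) next
    a <- s$assoc[match(w$id, s$assoc$id), ]
    expect_true(all(a$p < mods$p_threshold[i]))
    if (mods$maf_rule[i] == "maf05") expect_true(all(a$maf >= 0.05))
    if (mods$maf_rule[i] == "mac10") expect_true(all(a$mac >= 10))
  }
  # single-variant model: score is an affine function of that dosage
  one <- tibble::tibble(id = s$causal, ea = "G", beta = 0.7,
                        freq = unname(s$ld$freq[s$causal]))
  sc1 <- score_cohort(one, s$coh_v)
  d <- pqtlkit:::impute_dosages(s$coh_v$dosages[, s$causal, drop = FALSE])[, 1]
  expect_equal(unname(cor(sc1, d)), 1)
  # 3-variant hand-computed scores
  ids3 <- s$assoc$id[1:3]
  w3 <- tibble::tibble(id = ids3, ea = "G", beta = c(0.5, -0.2, 0.1),
                       freq = unname(s$ld$freq[ids3]))
  sc3 <- score_cohort(w3, s$coh_v)
  G3 <- s$coh_v$dosages[, ids3]
  for (j in 1:3) {
    f <- w3$freq[j]
    G3[is.na(G3[, j]), j] <- 2 * f
  }
  expect_equal(unname(sc3), unname(as.numeric(G3 %*% w3$beta)))
  # linearity: score of summed dosages equals the sum of scores
  cohA <- s$coh_v
  cohB <- s$coh_v
  cohSum <- s$coh_v
  cohSum$dosages <- cohA$dosages + cohB$dosages
  miss <- is.na(cohA$dosages)
  expect_equal(score_cohort(w3, cohSum)[!miss[, 1]],
               (score_cohort(w3, cohA) + score_cohort(w3, cohB))[!miss[, 1]],
               tolerance = 1e-10)
})

test_that("validation r2 recovers the planted architecture", {
  s <- pgs_setup()
  grid <- pgs_threshold_grid(1e-10, length = 5)
  mods <- fit_scores(s$assoc, s$ld, grid, protein = "PX")
  ev <- evaluate_scores(mods, s$coh_v, s$prep_v)
  expect_true(all(ev$r2 >= 0 & ev$r2 <= 1))
  best <- ev[ev$best, ]
  expect_equal(nrow(best), 1)
  # the planted cis variant explains ~40%: recovery band
  expect_gt(best$r2, 0.30)
  expect_lt(best$r2, 0.50)
  # score = phenotype gives r2 = 1; permuted phenotype near 0
  ph <- s$prep_v[s$prep_v$protein == "PX", ]
  fake <- tibble::tibble(protein = "PX", id = ph$id, value = ph$value)
  direct_r2 <- cor(ph$value, ph$value)^2
  expect_equal(direct_r2, 1)
  set.seed(175)
  perm <- dplyr::mutate(ph, value = sample(value))
  ev_perm <- evaluate_scores(mods[which.max(ev$r2), ], s$coh_v, perm)
  expect_lt(ev_perm$r2, 0.03)
})

test_that("cross-validation is deterministic and honest under the null", {
  s <- pgs_setup()
  grid <- pgs_threshold_grid(1e-10, length = 4)
  mods <- fit_scores(s$assoc, s$ld, grid, maf_rules = "mac10",
                     protein = "PX")
  cv1 <- cross_validate(mods, s$coh_v, s$prep_v, seed = 19)
  cv2 <- cross_validate(mods, s$coh_v, s$prep_v, seed = 19)
  expect_identical(cv1, cv2)
  expect_gt(mean(cv1$r2_test), 0.2)  # real signal survives CV
  # null phenotype: mean CV r2 near zero
  set.seed(176)
  null_prep <- dplyr::mutate(s$prep_v, value = rnorm(dplyr::n()))
  cv0 <- cross_validate(mods, s$coh_v, null_prep[null_prep$protein == "PX", ],
                        seed = 20)
  expect_lt(mean(cv0$r2_test), 2 / sqrt(80))
})

test_that("disease screening detects planted score-liability links", {
  set.seed(177)
  n <- 3000
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(NULL, c("PA", "PB", "PC")))
  covs <- data.frame(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  # PB drives disease at OR 1.5 per SD
  lin <- -1 + log(1.5) * scores[, "PB"] + 0.01 * (covs$age - 55)
  y <- rbinom(n, 1, plogis(lin))
  labels <- data.frame(D1 = y)
  res <- disease_screen(scores, labels, covs, n_proteins = 47,
                        n_eff_phenotypes = 64)
  expect_equal(attr(res, "threshold"), 0.05 / (47 * 64))
  expect_true(res$passes_bonferroni[res$protein == "PB"])
  expect_false(any(res$passes_bonferroni[res$protein != "PB"]))
  # null scores give roughly uniform Wald p
  expect_gt(min(res$wald_p[res$protein != "PB"]), 1e-4)
  # degenerate labels refuse
  expect_error(disease_screen(scores, data.frame(D = rep(1, n)), covs),
               "cases")
})

test_that("nested model comparison matches brute-force AUC counting", {
  set.seed(178)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x))
  covs <- data.frame(z = rnorm(n))
  base <- glm(y ~ z, data = cbind(data.frame(y = y), covs),
              family = binomial())
  aug <- glm(y ~ z + x, data = cbind(data.frame(y = y, x = x), covs),
             family = binomial())
  cmp <- compare_models(base, aug)
  expect_lt(cmp$lrt_p, 1e-6)
  expect_gt(cmp$delta_auc, 0)
  expect_lt(cmp$delong_p, 0.05)
  # identical models: delta AUC 0, DeLong p = 1
  cmp0 <- compare_models(base, base)
  expect_equal(cmp0$delta_auc, 0)
  expect_equal(cmp0$delong_p, 1)
  # brute-force AUC via exhaustive pair counting (ties half credit)
  pred <- predict(aug, type = "response")
  cases <- pred[y == 1]; controls <- pred[y == 0]
  auc_brute <- mean(outer(cases, controls, function(a, b)
    (a > b) + 0.5 * (a == b)))
  dl <- delong_test(pred, predict(base, type = "response"), y)
  expect_equal(dl$auc1, auc_brute, tolerance = 1e-12)
  # perfect separation toy: AUC exactly 1
  dl_perf <- delong_test(c(0.9, 0.8, 0.95, 0.1, 0.2, 0.15),
                         rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(dl_perf$auc1, 1)
  # independent implementation agreement (pROC)
  r1 <- pROC::roc(y, pred, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(y, predict(base, type = "response"), quiet = TRUE,
                  direction = "<")
  pr <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(dl$p, pr$p.value, tolerance = 1e-6)
  # augmenting an informative model with pure noise: null LRT, tiny
  # in-sample AUC gain only
  noise_fit <- glm(y ~ z + x + n1, data = data.frame(y = y, z = covs$z,
                                                     x = x, n1 = rnorm(n)),
                   family = binomial())
  cmpn <- compare_models(aug, noise_fit)
  expect_gt(cmpn$lrt_p, 0.01)
  expect_lt(abs(cmpn$delta_auc), 0.05)
  expect_error(compare_models(aug, base), "nested|parameters")
})

test_that("elastic-net selection keeps planted signals and drops noise", {
  set.seed(179)
  n <- 500
  scores <- matrix(rnorm(n * 8), n, 8,
                   dimnames = list(NULL, sprintf("S%d", 1:8)))
  y <- rbinom(n, 1, plogis(-0.3 + 1.5 * scores[, 3]))
  sel <- elastic_net_select(scores, y, alpha_grid = c(0.1, 0.5, 1),
                            folds = 5, seed = 30)
  expect_true("S3" %in% sel$selected)
  # ridge never zeroes coefficients entirely
  sel_ridge <- elastic_net_select(scores, y, alpha_grid = 0, folds = 5,
                                  seed = 31)
  expect_equal(sel_ridge$per_alpha$n_selected, 8)
  # pure-noise scores: empty selection in most seeds at the 1-SE lambda
  empty_ct <- 0
  for (s in 1:5) {
    y0 <- rbinom(n, 1, 0.3)
    sel0 <- elastic_net_select(scores, y0, alpha_grid = 0.5, folds = 5,
                               seed = 40 + s)
    if (sel0$per_alpha$n_selected == 0) empty_ct <- empty_ct + 1
  }
  expect_gte(empty_ct, 4)
})

test_that("discovery r2 exceeds validation r2 in expectation", {
  pool <- fx_pool()
  diffs <- vapply(1:4, function(s) {
    coh_d <- simulate_cohort(pool, n = 350, seed = 700 + s)
    coh_v <- simulate_cohort(pool, n = 350, seed = 750 + s)
    fr <- cohort_freq(coh_d)
    v <- fr$id[fr$maf > 0.25 & fr$miss == 0][s]
    cfg <- effect_config(cis_effects = tibble::tibble(
      protein = "PX", variant_id = v, beta = 0.35))
    sim_d <- simulate_proteins(coh_d, cfg, n_proteins = 2, seed = 800 + s)
    sim_v <- simulate_proteins(coh_v, cfg, n_proteins = 2, seed = 850 + s)
    prep_d <- adjust_and_transform(censor_below_lod(sim_d$panel),
                                   coh_d$samples)
    prep_v <- adjust_and_transform(censor_below_lod(sim_v$panel),
                                   coh_v$samples)
    px <- prep_d[prep_d$protein == "PX", ]
    vc <- reml_fit(px[, c("id", "value")],
                   structure(list(matrix = diag(350),
                                  sample_id = rownames(coh_d$dosages)),
                             class = "pqtl_grm"))
    assoc <- score_scan(px, coh_d, vc)
    ld <- ld_from_cohort(coh_d)
    mods <- fit_scores(assoc, ld, pgs_threshold_grid(1e-6, length = 4),
                       maf_rules = "mac10", protein = "PX")
    ev_d <- evaluate_scores(mods, coh_d, px)
    ev_v <- evaluate_scores(mods, coh_v, prep_v[prep_v$protein == "PX", ])
    max(ev_d$r2) - max(ev_v$r2)
  }, numeric(1))
  # overfitting direction: in-sample performance wins on average
  expect_gt(mean(diffs), 0)
})

test_that("disease screening ranks the planted protein first across seeds", {
  top_hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 1500
    scores <- matrix(rnorm(n * 3), n, 3,
                     dimnames = list(NULL, c("PA", "PB", "PC")))
    y <- rbinom(n, 1, plogis(-1 + log(1.6) * scores[, "PB"]))
    res <- disease_screen(scores, data.frame(D = y),
                          data.frame(age = rnorm(n)), 47, 64)
    res$protein[which.min(res$wald_p)]
  }, character(1))
  expect_gte(mean(top_hits == "PB"), 0.9)
})
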