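# designed-LD toy: v1~v2 strongly linked, v4~v5 moderately, rest unlinked
toy_ld_cohort <- function() {
  set.seed(31)
  n <- 400
  g1 <- rbinom(n, 2, 0.4)
  g2 <- g1; flip <- sample(n, 12); g2[flip] <- rbinom(12, 2, 0.4)
  g3 <- rbinom(n, 2, 0.35)
  g4 <- rbinom(n, 2, 0.45)
  g5 <- g4; flip <- sample(n, 150); g5[flip] <- rbinom(150, 2, 0.45)
  g6 <- rbinom(n, 2, 0.25)
  make_toy_cohort(cbind(v1 = g1, v2 = g2, v3 = g3, v4 = g4, v5 = g5, v6 = g6),
                  pos = c(1e6, 1.2e6, 1.5e6, 5e6, 5.3e6, 5.5e6))
}

toy_assoc <- function() {
  make_assoc(id = sprintf("v%d", 1:6),
             p = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 0.5),
             pos = c(1e6, 1.2e6, 1.5e6, 5e6, 5.3e6, 5.5e6))
}

test_that("signal extraction follows the sort-prune-group algorithm", {
  coh <- toy_ld_cohort()
  ld <- ld_from_cohort(coh)
  # confirm the designed r2 regimes before tracing
  r2 <- ld$r2(sprintf("v%d", 1:6))
  expect_gt(r2["v1", "v2"], 0.2)
  expect_gt(r2["v4", "v5"], 0.2)
  expect_lt(max(r2["v3", c("v1", "v2", "v4", "v5", "v6")]), 0.2)

  asc <- toy_assoc()
  sig <- extract_signals(asc, threshold = 1e-5, ld)
  # hand trace: v1 retained (prunes v2), v3 retained, v4 retained
  # (prunes v5); v6 not significant; v1+v3 within 2 Mb group, v4 alone
  expect_equal(nrow(sig), 2)
  expect_equal(sig$index_id, c("v1", "v4"))
  expect_equal(sig$index_p, c(1e-10, 1e-7))
  expect_setequal(sig$members[[1]], c("v1", "v2", "v3"))
  expect_setequal(sig$members[[2]], c("v4", "v5"))

  # single significant variant: one signal, itself index
  sig1 <- extract_signals(asc, threshold = 5e-10, ld)
  expect_equal(nrow(sig1), 1)
  expect_equal(sig1$index_id, "v1")
  # nothing significant: empty
  expect_equal(nrow(extract_signals(asc, threshold = 1e-20, ld)), 0)

  # row-order invariance
  sig_shuf <- extract_signals(asc[sample(6), ], threshold = 1e-5, ld)
  expect_equal(sig_shuf$index_id, sig$index_id)
  expect_equal(sig_shuf$members, sig$members)

  # signal count is monotone in threshold stringency
  n_loose <- nrow(extract_signals(asc, threshold = 1e-5, ld))
  n_strict <- nrow(extract_signals(asc, threshold = 1e-9, ld))
  expect_gte(n_loose, n_strict)
  # and non-increasing as r2_prune tightens to 0 (more pruning)
  n_r2_tight <- nrow(extract_signals(asc, threshold = 1e-5, ld,
                                     r2_prune = 0.01))
  expect_lte(n_r2_tight, n_loose)
})

test_that("clumping matches an exhaustive greedy oracle", {
  coh <- toy_ld_cohort()
  ld <- ld_from_cohort(coh)
  asc <- toy_assoc()
  kept <- clump(asc, ld, r2 = 0.1, window_bp = 1e6, p_max = 1)
  # independent oracle: greedy by ascending p
  r2 <- ld$r2(asc$id)
  ord <- order(asc$p)
  active <- rep(TRUE, 6)
  oracle <- character(0)
  for (i in ord) {
    if (!active[i]) next
    oracle <- c(oracle, asc$id[i])
    near <- abs(asc$pos - asc$pos[i]) <= 1e6
    active[active & near & r2[i, ] > 0.1] <- FALSE
  }
  expect_identical(kept, oracle)
  # unlinked variants all retained
  set.seed(33)
  G <- sapply(1:5, function(i) rbinom(300, 2, 0.4))
  colnames(G) <- sprintf("u%d", 1:5)
  coh2 <- make_toy_cohort(G, pos = (1:5) * 1e5)
  ld2 <- ld_from_cohort(coh2)
  r2u <- ld2$r2(colnames(G)); diag(r2u) <- 0
  asc2 <- make_assoc(colnames(G), p = c(0.01, 0.2, 0.03, 0.4, 0.05),
                     pos = (1:5) * 1e5)
  if (max(r2u) <= 0.1) {
    expect_setequal(clump(asc2, ld2, r2 = 0.1), colnames(G))
  }
  # a linked pair within the window keeps only the better p
  g <- rbinom(300, 2, 0.4)
  g2 <- g; g2[1:80] <- rbinom(80, 2, 0.4)   # r2 around 0.15-0.6
  coh3 <- make_toy_cohort(cbind(a = g, b = g2), pos = c(1e5, 6e5))
  ld3 <- ld_from_cohort(coh3)
  if (ld3$r2(c("a", "b"))["a", "b"] > 0.1) {
    asc3 <- make_assoc(c("a", "b"), p = c(1e-4, 1e-3), pos = c(1e5, 6e5))
    expect_identical(clump(asc3, ld3, r2 = 0.1), "a")
  }
})

test_that("joint selection approximates exact multiple regression", {
  coh <- fx_cohort()
  fr <- cohort_freq(coh)
  common <- fr$id[fr$maf > 0.15 & fr$miss == 0]
  # two causal variants in different blocks plus bystanders
  v_causal <- common[c(2, length(common) - 2)]
  set.seed(34)
  n <- nrow(coh$dosages)
  G <- impute_dosages(coh$dosages)
  y <- 0.6 * G[, v_causal[1]] - 0.55 * G[, v_causal[2]] + rnorm(n)
  vcI <- reml_fit(y, fx_grm_identity())
  sc <- score_scan(y, coh, vcI)
  ld <- fx_ld()
  jm <- cojo_select(sc, ld, p_threshold = 1e-4)
  sel <- tidy(jm)
  expect_true(all(v_causal %in% sel$id))
  # exact multiple-regression oracle on raw dosages
  fit <- lm(y ~ G[, sel$id])
  b_exact <- coef(fit)[-1]
  for (k in seq_along(sel$id)) {
    expect_lt(abs(sel$beta_joint[k] - b_exact[k]) / abs(b_exact[k]), 0.10)
  }
  # linkage-equilibrium limit: joint betas equal marginal betas
  sel_le <- sel[sel$id %in% v_causal, ]
  r2sel <- ld$r2(v_causal)
  if (r2sel[1, 2] < 0.02) {
    expect_equal(sel_le$beta_joint, sel_le$beta_marginal, tolerance = 0.05)
  }
})

test_that("collinear duplicates are never co-selected", {
  set.seed(35)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  gdup <- g
  gother <- rbinom(n, 2, 0.3)
  coh <- make_toy_cohort(cbind(top = g, dup = gdup, oth = gother),
                         pos = c(1e5, 2e5, 8e5))
  y <- 0.5 * g + rnorm(n)
  vcI <- reml_fit(y, structure(list(matrix = diag(n),
                                    sample_id = rownames(coh$dosages)),
                               class = "pqtl_grm"))
  sc <- score_scan(y, coh, vcI)
  ld <- ld_from_cohort(coh)
  jm <- cojo_select(sc, ld, p_threshold = 1e-4)
  sel <- tidy(jm)
  expect_false(all(c("top", "dup") %in% sel$id))
  expect_true(any(grepl("collinear", jm$log)))
})

test_that("conditional scans absorb linked signals and spare unlinked ones", {
  coh <- toy_ld_cohort()
  ld <- ld_from_cohort(coh)
  asc <- toy_assoc()
  # conditioning on an unlinked variant leaves effects near-marginal
  cs <- conditional_scan(asc, "v6", ld)
  row3 <- cs[cs$id == "v3", ]
  expect_lt(abs(row3$beta_cond - asc$beta[asc$id == "v3"]) /
              abs(asc$beta[asc$id == "v3"]), 0.1)
  # conditioning a variant on a near-perfect proxy: conditional p -> 1
  set.seed(36)
  g <- rbinom(400, 2, 0.4)
  coh2 <- make_toy_cohort(cbind(a = g, b = g), pos = c(1e5, 2e5))
  ld2 <- ld_from_cohort(coh2)
  asc2 <- make_assoc(c("a", "b"), p = c(1e-8, 1e-8), pos = c(1e5, 2e5))
  cs2 <- conditional_scan(asc2, "a", ld2)
  expect_equal(cs2$p_cond[cs2$id == "b"], 1)
  expect_true(cs2$collinear[cs2$id == "b"])
  # conditioning variant must exist
  expect_error(conditional_scan(asc2, "zzz", ld2), "absent")
})

test_that("a shadow signal vanishes under conditioning while truth persists", {
  # designed pair: shadow shares ~70% of entries with truth (r2 ~ 0.5)
  set.seed(37)
  n <- 500
  g_true <- rbinom(n, 2, 0.35)
  g_shadow <- g_true
  flip <- sample(n, 150)
  g_shadow[flip] <- rbinom(150, 2, 0.35)
  g_null <- rbinom(n, 2, 0.3)
  coh <- make_toy_cohort(cbind(truth = g_true, shadow = g_shadow,
                               nullv = g_null),
                         pos = c(1e5, 2e5, 9e5))
  ld <- ld_from_cohort(coh)
  r2p <- ld$r2(c("truth", "shadow"))["truth", "shadow"]
  expect_true(r2p > 0.3 && r2p < 0.9)
  v_true <- "truth"; v_shadow <- "shadow"
  G <- coh$dosages
  y <- 0.6 * G[, v_true] + rnorm(n)
  vcI <- reml_fit(y, structure(list(matrix = diag(n),
                                    sample_id = rownames(coh$dosages)),
                               class = "pqtl_grm"))
  sc <- score_scan(y, coh, vcI)
  expect_lt(sc$p[sc$id == v_shadow], 1e-3)  # shadow is marginally assoc
  cs <- conditional_scan(sc, v_true, ld)
  expect_gt(cs$p_cond[cs$id == v_shadow], 0.05)
})

test_that("joint model on orthonormal-like genotypes reduces to thresholding", {
  # unlinked variants: selection keeps exactly those passing the
  # threshold marginally
  set.seed(38)
  n <- 600
  G <- sapply(1:6, function(i) rbinom(n, 2, 0.5))
  colnames(G) <- sprintf("o%d", 1:6)
  coh <- make_toy_cohort(G, pos = (1:6) * 1e6)
  y <- 0.3 * G[, 1] + 0.25 * G[, 4] + rnorm(n)
  vcI <- reml_fit(y, structure(list(matrix = diag(n),
                                    sample_id = rownames(coh$dosages)),
                               class = "pqtl_grm"))
  sc <- score_scan(y, coh, vcI)
  ld <- ld_from_cohort(coh)
  r2m <- ld$r2(colnames(G)); diag(r2m) <- 0
  if (max(r2m) < 0.02) {
    jm <- cojo_select(sc, ld, p_threshold = 1e-5)
    expect_setequal(tidy(jm)$id, sc$id[sc$p <= 1e-5])
  }
})
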