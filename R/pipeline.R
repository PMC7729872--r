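#' Seeded end-to-end pQTL pipeline demonstration
#'
#' Generates a complete synthetic study -- a discovery cohort with
#' cryptic relatedness, an independent replication cohort, and an
#' independent outcome cohort -- with three planted signal classes
#' (a common cis variant, a common trans variant, and a rare-variant
#' burden in one gene), then runs the full analysis: phenotype
#' preparation, GRM + REML + score scans with genomic-control gating,
#' effective-trait multiple-testing calibration, signal extraction and
#' conditional/joint selection, functionally weighted SKAT-O burden
#' testing with conditional re-testing, replication assessment,
#' two-sample Mendelian randomization, and polygenic score validation.
#'
#' @param seed Integer seed driving every random component.
#' @param n_discovery,n_replication,n_outcome Cohort sizes.
#' @param theta Causal effect of the cis protein on the outcome.
#' @return A list of summary quantities (see the acceptance checks and
#'   README) plus the per-stage result tables under `$tables`.
#' @export
pipeline_demo_run <- function(seed = 2024, n_discovery = 800,
                              n_replication = 900, n_outcome = 1500,
                              theta = 0.4) {
  pool <- simulate_haplotypes(n_founder = 500, n_blocks = 20,
                              vars_per_block = 60, seed = seed)
  coh_d <- simulate_cohort(pool, n = n_discovery, n_families = 60,
                           drift_F = 0.02, miss_rate = 0.001,
                           seed = seed + 1)
  coh_r <- simulate_cohort(pool, n = n_replication, seed = seed + 2)
  coh_o <- simulate_cohort(pool, n = n_outcome, seed = seed + 3)
  fr <- cohort_freq(coh_d)

  # one gene with coding window in the tail of block 3 and a
  # regulatory flank over the preceding variants
  gw <- tibble::tibble(gene = "G1", chrom = "1",
                       start = 2e6 + 60001L, end = 2e6 + 118001L)
  ann <- simulate_annotations(coh_d, gw, seed = seed + 4)

  # planted architecture -------------------------------------------------
  in_window <- fr$pos >= gw$start & fr$pos <= gw$end
  cis_v <- fr$id[in_window & fr$maf > 0.2 & fr$miss == 0][1]
  trans_v <- fr$id[fr$pos > 15e6 & fr$maf > 0.2 & fr$miss == 0][1]
  masks0 <- build_masks("G1", ann, coh_d)
  cc0 <- masks0[masks0$scheme == "coding_cadd", ]
  bids <- cc0$variant_ids[[1]]
  bf <- fr$maf[match(bids, fr$id)]
  eff_w <- cc0$weights[[1]]^2 * 2 * bf * (1 - bf)
  drivers <- bids[order(-eff_w)][1:2]
  fdrv <- fr$maf[match(drivers, fr$id)]
  beta_drv <- 0.25 / sqrt(2 * fdrv * (1 - fdrv))  # ~6% variance each

  cfg <- effect_config(
    cis_effects = tibble::tibble(protein = "PCIS", variant_id = cis_v,
                                 beta = 0.5),
    trans_effects = tibble::tibble(protein = "PTRANS", variant_id = trans_v,
                                   beta = 0.45),
    burden_effects = tibble::tibble(protein = "PBURD", gene = "G1",
                                    variant_id = drivers, beta = beta_drv),
    h2_poly = 0.15,
    covariate_effects = list(age = 0.2, sex = 0.15, season = 0.1,
                             plate_sd = 0.1),
    lod_quantile = 0.02)

  sim_d <- simulate_proteins(coh_d, cfg, n_proteins = 6, seed = seed + 5)
  sim_r <- simulate_proteins(coh_r, cfg, n_proteins = 6, seed = seed + 6)

  # phenotype preparation -------------------------------------------------
  pan_d <- censor_below_lod(sim_d$panel)
  pan_r <- censor_below_lod(sim_r$panel)
  prep_d <- adjust_and_transform(pan_d, coh_d$samples)
  prep_r <- adjust_and_transform(pan_r, coh_r$samples)

  # mixed-model scans -----------------------------------------------------
  grm_d <- compute_grm(coh_d)
  grm_r <- compute_grm(coh_r)
  ld_d <- ld_from_cohort(coh_d)
  scan_of <- function(prep, coh, grm, protein) {
    ph <- prep[prep$protein == protein, ]
    vc <- reml_fit(ph[, c("id", "value")], grm)
    list(vc = vc, assoc = score_scan(ph, coh, vc))
  }
  d_cis <- scan_of(prep_d, coh_d, grm_d, "PCIS")
  d_trans <- scan_of(prep_d, coh_d, grm_d, "PTRANS")
  d_burd <- scan_of(prep_d, coh_d, grm_d, "PBURD")

  # study-wide threshold from the effective trait count
  pm <- prepared_matrix(prep_d)
  m_eff <- effective_traits(stats::cor(pm, use = "pairwise.complete.obs"))
  n_tested <- nrow(d_cis$assoc)
  threshold <- study_threshold(0.05, m_eff$m_eff, n_tested)

  lambda_cis <- genomic_control(d_cis$assoc)$lambda_gc

  # signals + joint model -------------------------------------------------
  sig_cis <- extract_signals(d_cis$assoc, threshold, ld_d)
  sig_trans <- extract_signals(d_trans$assoc, threshold, ld_d)
  proxy_of <- function(signals, v) {
    if (nrow(signals) == 0) return(FALSE)
    members <- unique(unlist(signals$members))
    if (v %in% members) return(TRUE)
    r2 <- ld_d$r2(c(v, members))[v, members]
    any(r2 > 0.8)
  }
  cis_found <- proxy_of(sig_cis, cis_v)
  trans_found <- proxy_of(sig_trans, trans_v)

  jm_cis <- cojo_select(d_cis$assoc, ld_d, p_threshold = threshold)
  jm_trans <- cojo_select(d_trans$assoc, ld_d, p_threshold = threshold)
  sel_cis <- tidy(jm_cis)
  sel_trans <- tidy(jm_trans)
  selected_proxy <- function(sel, v) {
    if (nrow(sel) == 0) return(FALSE)
    if (v %in% sel$id) return(TRUE)
    r2 <- ld_d$r2(c(v, sel$id))[v, sel$id]
    any(r2 > 0.5)
  }

  # burden + conditional --------------------------------------------------
  br <- burden_scan("G1", ann, coh_d, d_burd$vc)
  best_mask <- br[which.min(br$p), ]
  mask_row <- masks0[masks0$scheme == best_mask$scheme, ]
  in_mask <- d_burd$assoc[d_burd$assoc$id %in% mask_row$variant_ids[[1]], ]
  top_sp <- in_mask$id[which.min(in_mask$p)]
  cond <- conditional_burden(mask_row, top_sp, coh_d, d_burd$vc)

  # replication -----------------------------------------------------------
  r_cis <- scan_of(prep_r, coh_r, grm_r, "PCIS")
  disc_tab <- dplyr::bind_rows(
    dplyr::transmute(sel_cis, id, beta = beta_joint),
    dplyr::transmute(sel_trans, id, beta = beta_joint))
  rep_report <- replication_assess(
    dplyr::transmute(sel_cis, id, beta = beta_joint),
    r_cis$assoc, ld_d, n_for_threshold = max(nrow(disc_tab), 1))
  cis_rep <- rep_report$status[rep_report$id == cis_v]
  if (length(cis_rep) == 0) {
    # index may be a proxy of the causal variant
    cis_rep <- rep_report$status[1]
  }

  # Mendelian randomization ----------------------------------------------
  og <- simulate_outcome_gwas(
    coh_o, tibble::tibble(variant_id = cis_v, beta = 0.5), theta = theta,
    seed = seed + 7)
  expo <- dplyr::transmute(
    sel_cis, protein = "PCIS", outcome = "disease", id,
    beta_exp = beta_joint, se_exp = se_joint,
    ea = coh_d$variants$alt[match(id, coh_d$variants$id)],
    oa = coh_d$variants$ref[match(id, coh_d$variants$id)])
  ins <- assemble_instruments(expo, og, ld_d)
  ins$protein <- "PCIS"; ins$outcome <- "disease"
  mr <- mr_screen(ins)

  # polygenic scores ------------------------------------------------------
  grid <- pgs_threshold_grid(threshold)
  mods <- fit_scores(d_cis$assoc, ld_d, grid, protein = "PCIS")
  ev <- evaluate_scores(mods, coh_r, prep_r[prep_r$protein == "PCIS", ])

  list(
    seed = seed, theta = theta, threshold = threshold, m_eff = m_eff$m_eff,
    lambda_gc_cis = lambda_cis,
    cis_variant = cis_v, trans_variant = trans_v, burden_drivers = drivers,
    cis_found = cis_found, trans_found = trans_found,
    cis_selected = selected_proxy(sel_cis, cis_v),
    trans_selected = selected_proxy(sel_trans, trans_v),
    burden_scheme = best_mask$scheme, burden_p = best_mask$p,
    burden_p_conditional = cond$p_conditional,
    cis_replication_status = cis_rep,
    mr_estimate = mr$estimate[1], mr_se = mr$se[1], mr_q = mr$q[1],
    pgs_best_r2 = max(ev$r2),
    tables = list(signals_cis = sig_cis, joint_cis = sel_cis,
                  joint_trans = sel_trans, burden = br,
                  replication = rep_report, mr = mr, pgs = ev,
                  truth = sim_d$truth)
  )
}
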