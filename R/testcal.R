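#' Effective number of independent traits
#'
#' Computes the effective number of independent phenotypes from the
#' eigenvalue variance of their correlation matrix:
#' `M_eff = M * (1 - (M - 1) * V_lambda / M^2)`, where `V_lambda` is the
#' population variance (divisor `M`) of the eigenvalues. Identity
#' correlation gives `M_eff = M`; perfect correlation of two traits
#' gives 1.5.
#'
#' @param trait_corr Trait correlation matrix (symmetric, unit
#'   diagonal).
#' @param alpha Family-wise alpha used for the derived threshold.
#' @param n_eff_variants Effective number of variant-side tests entering
#'   the derived threshold.
#' @return A `meff_report` list: `M`, `eigenvalues`, `v_lambda_obs`,
#'   `m_eff`, `m_eff_rounded`, `threshold`.
#' @export
effective_traits <- function(trait_corr, alpha = 0.05, n_eff_variants = 1) {
  M <- nrow(trait_corr)
  assert_that(isTRUE(all.equal(trait_corr, t(trait_corr), tolerance = 1e-8)),
              "correlation matrix must be symmetric")
  assert_that(max(abs(diag(trait_corr) - 1)) < 1e-8,
              "correlation matrix must have unit diagonal")
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * M) abort("correlation matrix is not positive semi-definite")
  v_lambda <- mean((ev - mean(ev))^2)
  m_eff <- M * (1 - (M - 1) * v_lambda / M^2)
  structure(list(
    M = M, eigenvalues = ev, v_lambda_obs = v_lambda, m_eff = m_eff,
    m_eff_rounded = round(m_eff),
    threshold = study_threshold(alpha, m_eff, n_eff_variants)
  ), class = "meff_report")
}

#' @export
print.meff_report <- function(x, ...) {
  cat(sprintf("<meff_report> M = %d, V_lambda = %.4f, M_eff = %.2f (rounded %d), threshold = %.3g\n",
              x$M, x$v_lambda_obs, x$m_eff, x$m_eff_rounded, x$threshold))
  invisible(x)
}

#' Study-wide significance threshold
#'
#' `alpha / (m_eff_traits * n_eff_variants)`.
#'
#' @param alpha Family-wise alpha.
#' @param m_eff_traits Effective number of traits.
#' @param n_eff_variants Effective number of variant-side tests.
#' @return The p-value threshold.
#' @export
study_threshold <- function(alpha, m_eff_traits, n_eff_variants = 1) {
  assert_that(alpha > 0 && m_eff_traits > 0 && n_eff_variants > 0,
              "all inputs must be positive")
  alpha / (m_eff_traits * n_eff_variants)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values (wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' One-sided one-sample proportion test
#'
#' Normal-approximation z-test without continuity correction for
#' `H1: p > p0`:
#' `p = Phi_upper((k/n - p0) / sqrt(p0 (1 - p0) / n))`.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null proportion.
#' @return One-sided p-value.
#' @export
proportion_test_one_sided <- function(k, n, p0 = 0.5) {
  assert_that(n > 0, "n must be positive")
  assert_that(k >= 0 && k <= n, "k must lie in [0, n]")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  pnorm(z, lower.tail = FALSE)
}

#' Effective test counts for combined single-point and burden reporting
#'
#' Simulation estimate of the multiple-testing burden when single-point
#' results, rare-variant burden results, or both are reported. For each
#' null phenotype replicate the minimum p is taken across (a) the
#' single-point scan, (b) the gene-based burden scan, and (c) their
#' union; the effective number of tests for each reporting scheme is
#' `alpha / q_alpha(min p)` with `q_alpha` the empirical alpha-quantile
#' over replicates, and the inflation ratio is combined / single-point.
#'
#' Null phenotypes are independent standard normal draws (no
#' relatedness), so the scan reduces to ordinary least squares, and the
#' burden scan uses SKAT-O with precomputed per-mask structure and the
#' fast moment-matching quadratic-form method.
#'
#' @param cohort A `pqtl_cohort`.
#' @param annotation Annotation table covering the cohort variants.
#' @param genes Gene ids to include in the burden side.
#' @param n_replicates Number of null replicates (>= 100).
#' @param alpha Quantile level used for effective-test estimation.
#' @param mac_min,miss_max Single-point filters.
#' @param maf_max Burden rare-variant MAF cutoff.
#' @param seed Integer seed.
#' @return List with `eff_single`, `eff_burden`, `eff_combined`,
#'   `ratio`, `n_replicates`, and the per-replicate minima.
#' @export
combined_test_inflation <- function(cohort, annotation, genes,
                                    n_replicates = 200, alpha = 0.05,
                                    mac_min = 10, miss_max = 0.01,
                                    maf_max = 0.05, seed = 1) {
  assert_that(n_replicates >= 100, "need >= 100 replicates for the quantile")
  with_seed(seed, {
    n <- nrow(cohort$dosages)
    fr <- cohort_freq(cohort)
    keep <- fr$mac >= mac_min & fr$miss <= miss_max
    G <- impute_dosages(cohort$dosages[, fr$id[keep], drop = FALSE])
    Gc <- sweep(G, 2, colMeans(G))
    gtg <- colSums(Gc^2)
    ok <- gtg > 0
    Gc <- Gc[, ok, drop = FALSE]; gtg <- gtg[ok]
    Y <- matrix(rnorm(n * n_replicates), n, n_replicates)
    Y <- sweep(Y, 2, colMeans(Y))
    yty <- colSums(Y^2)
    num <- crossprod(Gc, Y)                       # m x R
    # per-variant OLS z^2 for every replicate
    beta2 <- sweep(num^2, 1, gtg^2, `/`)
    sse <- -sweep(sweep(num^2, 1, gtg, `/`), 2, yty)  # yty - num^2/gtg
    z2 <- beta2 * gtg * (n - 2) / sse
    p_single <- matrix(pchisq(z2, 1, lower.tail = FALSE), nrow = nrow(num))
    min_single <- apply(p_single, 2, min)
    # burden side: per-mask SKAT-O structure precomputed once, reused
    # across replicates (masks do not depend on the phenotype)
    masks_pre <- list()
    for (g in genes) {
      masks <- build_masks(g, annotation, cohort, maf_max = maf_max,
                           miss_max = miss_max)
      masks <- masks[masks$n_variants > 0, ]
      for (i in seq_len(nrow(masks))) {
        ids <- masks$variant_ids[[i]]
        Gm <- impute_dosages(cohort$dosages[, ids, drop = FALSE])
        Gm <- sweep(Gm, 2, colMeans(Gm))
        Z <- sweep(Gm, 2, masks$weights[[i]], `*`)
        masks_pre[[length(masks_pre) + 1]] <-
          list(Z = Z, pre = skato_precompute(Z))
      }
    }
    min_burden <- rep(NA_real_, n_replicates)
    if (length(masks_pre) > 0) {
      for (r in seq_len(n_replicates)) {
        u <- Y[, r] / sqrt(yty[r] / (n - 1))
        pb <- vapply(masks_pre, function(mp) {
          skato_pvalue(mp$pre, as.numeric(crossprod(mp$Z, u)),
                       method = "liu")$p
        }, numeric(1))
        min_burden[r] <- min(pb)
      }
    }
    min_combined <- if (length(masks_pre) > 0) {
      pmin(min_single, min_burden)
    } else min_single
    eff_of <- function(minp) alpha / as.numeric(quantile(minp, alpha, type = 1))
    eff_single <- eff_of(min_single)
    eff_burden <- if (length(masks_pre) > 0) eff_of(min_burden) else NA_real_
    eff_combined <- eff_of(min_combined)
    list(eff_single = eff_single, eff_burden = eff_burden,
         eff_combined = eff_combined, ratio = eff_combined / eff_single,
         n_replicates = n_replicates, n_burden_masks = length(masks_pre),
         min_single = min_single, min_burden = min_burden,
         min_combined = min_combined)
  })
}

#' Replication assessment of discovery variants
#'
#' Maps each discovery variant to itself or to its best tagging proxy
#' (r-squared above `tag_r2`) present in the replication association
#' table, and calls replication when the replication p-value is strictly
#' below `0.05 / n_for_threshold` and (optionally) the effect direction
#' agrees. Variants absent from replication with no adequate proxy, or
#' monomorphic in replication, are reported unassessable.
#'
#' @param discovery Tibble of discovery variants with `id` and `beta`
#'   (e.g. the `selected` table of a `pqtl_joint_model` with
#'   `beta_joint` renamed, or a marginal assoc subset).
#' @param replication A `pqtl_assoc` from the replication cohort.
#' @param ld A `pqtl_ld` spanning both cohorts' variants (discovery
#'   in-sample LD is used for proxy search).
#' @param n_for_threshold Denominator of the replication threshold
#'   `0.05 / N`.
#' @param tag_r2 Minimum proxy r-squared.
#' @param require_direction Require consistent effect direction
#'   (default TRUE).
#' @return A `replication_report`: tibble with per-variant proxy, p and
#'   status, plus attributes `n_replicated`, `n_assessable`,
#'   `threshold`.
#' @export
replication_assess <- function(discovery, replication, ld,
                               n_for_threshold, tag_r2 = 0.8,
                               require_direction = TRUE) {
  threshold <- 0.05 / n_for_threshold
  rows <- purrr::map(seq_len(nrow(discovery)), function(i) {
    id <- discovery$id[i]
    proxy <- NA_character_
    sign_flip <- 1
    if (id %in% replication$id) {
      proxy <- id
    } else if (id %in% ld$ids) {
      cands <- intersect(ld$ids, replication$id)
      if (length(cands) > 0) {
        r <- ld$cor(c(id, cands))[id, cands]
        best <- which.max(r^2)
        if (r[best]^2 > tag_r2) {
          proxy <- cands[best]
          sign_flip <- sign(r[best])
        }
      }
    }
    if (is.na(proxy)) {
      return(tibble::tibble(id = id, proxy = NA_character_,
                            p_replication = NA_real_,
                            status = "unassessable"))
    }
    rrow <- replication[replication$id == proxy, ]
    if (rrow$mac[1] == 0 || is.na(rrow$p[1])) {
      return(tibble::tibble(id = id, proxy = proxy, p_replication = NA_real_,
                            status = "unassessable"))
    }
    dir_ok <- !require_direction ||
      sign(discovery$beta[i]) == sign(rrow$beta[1] * sign_flip)
    rep_ok <- rrow$p[1] < threshold && dir_ok
    tibble::tibble(id = id, proxy = proxy, p_replication = rrow$p[1],
                   status = if (rep_ok) "replicated" else "not_replicated")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "n_replicated") <- sum(out$status == "replicated")
  attr(out, "n_assessable") <- sum(out$status != "unassessable")
  class(out) <- c("replication_report", class(out))
  out
}

#' Allele-frequency divergence between a cohort and a reference panel
#'
#' Per-variant fold change of the cohort minor allele frequency relative
#' to a reference population, with a two-proportion z-test (no
#' continuity correction) of the frequency difference, and a flag for
#' greater-than-5-fold increases.
#'
#' @param cohort_maf,ref_maf Frequencies in (0, 1) (reference MAF of 0
#'   yields an undefined fold change, flagged).
#' @param n_cohort,n_ref Diploid sample sizes (allele counts are
#'   `2 * n`).
#' @param variant_ids Optional ids.
#' @return Tibble: id, cohort_maf, ref_maf, fold, p_diff, increased,
#'   fold_gt5.
#' @export
af_divergence <- function(cohort_maf, ref_maf, n_cohort, n_ref,
                          variant_ids = NULL) {
  assert_that(all(cohort_maf >= 0 & cohort_maf < 1) && all(ref_maf >= 0 & ref_maf < 1),
              "frequencies must lie in [0, 1)")
  k1 <- round(2 * n_cohort * cohort_maf)
  k2 <- round(2 * n_ref * ref_maf)
  p_diff <- purrr::map2_dbl(k1, k2, function(a, b) {
    if (a + b == 0) return(1)
    suppressWarnings(
      prop.test(c(a, b), c(2 * n_cohort, 2 * n_ref), correct = FALSE)$p.value
    )
  })
  tibble::tibble(
    id = variant_ids %||% sprintf("v%d", seq_along(cohort_maf)),
    cohort_maf = cohort_maf, ref_maf = ref_maf,
    fold = ifelse(ref_maf > 0, cohort_maf / ref_maf, NA_real_),
    p_diff = p_diff,
    increased = cohort_maf > ref_maf,
    fold_gt5 = !is.na(ifelse(ref_maf > 0, cohort_maf / ref_maf, NA_real_)) &
      cohort_maf / ref_maf > 5
  )
}
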