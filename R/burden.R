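#' Build functionally weighted rare-variant burden masks for a gene
#'
#' Applies the rare-variant filters (MAF strictly below `maf_max`,
#' missingness strictly below `miss_max`) to the variants linked to a
#' gene and assembles four weighting schemes:
#' \describe{
#'   \item{severe}{coding variants with most severe consequence strictly
#'     more severe than missense; all weights 1 (set
#'     `include_missense = TRUE` to relax to "at least missense").}
#'   \item{coding_cadd}{all coding variants, weighted by the CADD-like
#'     phred score.}
#'   \item{exon_reg_eigen}{coding and gene-linked regulatory variants,
#'     weighted by the Eigen-like phred score.}
#'   \item{reg_only_eigen}{gene-linked regulatory variants only,
#'     weighted by the Eigen-like phred score.}
#' }
#'
#' @param gene Gene id (must appear in the annotation's `gene_links`).
#' @param annotation Annotation tibble from [simulate_annotations()] (or
#'   same columns).
#' @param cohort A `pqtl_cohort` (for MAF / missingness).
#' @param maf_max,miss_max Rare-variant filters.
#' @param include_missense Include missense variants in the `severe`
#'   mask.
#' @return Tibble with one row per scheme: gene, scheme, variant_ids
#'   (list), weights (list), n_variants. Schemes can be empty.
#' @export
build_masks <- function(gene, annotation, cohort, maf_max = 0.05,
                        miss_max = 0.01, include_missense = FALSE) {
  sev <- consequence_severity()
  linked <- purrr::map_lgl(strsplit(annotation$gene_links, ",", fixed = TRUE),
                           function(g) gene %in% g)
  if (!any(linked)) abort(sprintf("gene '%s' absent from annotation links", gene))
  ann <- annotation[linked, ]
  fr <- cohort_freq(cohort)
  fr <- fr[match(ann$id, fr$id), ]
  rare <- fr$maf < maf_max & fr$miss < miss_max & fr$mac > 0
  ann <- ann[rare, ]
  rank_of <- sev[ann$consequence]
  coding <- rank_of >= sev[["synonymous"]]
  severe_cut <- if (include_missense) sev[["missense"]] else sev[["missense"]] + 1L
  severe <- rank_of >= severe_cut & coding
  regulatory <- ann$consequence == "regulatory"
  mk <- function(scheme, sel, w) {
    tibble::tibble(gene = gene, scheme = scheme,
                   variant_ids = list(ann$id[sel]),
                   weights = list(unname(w[sel])),
                   n_variants = sum(sel))
  }
  dplyr::bind_rows(
    mk("severe", severe, rep(1, nrow(ann))),
    mk("coding_cadd", coding, ann$cadd_phred),
    mk("exon_reg_eigen", coding | regulatory, ann$eigen_phred),
    mk("reg_only_eigen", regulatory, ann$eigen_phred)
  )
}

# default rho grid of the optimal unified test
.skato_rho_grid <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)

# decorrelating null model: V^-1/2 rotation from the fitted variance
# components plus OLS projection on the rotated covariates
skato_null_model <- function(vc, extra_covariates = NULL) {
  s <- 1 / sqrt(vc$sigma_g2 * vc$eigen_d + vc$sigma_e2)
  W <- vc$W
  if (!is.null(extra_covariates)) W <- cbind(W, extra_covariates)
  Ut <- t(vc$eigen_U)
  Xt <- s * (Ut %*% W)
  qrX <- qr(Xt)
  yt <- s * as.numeric(Ut %*% vc$y)
  res <- qr.resid(qrX, yt)
  list(s = s, Ut = Ut, qrX = qrX, res = res, n = vc$n)
}

# transform, project and weight genotypes -> Z (n x m)
skato_Z <- function(null, G, weights) {
  Gt <- null$s * (null$Ut %*% G)
  Z <- qr.resid(null$qrX, Gt)
  sweep(Z, 2, weights, `*`)
}

# SKAT-O structural quantities that do not depend on the phenotype;
# per-rho eigenvalues and Liu parameters are cached so repeated calls
# (null simulations, effective-test estimation) stay cheap
skato_precompute <- function(Z, rho_grid = .skato_rho_grid) {
  m <- ncol(Z)
  ZtZ <- crossprod(Z)
  lambdas <- lapply(rho_grid, function(rho) {
    if (m == 1) return(as.numeric(ZtZ))
    Rh <- matrix(-(sqrt(1 - rho)) / m + sqrt(1 - rho + m * rho) / m, m, m)
    diag(Rh) <- diag(Rh) + sqrt(1 - rho)
    ev <- eigen(Rh %*% ZtZ %*% Rh, symmetric = TRUE, only.values = TRUE)$values
    ev[ev > max(ev) * 1e-10]
  })
  liu_rho <- lapply(lambdas, liu_params)
  zbar <- rowMeans(Z)
  sig_a2 <- sum(zbar^2)
  lee <- NULL
  if (m > 1 && sig_a2 > 1e-12) {
    gam <- as.numeric(crossprod(zbar, Z)) / sig_a2
    Z2 <- Z - tcrossprod(zbar, gam)
    lam_k <- eigen(crossprod(Z2), symmetric = TRUE, only.values = TRUE)$values
    lam_k <- lam_k[lam_k > max(lam_k, 1e-12) * 1e-10]
    varzeta <- 4 * sig_a2 * sum((Z2 %*% gam)^2)
    tau <- ((1 - rho_grid) * sum(gam^2) + rho_grid * m^2) * sig_a2
    lee <- list(lam_k = lam_k, liu_k = liu_params(lam_k),
                mu_k = sum(lam_k), var_k = 2 * sum(lam_k^2),
                varzeta = varzeta, tau = tau)
  }
  list(m = m, rho_grid = rho_grid, lambdas = lambdas, liu_rho = liu_rho,
       lee = lee)
}

# p-value from precomputed structure and score vector S = Z'res
skato_pvalue <- function(pre, S, method = "imhof") {
  rho <- pre$rho_grid
  Q <- (1 - rho) * sum(S^2) + rho * sum(S)^2
  p_rho <- if (method == "liu") {
    vapply(seq_along(rho), function(i) {
      min(max(liu_pval_params(Q[i], pre$liu_rho[[i]]), 1e-14), 1)
    }, numeric(1))
  } else {
    vapply(seq_along(rho), function(i) {
      pchisqsum(Q[i], pre$lambdas[[i]], method = method)$p
    }, numeric(1))
  }
  T_min <- min(p_rho)
  i_opt <- which.min(p_rho)
  fallback <- FALSE
  if (pre$m == 1 || length(rho) == 1) {
    p_overall <- p_rho[i_opt]
  } else if (is.null(pre$lee)) {
    p_overall <- min(1, T_min * length(rho))
    fallback <- TRUE
  } else {
    lee <- pre$lee
    q_rho <- vapply(seq_along(rho), function(i) {
      liu_qval_params(T_min, pre$liu_rho[[i]])
    }, numeric(1))
    shrink <- sqrt(lee$var_k / (lee$var_k + lee$varzeta))
    is1 <- rho >= 1 - 1e-12
    xmax <- if (any(is1)) min(q_rho[is1] / lee$tau[is1]) else 200
    q_ni <- q_rho[!is1]; tau_ni <- lee$tau[!is1]; om_ni <- 1 - rho[!is1]
    Fkappa <- function(x) {
      # min over non-unity rho of the kappa bound, variance-adjusted
      t0 <- do.call(pmin, lapply(seq_along(q_ni), function(i) {
        (q_ni[i] - tau_ni[i] * x) / om_ni[i]
      }))
      t_adj <- (t0 - lee$mu_k) * shrink + lee$mu_k
      out <- numeric(length(x))
      ok <- t0 > 0 & t_adj > 0
      if (any(ok)) {
        out[ok] <- 1 - liu_pval_params(t_adj[ok], lee$liu_k)
      }
      out
    }
    val <- tryCatch(
      integrate(function(x) stats::dchisq(x, 1) * Fkappa(x), 0, xmax,
                rel.tol = 1e-5, subdivisions = 200L)$value,
      error = function(e) NA_real_)
    if (is.finite(val)) {
      p_overall <- min(max(1 - val, T_min), 1)
    } else {
      p_overall <- min(1, T_min * length(rho))
      fallback <- TRUE
    }
  }
  list(p = p_overall, p_rho = p_rho, rho_opt = rho[i_opt], Q = Q[i_opt],
       min_p = T_min, fallback = fallback)
}

#' SKAT-O rare-variant burden test under the linear mixed model
#'
#' Optimal unified variance-component/burden test on a weighted mask of
#' rare variants, computed on mixed-model-decorrelated residuals: with
#' `V = sigma_g^2 K + sigma_e^2 I` estimated by REML, genotypes and
#' phenotype are rotated by `V^-1/2`, projected orthogonally to the
#' covariates, and the scores `S_j` enter
#' `Q_rho = (1 - rho) * sum_j w_j^2 S_j^2 + rho * (sum_j w_j S_j)^2`.
#' Per-rho p-values come from the exact distribution of a quadratic form
#' in normals (Imhof inversion, Liu moment-matching fallback); the
#' overall p combines the grid minimum through the one-dimensional
#' integration of the optimal-test construction.
#'
#' @param y Prepared phenotype (vector in fit order, or tibble with
#'   `id`, `value`); may be omitted (`NULL`) to reuse the phenotype
#'   stored in `vc`.
#' @param mask One-row mask tibble from [build_masks()] (or a list with
#'   `gene`, `scheme`, `variant_ids`, `weights`).
#' @param cohort A `pqtl_cohort`.
#' @param vc A `pqtl_vc` from [reml_fit()].
#' @param rho_grid Grid of the burden/variance-component mixing
#'   parameter.
#' @param method Quadratic-form method, "imhof" or "liu".
#' @return One-row `BurdenResult` tibble: gene, scheme, n_variants,
#'   cum_mac, Q, rho_opt, p, min_p, fallback.
#' @export
skato_lmm <- function(mask, cohort, vc, y = NULL,
                      rho_grid = .skato_rho_grid, method = "imhof") {
  ids <- mask$variant_ids[[1]]
  w <- mask$weights[[1]]
  assert_that(length(ids) > 0, "mask is empty")
  vc <- vc_with_phenotype(vc, y)
  null <- skato_null_model(vc)
  row_idx <- match(vc$sample_id, rownames(cohort$dosages))
  G <- impute_dosages(cohort$dosages[row_idx, ids, drop = FALSE])
  Z <- skato_Z(null, G, w)
  pre <- skato_precompute(Z, rho_grid)
  S <- as.numeric(crossprod(Z, null$res))
  ans <- skato_pvalue(pre, S, method = method)
  cum_mac <- sum(vapply(ids, function(v) mac_of(cohort$dosages[row_idx, v]),
                        numeric(1)))
  tibble::tibble(gene = mask$gene[[1]], scheme = mask$scheme[[1]],
                 n_variants = length(ids), cum_mac = cum_mac,
                 Q = ans$Q, rho_opt = ans$rho_opt, p = ans$p,
                 min_p = ans$min_p, fallback = ans$fallback)
}

# substitute a phenotype into a fitted vc (variance components kept)
vc_with_phenotype <- function(vc, y) {
  if (is.null(y)) return(vc)
  if (is.data.frame(y)) {
    idx <- match(vc$sample_id, y$id)
    assert_that(!anyNA(idx), "phenotype must cover all fitted samples")
    y <- y$value[idx]
  }
  assert_that(length(y) == vc$n, "phenotype length mismatch")
  vc$y <- y
  vc
}

#' Burden test conditional on the top single-point variant
#'
#' Re-runs the SKAT-O burden with the dosage of the most significant
#' single-point variant in the mask added to the fixed covariates and
#' that variant removed from the mask, so that only signals supported by
#' at least two distinct variants remain significant.
#'
#' @param mask One-row mask tibble containing `top_variant_id`.
#' @param top_variant_id Id of the conditioning variant (must be a mask
#'   member).
#' @inheritParams skato_lmm
#' @return One-row tibble as [skato_lmm()] plus `p_conditional` and
#'   `conditioned_on`; for masks of size 1 the conditional p is `NA`
#'   (undefined) with a note.
#' @export
conditional_burden <- function(mask, top_variant_id, cohort, vc, y = NULL,
                               rho_grid = .skato_rho_grid, method = "imhof") {
  ids <- mask$variant_ids[[1]]
  assert_that(top_variant_id %in% ids, "conditioning variant must be a mask member")
  base <- skato_lmm(mask, cohort, vc, y = y, rho_grid = rho_grid,
                    method = method)
  if (length(ids) == 1) {
    return(dplyr::mutate(base, p_conditional = NA_real_,
                         conditioned_on = top_variant_id,
                         note = "single-variant mask: conditional p undefined"))
  }
  keep <- ids != top_variant_id
  vc <- vc_with_phenotype(vc, y)
  row_idx <- match(vc$sample_id, rownames(cohort$dosages))
  g_top <- impute_dosages(cohort$dosages[row_idx, top_variant_id, drop = FALSE])
  null <- skato_null_model(vc, extra_covariates = g_top)
  G <- impute_dosages(cohort$dosages[row_idx, ids[keep], drop = FALSE])
  Z <- skato_Z(null, G, mask$weights[[1]][keep])
  pre <- skato_precompute(Z, rho_grid)
  S <- as.numeric(crossprod(Z, null$res))
  ans <- skato_pvalue(pre, S, method = method)
  dplyr::mutate(base, p_conditional = ans$p, conditioned_on = top_variant_id,
                note = NA_character_)
}

#' Gene-by-gene burden scan over all masks
#'
#' Convenience wrapper: builds the four masks per gene and tests each
#' non-empty one.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Annotation table.
#' @inheritParams skato_lmm
#' @inheritParams build_masks
#' @return `BurdenResult` tibble, one row per non-empty gene x scheme.
#' @export
burden_scan <- function(genes, annotation, cohort, vc, y = NULL,
                        maf_max = 0.05, miss_max = 0.01,
                        rho_grid = .skato_rho_grid, method = "imhof",
                        include_missense = FALSE) {
  purrr::map(genes, function(g) {
    masks <- build_masks(g, annotation, cohort, maf_max = maf_max,
                         miss_max = miss_max,
                         include_missense = include_missense)
    masks <- masks[masks$n_variants > 0, ]
    purrr::map(seq_len(nrow(masks)), function(i) {
      skato_lmm(masks[i, ], cohort, vc, y = y, rho_grid = rho_grid,
                method = method)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Meta-analysis of burden results across two cohorts
#'
#' Stouffer combination of one-sided Z-equivalents of the per-cohort
#' burden p-values, weighted by the square root of the sample sizes.
#' Gene/scheme pairs present in only one cohort are carried through with
#' their single-cohort p and flagged.
#'
#' @param res1,res2 `BurdenResult` tibbles (columns gene, scheme, p).
#' @param n1,n2 Cohort sample sizes.
#' @return Tibble: gene, scheme, p1, p2, p_meta, meta_method.
#' @export
burden_meta <- function(res1, res2, n1, n2) {
  j <- dplyr::full_join(
    dplyr::select(res1, gene, scheme, p1 = p),
    dplyr::select(res2, gene, scheme, p2 = p),
    by = c("gene", "scheme")
  )
  stouffer <- function(p1, p2) {
    z <- sqrt(n1) * qnorm(p1, lower.tail = FALSE) +
      sqrt(n2) * qnorm(p2, lower.tail = FALSE)
    pnorm(z / sqrt(n1 + n2), lower.tail = FALSE)
  }
  j |>
    dplyr::mutate(
      p_meta = dplyr::case_when(
        is.na(p1) ~ p2,
        is.na(p2) ~ p1,
        TRUE ~ stouffer(p1, p2)
      ),
      meta_method = dplyr::case_when(
        is.na(p1) | is.na(p2) ~ "single-cohort",
        TRUE ~ "stouffer"
      )
    )
}
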