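#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on genotype counts: the p-value is
#' the total probability, under the hypergeometric-type conditional
#' distribution of the heterozygote count given allele counts, of all
#' heterozygote counts at most as probable as the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, positive sum).
#' @return p-value in (0, 1]; monomorphic input returns 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  assert_that(n_AA >= 0 && n_Aa >= 0 && n_aa >= 0 && n_AA + n_Aa + n_aa > 0,
              "counts must be non-negative with positive sum")
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  het_obs <- n_Aa
  # conditional probabilities over all het counts with the parity of `rare`
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-12)]))
}

#' Greedy positional LD pruning
#'
#' Walks variants in position order and retains a variant only if its
#' squared dosage correlation with every already-retained variant within
#' `window_bp` is at most `r2_max`.
#'
#' @param cohort A `pqtl_cohort`.
#' @param r2_max Maximum allowed pairwise r-squared among retained
#'   variants.
#' @param window_bp Window within which pairs are checked.
#' @param variant_ids Optional subset to prune (default all).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(cohort, r2_max = 0.2, window_bp = 1e6,
                     variant_ids = NULL) {
  assert_that(r2_max > 0 && r2_max < 1, "r2_max must be in (0, 1)")
  v <- cohort$variants
  ids <- variant_ids %||% v$id
  v <- v[match(ids, v$id), ]
  ord <- order(v$chrom, v$pos)
  v <- v[ord, ]
  G <- impute_dosages(cohort$dosages[, v$id, drop = FALSE])
  G <- scale(G)
  G[is.na(G)] <- 0  # zero-variance columns
  n <- nrow(G)
  kept <- integer(0)
  kept_chrom <- character(0)
  kept_pos <- integer(0)
  for (i in seq_len(nrow(v))) {
    near <- kept[kept_chrom == v$chrom[i] & kept_pos >= v$pos[i] - window_bp]
    if (length(near) > 0) {
      r <- crossprod(G[, near, drop = FALSE], G[, i]) / (n - 1)
      if (any(r^2 > r2_max, na.rm = TRUE)) next
    }
    kept <- c(kept, i)
    kept_chrom <- c(kept_chrom, v$chrom[i])
    kept_pos <- c(kept_pos, v$pos[i])
  }
  v$id[kept]
}

#' Empirical genetic relationship matrix
#'
#' GRM on variants passing MAF, Hardy-Weinberg and LD-pruning filters:
#' `K = (1/m) * sum_j (d_j - 2 f_j)(d_j - 2 f_j)' / (2 f_j (1 - f_j))`
#' over passing variants, with per-variant mean imputation of missing
#' dosages.
#'
#' @param cohort A `pqtl_cohort`.
#' @param maf_min Minimum MAF (strict) for inclusion.
#' @param hwe_p_min Variants with HWE exact p below this are excluded.
#' @param prune Logical: apply LD pruning.
#' @param r2_max,window_bp Pruning parameters.
#' @return A `pqtl_grm`: list with `matrix`, `n_variants_used`,
#'   `sample_id`.
#' @export
compute_grm <- function(cohort, maf_min = 0.01, hwe_p_min = 1e-5,
                        prune = TRUE, r2_max = 0.2, window_bp = 1e6) {
  fr <- cohort_freq(cohort)
  ids <- fr$id[fr$maf > maf_min]
  if (length(ids) > 0 && hwe_p_min > 0) {
    keep_hwe <- vapply(ids, function(id) {
      d <- round(cohort$dosages[, id])
      hwe_exact_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                     sum(d == 2, na.rm = TRUE)) >= hwe_p_min
    }, logical(1))
    ids <- ids[keep_hwe]
  }
  if (length(ids) == 0) abort("no variants pass the GRM filters")
  if (prune && length(ids) > 1) {
    ids <- ld_prune(cohort, r2_max = r2_max, window_bp = window_bp,
                    variant_ids = ids)
  }
  G <- impute_dosages(cohort$dosages[, ids, drop = FALSE])
  f <- colMeans(G) / 2
  X <- sweep(G, 2, 2 * f)
  X <- sweep(X, 2, sqrt(2 * f * (1 - f)), `/`)
  K <- tcrossprod(X) / length(ids)
  dimnames(K) <- list(rownames(cohort$dosages), rownames(cohort$dosages))
  structure(list(matrix = K, n_variants_used = length(ids),
                 sample_id = rownames(cohort$dosages), variant_ids = ids),
            class = "pqtl_grm")
}

#' @export
print.pqtl_grm <- function(x, ...) {
  cat(sprintf("<pqtl_grm> %d samples, %d variants used\n",
              nrow(x$matrix), x$n_variants_used))
  invisible(x)
}

# REML log-likelihood at log-lambda, given eigen-rotated data
reml_loglik <- function(loglambda, d, ystar, Wstar, WtW_logdet) {
  lambda <- exp(loglambda)
  delta <- lambda * d + 1
  w <- 1 / delta
  A <- crossprod(Wstar, Wstar * w)
  alpha <- solve(A, crossprod(Wstar, ystar * w))
  r <- ystar - Wstar %*% alpha
  rss <- sum(w * r^2)
  n <- length(ystar); c <- ncol(Wstar)
  sigma_e2 <- rss / (n - c)
  -0.5 * ((n - c) * (log(2 * pi * sigma_e2) + 1) + sum(log(delta)) +
            determinant(A, logarithm = TRUE)$modulus - WtW_logdet)
}

#' REML variance components under the kinship model
#'
#' Fits `y = W a + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, profiling
#' everything but `lambda = sigma_g^2 / sigma_e^2` via the
#' eigendecomposition of the GRM, then maximizing over `log(lambda)` on
#' `[-5, 5]` (base 10) with a decade-grid bracket followed by Brent
#' search.
#'
#' @param y Numeric phenotype (complete; order matching the GRM), or a
#'   prepared-phenotype tibble with `id` and `value`.
#' @param W Fixed-effect design matrix (default intercept only).
#' @param grm A `pqtl_grm` (or bare matrix).
#' @return A `pqtl_vc`: variance components, `lambda_ratio`,
#'   `loglik_reml`, heritability estimate `h2`, plus cached
#'   eigendecomposition for downstream scans.
#' @export
reml_fit <- function(y, grm, W = NULL) {
  K <- if (inherits(grm, "pqtl_grm")) grm$matrix else grm
  sample_id <- if (inherits(grm, "pqtl_grm")) grm$sample_id else rownames(K)
  if (is.data.frame(y)) {
    assert_that(all(c("id", "value") %in% names(y)),
                "data-frame y needs columns id and value")
    idx <- match(y$id, sample_id)
    assert_that(!anyNA(idx), "phenotype ids must all be in the GRM")
    if (!identical(idx, seq_along(sample_id))) {
      K <- K[idx, idx]
      if (inherits(grm, "pqtl_grm")) grm$eigen_cache <- NULL
    }
    sample_id <- y$id
    y <- y$value
  }
  assert_that(!anyNA(y), "y must be complete")
  n <- length(y)
  assert_that(nrow(K) == n, "GRM dimension must match y")
  W <- W %||% matrix(1, n, 1)
  # repeated fits against the same kinship (null simulations, per-trait
  # scans) can reuse a cached eigendecomposition on the grm object
  eg <- if (inherits(grm, "pqtl_grm") && !is.null(grm$eigen_cache) &&
              length(grm$eigen_cache$values) == n) {
    grm$eigen_cache
  } else {
    eigen(K, symmetric = TRUE)
  }
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    abort("GRM is not positive semi-definite beyond tolerance")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ystar <- as.numeric(crossprod(U, y))
  Wstar <- crossprod(U, W)
  WtW_logdet <- determinant(crossprod(W), logarithm = TRUE)$modulus
  identifiable <- sd(d) > 1e-8
  if (!identifiable) {
    # K proportional to I: only the total variance is identifiable
    A <- crossprod(W)
    r <- y - W %*% solve(A, crossprod(W, y))
    sigma_e2 <- sum(r^2) / (n - ncol(W))
    ll <- reml_loglik(log(1e-12), d, ystar, Wstar, WtW_logdet)
    fit <- list(lambda = 0, loglik = ll, sigma_e2 = sigma_e2)
  } else {
    grid <- log(10^seq(-5, 5, by = 1))
    ll_grid <- vapply(grid, reml_loglik, numeric(1), d = d, ystar = ystar,
                      Wstar = Wstar, WtW_logdet = WtW_logdet)
    i <- which.max(ll_grid)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(reml_loglik, c(lo, hi), d = d, ystar = ystar,
                    Wstar = Wstar, WtW_logdet = WtW_logdet, maximum = TRUE,
                    tol = 1e-8)
    # boundary: allow lambda -> 0 if the grid maximum is at the low end
    if (i == 1 && ll_grid[1] >= opt$objective) {
      opt <- list(maximum = grid[1], objective = ll_grid[1])
    }
    lambda <- exp(opt$maximum)
    delta <- lambda * d + 1
    w <- 1 / delta
    A <- crossprod(Wstar, Wstar * w)
    alpha <- solve(A, crossprod(Wstar, ystar * w))
    rss <- sum(w * (ystar - Wstar %*% alpha)^2)
    sigma_e2 <- rss / (n - ncol(W))
    fit <- list(lambda = lambda, loglik = opt$objective, sigma_e2 = sigma_e2)
  }
  sigma_g2 <- fit$lambda * fit$sigma_e2
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = fit$sigma_e2,
    lambda_ratio = fit$lambda, loglik_reml = as.numeric(fit$loglik),
    h2 = sigma_g2 / (sigma_g2 + fit$sigma_e2),
    identifiable = identifiable,
    n = n, eigen_U = U, eigen_d = d, W = W, y = y, sample_id = sample_id
  ), class = "pqtl_vc")
}

#' @export
print.pqtl_vc <- function(x, ...) {
  cat(sprintf("<pqtl_vc> sigma_g2 = %.4f, sigma_e2 = %.4f (h2 = %.3f), REML loglik = %.2f\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik_reml))
  if (!x$identifiable) cat("  note: GRM ~ identity; components unidentifiable, total variance only\n")
  invisible(x)
}

# covariance-projection helper: returns function applying
# P = V^-1 - V^-1 W (W' V^-1 W)^-1 W' V^-1 in the eigenbasis
vc_projector <- function(vc) {
  w <- 1 / (vc$sigma_g2 * vc$eigen_d + vc$sigma_e2)
  Wstar <- crossprod(vc$eigen_U, vc$W)
  A <- crossprod(Wstar, Wstar * w)
  function(Mstar) {
    wM <- Mstar * w
    wM - (Wstar * w) %*% solve(A, crossprod(Wstar, wM))
  }
}

#' Mixed-model single-variant score scan
#'
#' Per-variant score test under the fitted variance components:
#' with `V = sigma_g^2 K + sigma_e^2 I` and projection
#' `P = V^-1 - V^-1 W (W'V^-1W)^-1 W'V^-1`, the statistic is
#' `(g'Py)^2 / (g'Pg)`, referred to the upper tail of chi-squared with
#' one degree of freedom; the reported effect and standard error are the
#' equivalent generalized-least-squares quantities `g'Py / g'Pg` and
#' `(g'Pg)^-1/2`. Missing dosages are mean-imputed per variant. Variants
#' failing the MAC or missingness filter are omitted; zero-variance
#' dosages are skipped.
#'
#' @param y Prepared phenotype: numeric vector (GRM order) or tibble with
#'   `id`, `value` matching the fit.
#' @param cohort A `pqtl_cohort`.
#' @param vc A `pqtl_vc` fitted on the same samples.
#' @param mac_min Minimum minor allele count (variants with MAC below
#'   this are excluded).
#' @param miss_max Maximum per-variant missingness.
#' @param variant_ids Optional subset of variants.
#' @return A `pqtl_assoc` tibble: chrom, pos, id, ea, oa, maf, mac, miss,
#'   beta, se, p.
#' @export
score_scan <- function(y, cohort, vc, mac_min = 10, miss_max = 0.01,
                       variant_ids = NULL) {
  if (is.data.frame(y)) {
    idx <- match(vc$sample_id, y$id)
    assert_that(!anyNA(idx), "prepared phenotype must cover all fitted samples")
    y <- y$value[idx]
  }
  assert_that(length(y) == vc$n, "phenotype length must match the fit")
  ids <- variant_ids %||% cohort$variants$id
  row_idx <- match(vc$sample_id, rownames(cohort$dosages))
  assert_that(!anyNA(row_idx), "fit samples missing from cohort")
  D <- cohort$dosages[row_idx, ids, drop = FALSE]
  n_ok <- colSums(!is.na(D))
  s <- colSums(D, na.rm = TRUE)
  mac <- pmin(s, 2 * n_ok - s)
  miss <- 1 - n_ok / nrow(D)
  keep <- mac >= mac_min & miss <= miss_max & n_ok > 0
  varpos <- apply(D[, keep, drop = FALSE], 2, function(x) var(x, na.rm = TRUE) > 0)
  skipped <- names(which(!varpos))
  keep[names(varpos)[!varpos]] <- FALSE
  ids <- ids[keep]
  if (length(ids) == 0) {
    return(empty_assoc())
  }
  G <- impute_dosages(D[, ids, drop = FALSE])
  U <- vc$eigen_U
  Gstar <- crossprod(U, G)
  ystar <- as.numeric(crossprod(U, y))
  P <- vc_projector(vc)
  Py <- P(matrix(ystar, ncol = 1))
  PG <- P(Gstar)
  num <- as.numeric(crossprod(Gstar, Py))
  den <- colSums(Gstar * PG)
  beta <- num / den
  se <- 1 / sqrt(den)
  chi2 <- num^2 / den
  vmeta <- cohort$variants[match(ids, cohort$variants$id), ]
  out <- tibble::tibble(
    chrom = vmeta$chrom, pos = vmeta$pos, id = ids,
    ea = vmeta$alt, oa = vmeta$ref,
    maf = unname(pmin(s[keep] / (2 * n_ok[keep]),
                      1 - s[keep] / (2 * n_ok[keep]))),
    mac = unname(mac[keep]), miss = unname(miss[keep]),
    beta = unname(beta), se = unname(se),
    p = unname(pchisq(chi2, 1, lower.tail = FALSE))
  )
  class(out) <- c("pqtl_assoc", class(out))
  attr(out, "n") <- vc$n
  attr(out, "skipped") <- skipped
  out
}

empty_assoc <- function() {
  out <- tibble::tibble(chrom = character(), pos = integer(), id = character(),
                        ea = character(), oa = character(), maf = numeric(),
                        mac = numeric(), miss = numeric(), beta = numeric(),
                        se = numeric(), p = numeric())
  class(out) <- c("pqtl_assoc", class(out))
  out
}

#' Genomic-control inflation factor
#'
#' `lambda_GC` is the median association chi-squared divided by the null
#' chi-squared(1) median 0.4549; traits pass when
#' `0.97 <= lambda_GC <= 1.05`.
#'
#' @param assoc A `pqtl_assoc` (needs >= 100 variants).
#' @param lower,upper Acceptance band.
#' @return List with `lambda_gc` and `pass`.
#' @export
genomic_control <- function(assoc, lower = 0.97, upper = 1.05) {
  assert_that(nrow(assoc) >= 100, "genomic control needs >= 100 variants")
  chi2 <- qchisq(assoc$p, 1, lower.tail = FALSE)
  lambda <- median(chi2) / 0.4549
  list(lambda_gc = lambda, pass = lambda >= lower && lambda <= upper)
}
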