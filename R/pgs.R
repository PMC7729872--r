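#' Log-spaced p-value threshold grid for score fitting
#'
#' Thresholds between a loose bound (default 1e-4) and the study-wide
#' significance threshold, log10-spaced.
#'
#' @param p_strict Strict end (study-wide threshold).
#' @param p_loose Loose end.
#' @param length Number of thresholds.
#' @return Decreasing numeric vector.
#' @export
pgs_threshold_grid <- function(p_strict, p_loose = 1e-4, length = 8) {
  10^seq(log10(p_loose), log10(p_strict), length.out = length)
}

# MAF rule predicates on an assoc table
pgs_maf_rule <- function(rule) {
  switch(rule,
         maf05 = function(a) a$maf >= 0.05,
         maf01 = function(a) a$maf >= 0.01,
         mac10 = function(a) a$mac >= 10,
         abort(sprintf("unknown MAF rule '%s'", rule)))
}

#' Fit clumping + p-value-thresholding polygenic score models
#'
#' For every combination of p-value threshold and MAF rule: LD-clump the
#' discovery summary statistics (greedy by p), keep clumped variants
#' passing the threshold and the rule, and store their discovery effect
#' sizes as score weights. Empty models (no passing variant) are
#' recorded as empty rather than erroring.
#'
#' @param assoc Discovery `pqtl_assoc` for one protein.
#' @param ld A `pqtl_ld` on the discovery cohort.
#' @param threshold_grid P-value thresholds (see
#'   [pgs_threshold_grid()]).
#' @param maf_rules Subset of `c("maf05", "maf01", "mac10")`.
#' @param clump_r2,clump_bp Clumping parameters.
#' @param protein Optional protein label carried through.
#' @return Tibble of `pgs_model`s: protein, p_threshold, maf_rule,
#'   n_variants, weights (list of tibbles id, ea, beta, freq).
#' @export
fit_scores <- function(assoc, ld, threshold_grid,
                       maf_rules = c("maf05", "maf01", "mac10"),
                       clump_r2 = 0.1, clump_bp = 1e6, protein = NA_character_) {
  p_loose <- max(threshold_grid)
  kept <- clump(assoc, ld, r2 = clump_r2, window_bp = clump_bp,
                p_max = p_loose)
  base <- assoc[assoc$id %in% kept, ]
  grid <- tidyr::expand_grid(p_threshold = threshold_grid,
                             maf_rule = maf_rules)
  grid$weights <- purrr::map2(grid$p_threshold, grid$maf_rule, function(th, rule) {
    sel <- base[base$p < th & pgs_maf_rule(rule)(base), ]
    tibble::tibble(id = sel$id, ea = sel$ea, beta = sel$beta,
                   freq = unname(ld$freq[sel$id]))
  })
  grid$n_variants <- purrr::map_int(grid$weights, nrow)
  dplyr::mutate(grid, protein = protein, .before = 1)
}

#' Compute polygenic scores in a cohort
#'
#' `score_i = sum_j beta_j * dosage_ij`; missing dosages are imputed
#' from the stored discovery allele frequencies (`2 * freq`). Variants
#' absent from the cohort are skipped.
#'
#' @param weights A weights tibble (id, ea, beta, freq) from a
#'   [fit_scores()] model row.
#' @param cohort Target `pqtl_cohort`.
#' @return Named numeric vector of per-sample scores (all zero for an
#'   empty model).
#' @export
score_cohort <- function(weights, cohort) {
  n <- nrow(cohort$dosages)
  s <- setNames(rep(0, n), rownames(cohort$dosages))
  use <- weights$id %in% colnames(cohort$dosages)
  if (!any(use)) return(s)
  w <- weights[use, ]
  D <- cohort$dosages[, w$id, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    d[is.na(d)] <- 2 * w$freq[j]
    s <- s + w$beta[j] * d
  }
  s
}

#' Evaluate polygenic score models in a validation cohort
#'
#' Validation r-squared is the squared Pearson correlation between the
#' score and the prepared phenotype; the best model per protein is the
#' grid argmax. Constant (e.g. empty) scores get r-squared 0 with a
#' flag.
#'
#' @param models [fit_scores()] tibble (possibly several proteins).
#' @param cohort Validation `pqtl_cohort` (disjoint from discovery).
#' @param prepared Prepared phenotypes (long tibble protein/id/value)
#'   for the validation cohort.
#' @return Tibble: model columns + r2, constant_score, best (per
#'   protein).
#' @export
evaluate_scores <- function(models, cohort, prepared) {
  out <- models
  out$r2 <- NA_real_
  out$constant_score <- FALSE
  for (i in seq_len(nrow(models))) {
    ph <- prepared[prepared$protein == models$protein[i], ]
    s <- score_cohort(models$weights[[i]], cohort)
    s <- s[ph$id]
    if (sd(s) == 0 || sd(ph$value) == 0) {
      out$r2[i] <- 0
      out$constant_score[i] <- TRUE
    } else {
      out$r2[i] <- cor(s, ph$value)^2
    }
  }
  out |>
    dplyr::group_by(protein) |>
    dplyr::mutate(best = dplyr::row_number() == which.max(r2) & max(r2) > 0) |>
    dplyr::ungroup()
}

#' Repeated k-fold cross-validation of score threshold selection
#'
#' Guards the threshold/rule optimization against overfitting: per
#' repeat, a hold-out fraction is set aside, the remaining samples are
#' split into `folds`; for each fold, the best model is selected on the
#' training folds and its r-squared recorded on the held fold and the
#' hold-out set. Byte-identical across reruns at a fixed seed.
#'
#' @param models [fit_scores()] tibble.
#' @param cohort Validation cohort.
#' @param prepared Prepared phenotypes for `cohort`.
#' @param folds,repeats,holdout CV layout.
#' @param seed Integer seed.
#' @return Tibble: protein, repeat, fold, selected model id, r2_train,
#'   r2_test, r2_holdout.
#' @export
cross_validate <- function(models, cohort, prepared, folds = 5, repeats = 3,
                           holdout = 0.2, seed = 1) {
  with_seed(seed, {
    proteins <- unique(models$protein)
    # precompute all scores once
    score_tab <- purrr::map(seq_len(nrow(models)),
                            function(i) score_cohort(models$weights[[i]], cohort))
    r2_of <- function(s, ph) {
      s <- s[ph$id]
      if (length(ph$id) < 3 || sd(s) == 0 || sd(ph$value) == 0) return(0)
      cor(s, ph$value)^2
    }
    out <- list()
    for (pr in proteins) {
      ph_all <- prepared[prepared$protein == pr, ]
      midx <- which(models$protein == pr)
      for (rep_i in seq_len(repeats)) {
        ids <- sample(ph_all$id)
        n_hold <- floor(length(ids) * holdout)
        hold_ids <- ids[seq_len(n_hold)]
        cv_ids <- setdiff(ids, hold_ids)
        fold_id <- rep_len(seq_len(folds), length(cv_ids))
        for (f in seq_len(folds)) {
          test_ids <- cv_ids[fold_id == f]
          train_ids <- setdiff(cv_ids, test_ids)
          r2_train <- vapply(midx, function(i) {
            r2_of(score_tab[[i]], ph_all[ph_all$id %in% train_ids, ])
          }, numeric(1))
          best <- midx[which.max(r2_train)]
          out[[length(out) + 1]] <- tibble::tibble(
            protein = pr, rep = rep_i, fold = f,
            p_threshold = models$p_threshold[best],
            maf_rule = models$maf_rule[best],
            r2_train = max(r2_train),
            r2_test = r2_of(score_tab[[best]], ph_all[ph_all$id %in% test_ids, ]),
            r2_holdout = r2_of(score_tab[[best]], ph_all[ph_all$id %in% hold_ids, ])
          )
        }
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Logistic screening of imputed protein levels against disease labels
#'
#' Per protein x phenotype: logistic regression of the binary label on
#' the protein's polygenic score plus covariates; the score's Wald
#' p-value is flagged against the Bonferroni threshold
#' `alpha / (n_proteins * n_eff_phenotypes)`. Fits with detected
#' separation are flagged and excluded from significance calls.
#'
#' @param scores Samples x proteins score matrix.
#' @param labels Samples x phenotypes 0/1 matrix (or data frame).
#' @param covariates Data frame of clinical covariates (same rows).
#' @param n_proteins,n_eff_phenotypes Bonferroni denominator terms
#'   (default: the matrix dimensions; the effective phenotype count may
#'   be supplied externally).
#' @param alpha Family-wise alpha.
#' @return `DiseaseScreenResult` tibble: protein, phenotype, coef,
#'   se, wald_p, separation, passes_bonferroni.
#' @export
disease_screen <- function(scores, labels, covariates,
                           n_proteins = ncol(scores),
                           n_eff_phenotypes = ncol(labels),
                           alpha = 0.05) {
  labels <- as.data.frame(labels)
  threshold <- alpha / (n_proteins * n_eff_phenotypes)
  out <- list()
  for (ph in colnames(labels)) {
    y <- labels[[ph]]
    if (length(unique(y[!is.na(y)])) < 2) {
      abort(sprintf("phenotype '%s' has no cases or no controls", ph))
    }
    for (pr in colnames(scores)) {
      df <- data.frame(y = y, score = as.numeric(scale(scores[, pr])), covariates)
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(y ~ ., data = df, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
            sep <<- TRUE
            invokeRestart("muffleWarning")
          }
        })
      sm <- summary(fit)$coefficients
      co <- sm["score", ]
      sep <- sep || abs(co[1]) > 15
      out[[length(out) + 1]] <- tibble::tibble(
        protein = pr, phenotype = ph,
        coef = co[1], se = co[2], wald_p = co[4],
        separation = sep,
        passes_bonferroni = !sep & co[4] < threshold
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "threshold") <- threshold
  res
}

# Wilcoxon AUC with half credit for ties
auc_of <- function(pred, labels) {
  r <- rank(pred)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong test for a difference in paired AUCs
#'
#' Paired structural-components estimator of the covariance of two
#' correlated AUCs on the same samples; ties receive half credit.
#' Identical predictions give a difference of exactly 0 with p-value 1.
#'
#' @param pred1,pred2 Risk predictions of the two classifiers.
#' @param labels Binary 0/1 labels.
#' @return List: auc1, auc2, delta, se, p.
#' @export
delong_test <- function(pred1, pred2, labels) {
  cases <- which(labels == 1); controls <- which(labels == 0)
  assert_that(length(cases) > 0 && length(controls) > 0,
              "need both cases and controls")
  comp <- function(pred) {
    x <- pred[cases]; y <- pred[controls]
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  c1 <- comp(pred1); c2 <- comp(pred2)
  m <- length(cases); n <- length(controls)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- c1$auc - c2$auc
  if (var_delta <= 1e-16) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    return(list(auc1 = c1$auc, auc2 = c2$auc, delta = delta, se = 0, p = p))
  }
  z <- delta / sqrt(var_delta)
  list(auc1 = c1$auc, auc2 = c2$auc, delta = delta, se = sqrt(var_delta),
       p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Compare nested logistic disease models
#'
#' Likelihood-ratio test of the deviance difference (chi-squared with
#' degrees of freedom equal to the parameter difference) and DeLong's
#' test on the difference in AUC of the fitted probabilities.
#'
#' @param base_fit,augmented_fit Nested `glm` (binomial) fits on
#'   identical samples; base terms must be a subset of augmented terms.
#' @return List: lrt_p, df, auc_base, auc_augmented, delong_p, delta_auc.
#' @export
compare_models <- function(base_fit, augmented_fit) {
  assert_that(length(base_fit$y) == length(augmented_fit$y) &&
                all(base_fit$y == augmented_fit$y),
              "models must be fitted on identical samples")
  tb <- attr(base_fit$terms, "term.labels")
  ta <- attr(augmented_fit$terms, "term.labels")
  if (!all(tb %in% ta)) abort("models are not nested")
  df <- augmented_fit$rank - base_fit$rank
  assert_that(df >= 0, "augmented model must have at least as many parameters")
  lrt_stat <- deviance(base_fit) - deviance(augmented_fit)
  lrt_p <- pchisq(max(lrt_stat, 0), df = max(df, 1), lower.tail = FALSE)
  dl <- delong_test(predict(augmented_fit, type = "response"),
                    predict(base_fit, type = "response"),
                    base_fit$y)
  list(lrt_p = lrt_p, lrt_stat = lrt_stat, df = df,
       auc_base = dl$auc2, auc_augmented = dl$auc1,
       delta_auc = dl$delta, delong_p = dl$p)
}

#' Elastic-net selection over all protein scores
#'
#' Penalized logistic regression of a disease label on all standardized
#' protein scores (covariates unpenalized), over a grid of elastic-net
#' mixing values `alpha`; per alpha the penalty is tuned by k-fold
#' cross-validated deviance and set one standard error above the
#' minimum (`lambda.1se`) for extra shrinkage. Hold-out AUC is reported
#' per alpha; the selected score set is the nonzero-coefficient scores
#' at the chosen alpha (best hold-out AUC unless `alpha_pick` is
#' given).
#'
#' @param scores Samples x proteins score matrix.
#' @param labels Binary 0/1 vector.
#' @param covariates Data frame (unpenalized), or NULL.
#' @param alpha_grid Elastic-net mixing grid (default 0 to 1 by 0.1).
#' @param folds Cross-validation folds.
#' @param holdout Hold-out fraction for AUC reporting.
#' @param alpha_pick Optional fixed alpha for the selection.
#' @param seed Integer seed.
#' @return List: `per_alpha` tibble (alpha, lambda_1se, n_selected,
#'   auc_holdout, selected list), `selected` for the chosen alpha,
#'   `alpha_chosen`.
#' @export
elastic_net_select <- function(scores, labels, covariates = NULL,
                               alpha_grid = seq(0, 1, by = 0.1),
                               folds = 10, holdout = 0.2,
                               alpha_pick = NULL, seed = 1) {
  with_seed(seed, {
    n <- length(labels)
    scores_s <- scale(scores)
    X <- if (is.null(covariates)) scores_s else {
      cbind(scores_s, model.matrix(~ . - 1, data = as.data.frame(covariates)))
    }
    n_sc <- ncol(scores_s)
    pf <- c(rep(1, n_sc), rep(0, ncol(X) - n_sc))
    hold <- sample.int(n, floor(n * holdout))
    train <- setdiff(seq_len(n), hold)
    foldid <- sample(rep_len(seq_len(folds), length(train)))
    rows <- purrr::map(alpha_grid, function(a) {
      cvfit <- glmnet::cv.glmnet(X[train, , drop = FALSE], labels[train],
                                 family = "binomial", alpha = a,
                                 foldid = foldid, penalty.factor = pf,
                                 standardize = FALSE)
      co <- as.matrix(coef(cvfit, s = "lambda.1se"))[-1, 1]
      sel <- colnames(scores_s)[which(co[seq_len(n_sc)] != 0)]
      pred <- predict(cvfit, newx = X[hold, , drop = FALSE],
                      s = "lambda.1se", type = "response")[, 1]
      tibble::tibble(alpha = a, lambda_1se = cvfit$lambda.1se,
                     n_selected = length(sel),
                     auc_holdout = auc_of(pred, labels[hold]),
                     selected = list(sel))
    })
    per_alpha <- dplyr::bind_rows(rows)
    chosen <- alpha_pick %||% per_alpha$alpha[which.max(per_alpha$auc_holdout)]
    sel <- per_alpha$selected[[which(per_alpha$alpha == chosen)[1]]]
    list(per_alpha = per_alpha, selected = sel, alpha_chosen = chosen)
  })
}
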