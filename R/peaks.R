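#' LD source backed by cohort dosages
#'
#' Builds an in-sample LD accessor over the discovery cohort: signed
#' dosage correlations, allele frequencies and effective (non-missing)
#' sample sizes, computed lazily per variant pair.
#'
#' @param cohort A `pqtl_cohort`.
#' @return A `pqtl_ld` list with functions `cor(ids)` (signed correlation
#'   matrix), `r2(ids)` and lookup tables `freq`, `n`, `pos`, `chrom`.
#' @export
ld_from_cohort <- function(cohort) {
  G <- impute_dosages(cohort$dosages)
  Gs <- scale(G)
  Gs[is.na(Gs)] <- 0
  n_all <- nrow(G)
  fr <- cohort_freq(cohort)
  cor_fun <- function(ids) {
    X <- Gs[, ids, drop = FALSE]
    r <- crossprod(X) / (n_all - 1)
    dimnames(r) <- list(ids, ids)
    r
  }
  structure(list(
    cor = cor_fun,
    r2 = function(ids) cor_fun(ids)^2,
    freq = setNames(fr$af, fr$id),
    maf = setNames(fr$maf, fr$id),
    n = setNames(round((1 - fr$miss) * n_all), fr$id),
    pos = setNames(fr$pos, fr$id),
    chrom = setNames(fr$chrom, fr$id),
    ids = fr$id
  ), class = "pqtl_ld")
}

#' Extract association signals by LD- and distance-based pruning
#'
#' Implements the peak-calling algorithm: sort variants passing the
#' significance threshold by increasing p-value; for each retained
#' variant remove all remaining significant variants with r-squared
#' greater than `r2_prune`; finally group retained variants located
#' within less than `merge_bp` of each other (transitive chaining on the
#' same chromosome) into signals, whose index variant is the member with
#' the lowest p-value.
#'
#' Ties in p are broken by genomic position (lower first).
#'
#' @param assoc A `pqtl_assoc`.
#' @param threshold Significance threshold on p.
#' @param ld A `pqtl_ld` from [ld_from_cohort()].
#' @param r2_prune LD-pruning threshold (default 0.2).
#' @param merge_bp Distance for grouping retained variants (default 2 Mb).
#' @return Tibble of signals: signal, index_id, index_p, chrom, start,
#'   end, n_members, members (list of member variant ids: the retained
#'   variants of the group plus their pruned LD partners).
#' @export
extract_signals <- function(assoc, threshold, ld, r2_prune = 0.2,
                            merge_bp = 2e6) {
  sig <- assoc |>
    dplyr::filter(p <= threshold) |>
    dplyr::arrange(p, chrom, pos)
  if (nrow(sig) == 0) {
    return(tibble::tibble(signal = integer(), index_id = character(),
                          index_p = numeric(), chrom = character(),
                          start = integer(), end = integer(),
                          n_members = integer(), members = list()))
  }
  R2 <- ld$r2(sig$id)
  active <- rep(TRUE, nrow(sig))
  retained <- integer(0)
  partners <- list()
  for (i in seq_len(nrow(sig))) {
    if (!active[i]) next
    retained <- c(retained, i)
    linked <- which(active & R2[i, ] > r2_prune)
    linked <- setdiff(linked, i)
    partners[[length(retained)]] <- sig$id[linked]
    active[linked] <- FALSE
    active[i] <- FALSE
  }
  kept <- sig[retained, ]
  kept$partners <- partners
  kept <- dplyr::arrange(kept, chrom, pos)
  # transitive <merge_bp chaining within chromosome
  grp <- integer(nrow(kept))
  g <- 0L
  for (i in seq_len(nrow(kept))) {
    if (i == 1 || kept$chrom[i] != kept$chrom[i - 1] ||
        kept$pos[i] - kept$pos[i - 1] >= merge_bp) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  kept$grp <- grp
  kept |>
    dplyr::group_by(grp) |>
    dplyr::summarise(
      index_id = id[which.min(p)],
      index_p = min(p),
      chrom = chrom[1],
      start = min(pos), end = max(pos),
      members = list(unique(c(id, unlist(partners)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_members = lengths(members), signal = dplyr::row_number()) |>
    dplyr::select(signal, index_id, index_p, chrom, start, end, n_members,
                  members)
}

#' Greedy LD clumping
#'
#' Retains variants greedily by ascending p-value; for each retained
#' index, candidates within `window_bp` with r-squared above `r2` are
#' removed.
#'
#' @param assoc A `pqtl_assoc`.
#' @param ld A `pqtl_ld`.
#' @param r2 Clumping r-squared (default 0.1).
#' @param window_bp Clumping window (default 1 Mb).
#' @param p_max Only variants with `p <= p_max` are considered.
#' @return Character vector of retained (index) variant ids.
#' @export
clump <- function(assoc, ld, r2 = 0.1, window_bp = 1e6, p_max = 1) {
  cand <- assoc |>
    dplyr::filter(p <= p_max) |>
    dplyr::arrange(p, chrom, pos)
  if (nrow(cand) == 0) return(character(0))
  R2 <- ld$r2(cand$id)
  active <- rep(TRUE, nrow(cand))
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    kept <- c(kept, cand$id[i])
    near <- abs(cand$pos - cand$pos[i]) <= window_bp & cand$chrom == cand$chrom[i]
    drop <- active & near & R2[i, ] > r2
    drop[i] <- TRUE
    active[drop] <- FALSE
  }
  kept
}

# approximate joint fit from summary statistics + LD reference:
# normal equations B = D^1/2 R D^1/2 with D_j = 2 f_j (1-f_j) n_j
cojo_joint_fit <- function(assoc, ids, ld) {
  a <- assoc[match(ids, assoc$id), ]
  f <- ld$freq[ids]
  n <- ld$n[ids]
  D <- 2 * f * (1 - f) * n
  R <- ld$cor(ids)
  B <- sqrt(outer(D, D)) * R
  Xty <- D * a$beta
  bJ <- tryCatch(as.numeric(solve(B, Xty)), error = function(e) NULL)
  if (is.null(bJ)) return(NULL)
  yty <- median(D * a$beta^2 + D * a$se^2 * (n - 1))
  df <- median(n) - length(ids)
  sigma2 <- max(yty - sum(bJ * Xty), 1e-12) / df
  Binv <- solve(B)
  se <- sqrt(pmax(diag(Binv), 0) * sigma2)
  tibble::tibble(
    id = ids,
    beta_joint = bJ, se_joint = se,
    p_joint = pchisq((bJ / se)^2, 1, lower.tail = FALSE),
    beta_marginal = a$beta, se_marginal = a$se, p_marginal = a$p
  )
}

#' Approximate conditional and joint stepwise model selection
#'
#' Forward selection of the most significant conditional variant from
#' summary statistics, with the joint model approximated from the
#' normal equations `D^1/2 R D^1/2` (`D_j = 2 f_j (1 - f_j) n_j`, `R` the
#' in-sample dosage correlation), followed by backward elimination of
#' variants whose joint p-value exceeds the threshold; iterated to a
#' fixed point. Candidates with r-squared above `collinearity_r2` with
#' the selected set are skipped and logged.
#'
#' @param assoc A `pqtl_assoc` (typically one locus).
#' @param ld A `pqtl_ld` covering the variants.
#' @param p_threshold Selection threshold on the conditional/joint p.
#' @param collinearity_r2 Collinearity cap (default 0.9).
#' @param max_iter Maximum forward/backward iterations.
#' @return A `pqtl_joint_model`: list with `selected` tibble (id, joint
#'   and marginal effects), `log` (character trace), `p_threshold`.
#' @export
cojo_select <- function(assoc, ld, p_threshold, collinearity_r2 = 0.9,
                        max_iter = 50) {
  assoc <- dplyr::arrange(assoc, p, chrom, pos)
  log_lines <- character(0)
  sel <- character(0)
  if (nrow(assoc) == 0 || min(assoc$p) > p_threshold) {
    return(structure(list(selected = NULL,
                          log = "no variant passes the threshold",
                          p_threshold = p_threshold),
                     class = "pqtl_joint_model"))
  }
  sel <- assoc$id[1]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    cand <- setdiff(assoc$id, sel)
    if (length(cand) > 0) {
      R2sel <- ld$r2(c(sel, cand))[cand, sel, drop = FALSE]
      collinear <- apply(R2sel, 1, max) > collinearity_r2
      if (any(collinear)) {
        log_lines <- c(log_lines,
                       sprintf("skipped collinear candidates: %s",
                               paste(cand[collinear], collapse = ", ")))
      }
      cand <- cand[!collinear]
      best_p <- Inf; best_id <- NULL
      for (cid in cand) {
        fit <- cojo_joint_fit(assoc, c(sel, cid), ld)
        if (is.null(fit)) next
        pc <- fit$p_joint[fit$id == cid]
        if (is.finite(pc) && pc < best_p) {
          best_p <- pc; best_id <- cid
        }
      }
      if (!is.null(best_id) && best_p <= p_threshold) {
        sel <- c(sel, best_id)
        changed <- TRUE
      }
    }
    # backward elimination
    repeat {
      fit <- cojo_joint_fit(assoc, sel, ld)
      if (is.null(fit)) {
        abort("singular joint model; collinearity cap too permissive")
      }
      if (length(sel) <= 1 || all(fit$p_joint <= p_threshold)) break
      worst <- fit$id[which.max(fit$p_joint)]
      # never drop below one variant; the top marginal stays if alone
      sel <- setdiff(sel, worst)
      log_lines <- c(log_lines, sprintf("dropped %s (joint p above threshold)", worst))
      changed <- TRUE
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("cojo_select did not converge; returning partial model")
  }
  fit <- cojo_joint_fit(assoc, sel, ld)
  structure(list(selected = fit, log = log_lines,
                 p_threshold = p_threshold, converged = converged),
            class = "pqtl_joint_model")
}

#' @export
print.pqtl_joint_model <- function(x, ...) {
  cat(sprintf("<pqtl_joint_model> %d selected variants (p threshold %.3g)\n",
              if (is.null(x$selected)) 0L else nrow(x$selected), x$p_threshold))
  if (!is.null(x$selected) && nrow(x$selected) > 0) print(x$selected)
  invisible(x)
}

#' Conditional association scan from summary statistics
#'
#' Re-computes each variant's effect and p-value conditional on a set of
#' conditioning variants, using the same approximate joint algebra as
#' [cojo_select()]: the conditional estimate for variant v is its entry
#' in the joint fit of `{v} + conditioning set`. Variants nearly
#' collinear with the conditioning set (r-squared above
#' `collinear_cap`) are reported with conditional p of 1 (their signal is
#' fully absorbed).
#'
#' @param assoc A `pqtl_assoc` containing both target and conditioning
#'   variants.
#' @param condition_ids Conditioning variant ids (must be in `assoc`).
#' @param ld A `pqtl_ld`.
#' @param collinear_cap r-squared above which a target is treated as a
#'   proxy of the conditioning set.
#' @return Tibble: id, beta_cond, se_cond, p_cond, collinear.
#' @export
conditional_scan <- function(assoc, condition_ids, ld,
                             collinear_cap = 0.9) {
  missing_ids <- setdiff(condition_ids, assoc$id)
  if (length(missing_ids) > 0) {
    abort(paste0("conditioning variants absent from assoc: ",
                 paste(missing_ids, collapse = ", ")))
  }
  targets <- setdiff(assoc$id, condition_ids)
  out <- purrr::map(targets, function(v) {
    r2v <- ld$r2(c(v, condition_ids))[v, condition_ids]
    if (max(r2v) > collinear_cap) {
      return(tibble::tibble(id = v, beta_cond = 0, se_cond = NA_real_,
                            p_cond = 1, collinear = TRUE))
    }
    fit <- cojo_joint_fit(assoc, c(condition_ids, v), ld)
    if (is.null(fit)) {
      return(tibble::tibble(id = v, beta_cond = NA_real_, se_cond = NA_real_,
                            p_cond = NA_real_, collinear = TRUE))
    }
    row <- fit[fit$id == v, ]
    tibble::tibble(id = v, beta_cond = row$beta_joint,
                   se_cond = row$se_joint, p_cond = row$p_joint,
                   collinear = FALSE)
  })
  dplyr::bind_rows(out)
}
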