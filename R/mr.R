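#' Assemble harmonized MR instruments for a protein
#'
#' Matches the conditionally independent exposure variants of a protein
#' to an outcome GWAS by variant id, falling back to the best tagging
#' proxy with r-squared above `tag_r2` (ties broken by distance);
#' harmonizes effect alleles (outcome effects are sign-flipped on
#' ref/alt swaps, proxy effects on negative LD sign); drops instruments
#' inside excluded pleiotropic loci and, optionally, palindromic
#' variants with MAF above 0.42.
#'
#' @param exposure Tibble of independent exposure variants: `id`,
#'   `beta_exp`, `se_exp` (e.g. a joint model's selected table renamed),
#'   plus `ea`, `oa` if allele harmonization against the outcome is
#'   needed (defaults taken from `ld` cohort variants are not available,
#'   so provide them; rows without alleles are matched by id only).
#' @param outcome Outcome GWAS tibble: `id`, `ea`, `oa`, `beta_out`,
#'   `se_out`, `p_out`, `n_out`.
#' @param ld A `pqtl_ld` for proxy search (NULL disables proxies).
#' @param pleio_exclude Tibble of excluded loci (`chrom`, `start`,
#'   `end`) or NULL; instruments whose position (from `ld`) falls inside
#'   are dropped.
#' @param tag_r2 Proxy threshold (default 0.8).
#' @param drop_palindromic Drop A/T & C/G variants with MAF > 0.42
#'   (needs `ld` for MAF; default TRUE).
#' @return Instrument tibble: id (exposure), proxy, provenance, beta_exp,
#'   se_exp, beta_out, se_out; attribute `dropped` logs exclusions.
#' @export
assemble_instruments <- function(exposure, outcome, ld = NULL,
                                 pleio_exclude = NULL, tag_r2 = 0.8,
                                 drop_palindromic = TRUE) {
  dropped <- character(0)
  rows <- purrr::map(seq_len(nrow(exposure)), function(i) {
    id <- exposure$id[i]
    if (!is.null(pleio_exclude) && !is.null(ld) && id %in% ld$ids) {
      pos <- ld$pos[id]; chrom <- ld$chrom[id]
      inside <- any(pleio_exclude$chrom == chrom &
                      pleio_exclude$start <= pos & pos <= pleio_exclude$end)
      if (inside) {
        dropped <<- c(dropped, sprintf("%s: excluded pleiotropic locus", id))
        return(NULL)
      }
    }
    if (drop_palindromic && !is.null(ld) && id %in% ld$ids &&
        all(c("ea", "oa") %in% names(exposure))) {
      pal <- paste0(exposure$ea[i], exposure$oa[i]) %in% c("AT", "TA", "CG", "GC")
      if (pal && ld$maf[id] > 0.42) {
        dropped <<- c(dropped, sprintf("%s: palindromic with MAF > 0.42", id))
        return(NULL)
      }
    }
    proxy <- id; prov <- "direct"; ld_sign <- 1
    if (!(id %in% outcome$id)) {
      proxy <- NA_character_
      if (!is.null(ld) && id %in% ld$ids) {
        cands <- intersect(ld$ids, outcome$id)
        if (length(cands) > 0) {
          r <- ld$cor(c(id, cands))[id, cands]
          r2 <- r^2
          best_r2 <- max(r2)
          if (best_r2 > tag_r2) {
            ties <- which(abs(r2 - best_r2) < 1e-12)
            if (length(ties) > 1) {
              dist <- abs(ld$pos[cands[ties]] - ld$pos[id])
              ties <- ties[which.min(dist)]
            }
            proxy <- cands[ties[1]]
            ld_sign <- sign(r[ties[1]])
            prov <- "tag"
          }
        }
      }
      if (is.na(proxy)) {
        dropped <<- c(dropped, sprintf("%s: absent from outcome, no r2>%.2f tag", id, tag_r2))
        return(NULL)
      }
    }
    out_row <- outcome[outcome$id == proxy, ][1, ]
    flip <- 1
    if (prov == "direct" && all(c("ea", "oa") %in% names(exposure))) {
      if (identical(out_row$ea, exposure$oa[i]) &&
          identical(out_row$oa, exposure$ea[i])) {
        flip <- -1
      } else if (!identical(out_row$ea, exposure$ea[i])) {
        dropped <<- c(dropped, sprintf("%s: alleles unmatchable", id))
        return(NULL)
      }
    }
    tibble::tibble(id = id, proxy = proxy, provenance = prov,
                   beta_exp = exposure$beta_exp[i],
                   se_exp = exposure$se_exp[i],
                   beta_out = out_row$beta_out * flip * ld_sign,
                   se_out = out_row$se_out)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- dropped
  out
}

#' Wald ratio causal estimate from a single instrument
#'
#' `estimate = beta_out / beta_exp`; first-order standard error
#' `se_out / |beta_exp|`; p-value from the normal distribution. A
#' weak-instrument warning is raised when `|beta_exp| / se_exp < 2`.
#'
#' @param instrument One-row instrument tibble (`beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @return One-row `mr_result` tibble: method, estimate, se, p,
#'   n_instruments.
#' @export
wald_ratio <- function(instrument) {
  assert_that(nrow(instrument) == 1, "wald_ratio takes a single instrument")
  b <- instrument$beta_exp
  assert_that(b != 0, "beta_exp must be nonzero")
  if (abs(b) / instrument$se_exp < 2) {
    warn("weak instrument: |beta_exp|/se_exp < 2")
  }
  est <- unname(instrument$beta_out / b)
  se <- unname(instrument$se_out / abs(b))
  tibble::tibble(method = "wald",
                 estimate = est, se = se,
                 p = max(2 * pnorm(abs(est / se), lower.tail = FALSE),
                         .Machine$double.xmin),
                 n_instruments = 1L)
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' Combines per-instrument Wald ratios with weights equal to the inverse
#' squared first-order ratio standard errors:
#' `estimate = sum(w_i r_i) / sum(w_i)`, `se = (sum w_i)^(-1/2)`.
#' Equivalent to the zero-intercept weighted regression of outcome on
#' exposure effects.
#'
#' @param instruments Instrument tibble (>= 2 rows).
#' @return One-row `mr_result` tibble.
#' @export
ivw <- function(instruments) {
  assert_that(nrow(instruments) >= 2, "ivw needs at least 2 instruments")
  if (any(abs(instruments$beta_exp) / instruments$se_exp < 2)) {
    warn("weak instrument(s): |beta_exp|/se_exp < 2")
  }
  ratio <- instruments$beta_out / instruments$beta_exp
  se_r <- instruments$se_out / abs(instruments$beta_exp)
  w <- 1 / se_r^2
  est <- unname(sum(w * ratio) / sum(w))
  se <- unname(1 / sqrt(sum(w)))
  tibble::tibble(method = "ivw", estimate = est, se = se,
                 p = max(2 * pnorm(abs(est / se), lower.tail = FALSE),
                         .Machine$double.xmin),
                 n_instruments = nrow(instruments))
}

#' Screen protein-outcome pairs by two-sample MR with FDR control
#'
#' Runs the Wald ratio (single instrument) or fixed-effect IVW (two or
#' more) per protein-outcome pair, adjusts p-values by
#' Benjamini-Hochberg across all pairs, and flags candidate protective
#' ("therapeutically actionable") pairs: a significant positive causal
#' estimate together with at least one level-lowering instrument allele,
#' i.e. the allele lowers the protein and lowers disease risk.
#'
#' @param instrument_table Tibble of instruments with columns `protein`,
#'   `outcome` plus the instrument columns of
#'   [assemble_instruments()].
#' @param fdr FDR level (default 0.05).
#' @return `mr_result` tibble: protein, outcome, method, estimate, se,
#'   p, q, n_instruments, significant, protective.
#' @export
mr_screen <- function(instrument_table, fdr = 0.05) {
  res <- instrument_table |>
    dplyr::group_by(protein, outcome) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 1) wald_ratio(df) else ivw(df)
    }) |>
    dplyr::ungroup()
  lower_allele <- instrument_table |>
    dplyr::group_by(protein, outcome) |>
    dplyr::summarise(has_lowering = any(beta_exp < 0), .groups = "drop")
  res |>
    dplyr::left_join(lower_allele, by = c("protein", "outcome")) |>
    dplyr::mutate(
      q = bh_fdr(p),
      significant = q < fdr,
      protective = significant & estimate > 0 & has_lowering
    ) |>
    dplyr::select(-has_lowering)
}
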