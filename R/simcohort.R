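#' Simulate a haplotype pool with blockwise linkage disequilibrium
#'
#' Generates a pool of founder haplotypes organised in independent LD
#' blocks. Within a block, haplotypes are built by mosaic copying from a
#' small set of template haplotypes with a per-site template-switch
#' (recombination) probability, so pairwise r-squared decays with
#' inter-variant distance; across blocks variants are unlinked in
#' expectation. The allele-frequency spectrum is drawn from a Beta
#' distribution skewed towards rare alleles so that rare (MAF < 1%)
#' variants are represented, as in sequencing data.
#'
#' The realized allele frequencies of the pool play the role of the
#' "reference panel" frequencies against which isolate drift is later
#' measured.
#'
#' @param n_founder Number of founder individuals (pool holds
#'   `2 * n_founder` haplotypes).
#' @param n_blocks Number of independent LD blocks.
#' @param vars_per_block Variants per block.
#' @param maf_shape1,maf_shape2 Beta parameters of the generating
#'   allele-frequency spectrum.
#' @param recomb Per-site template-switch probability within a block;
#'   smaller values give longer-range LD.
#' @param n_templates Number of template haplotypes per block.
#' @param rare_direct Generating frequencies below this are drawn
#'   directly (independently) on the pool haplotypes instead of by
#'   template copying, so the realized spectrum includes rare alleles.
#' @param spacing_bp Physical distance between adjacent variants.
#' @param seed Integer seed; all randomness is local to the call.
#' @return An object of class `hap_pool`: list with `haplotypes`
#'   (2N x M 0/1 matrix), `variants` (tibble: chrom, pos, id, ref, alt,
#'   block), `ref_freq`, and `recomb`.
#' @export
simulate_haplotypes <- function(n_founder = 1000, n_blocks = 20,
                                vars_per_block = 50,
                                maf_shape1 = 0.25, maf_shape2 = 1.4,
                                recomb = 0.08, n_templates = 16,
                                rare_direct = 0.05,
                                spacing_bp = 2000L, seed = 1) {
  assert_that(n_founder >= 1 && n_blocks >= 1 && vars_per_block >= 1,
              "all counts must be >= 1")
  with_seed(seed, {
    m <- n_blocks * vars_per_block
    p_gen <- pmin(pmax(rbeta(m, maf_shape1, maf_shape2), 0.002), 0.998)
    block <- rep(seq_len(n_blocks), each = vars_per_block)
    # templates: independent Bernoulli draws per block
    templates <- matrix(rbinom(n_templates * m, 1L, rep(p_gen, each = n_templates)),
                        nrow = n_templates, ncol = m)
    H <- mosaic_copy(templates, 2L * n_founder, block, recomb)
    # template copying quantizes frequencies at 1/n_templates, which
    # would leave no genuinely rare variation; draw alleles at rare
    # sites directly so the spectrum reaches below 1% MAF
    rare <- which(p_gen < rare_direct)
    for (j in rare) {
      H[, j] <- rbinom(nrow(H), 1L, p_gen[j])
    }
    ref_freq <- colMeans(H)
    if (all(ref_freq %in% c(0, 1))) {
      abort("monomorphic pool: every variant is fixed; increase n_templates or adjust the MAF spectrum")
    }
    pos <- (block - 1L) * 1e6L + ((seq_len(m) - 1L) %% vars_per_block) * spacing_bp + 1L
    variants <- tibble::tibble(
      chrom = "1",
      pos = as.integer(pos),
      id = sprintf("var%05d", seq_len(m)),
      ref = "A", alt = "G",
      block = block
    )
    structure(list(haplotypes = H, variants = variants,
                   ref_freq = ref_freq, recomb = recomb),
              class = "hap_pool")
  })
}

# build n_hap haplotypes by mosaic copying from `templates` rows;
# template switches occur with prob `recomb` per site, always at block edges
mosaic_copy <- function(templates, n_hap, block, recomb) {
  m <- ncol(templates)
  k <- nrow(templates)
  block_start <- c(TRUE, block[-1] != block[-m])
  H <- matrix(0L, nrow = n_hap, ncol = m)
  for (h in seq_len(n_hap)) {
    switch_here <- runif(m) < recomb | block_start
    seg <- cumsum(switch_here)
    tmpl <- sample.int(k, max(seg), replace = TRUE)[seg]
    H[h, ] <- templates[cbind(tmpl, seq_len(m))]
  }
  H
}

#' Simulate a cohort of diploid genotypes from a haplotype pool
#'
#' Draws cohort haplotypes by fresh mosaic copying from the pool (so
#' cohort allele frequencies are binomially distributed around the pool
#' frequencies), optionally applies isolate allele-frequency drift via a
#' Balding-Nichols Beta perturbation with parameter `drift_F`, and
#' optionally creates full-sib pairs to induce cryptic relatedness.
#' Genotype missingness is injected independently per genotype.
#'
#' Under Balding-Nichols drift, the drifted frequency p' for a variant
#' with reference frequency p satisfies E(p') = p and
#' Var(p') = F p (1 - p).
#'
#' @param pool A `hap_pool` from [simulate_haplotypes()].
#' @param n Number of samples (>= 2).
#' @param n_families Number of full-sib pairs among the `n` samples
#'   (each pair consumes two sample slots; parents are not retained).
#' @param drift_F Balding-Nichols drift parameter in `[0, 1)`.
#' @param miss_rate Per-genotype missingness probability.
#' @param seed Integer seed.
#' @return A `pqtl_cohort`: list with `dosages` (n x m, values 0/1/2 or
#'   NA), `variants`, `samples` (id, age, sex, plate, season),
#'   `kinship_truth` (n x n pedigree expectation, diagonal 1, sib pairs
#'   0.5), and `ref_freq`.
#' @export
simulate_cohort <- function(pool, n, n_families = 0, drift_F = 0,
                            miss_rate = 0, seed = 1) {
  assert_that(inherits(pool, "hap_pool"), "pool must be a hap_pool")
  assert_that(n >= 2, "n must be >= 2")
  assert_that(drift_F >= 0 && drift_F < 1, "drift_F must be in [0, 1)")
  if (2 * n_families > n) abort("n_families exceeds the number of samples")
  with_seed(seed, {
    m <- ncol(pool$haplotypes)
    block <- pool$variants$block
    p_ref <- pool$ref_freq
    poly <- p_ref > 0 & p_ref < 1
    p_drift <- p_ref
    if (drift_F > 0) {
      a <- p_ref * (1 - drift_F) / drift_F
      b <- (1 - p_ref) * (1 - drift_F) / drift_F
      p_drift[poly] <- rbeta(sum(poly), a[poly], b[poly])
    }
    n_unrel <- n - 2L * n_families
    draw_haps <- function(k) {
      H <- mosaic_copy(pool$haplotypes, k, block, pool$recomb)
      if (drift_F > 0) drift_flip(H, p_ref, p_drift) else H
    }
    H_unrel <- draw_haps(2L * n_unrel)
    dos <- matrix(0L, nrow = n, ncol = m)
    if (n_unrel > 0) {
      dos[seq_len(n_unrel), ] <-
        H_unrel[seq_len(n_unrel) * 2L - 1L, , drop = FALSE] +
        H_unrel[seq_len(n_unrel) * 2L, , drop = FALSE]
    }
    kin <- diag(1, n)
    if (n_families > 0) {
      n_block <- max(block)
      for (f in seq_len(n_families)) {
        par_h <- draw_haps(4L)  # rows 1,2 = mother; 3,4 = father
        i1 <- n_unrel + 2L * f - 1L
        i2 <- i1 + 1L
        for (child_row in c(i1, i2)) {
          pick_m <- sample(c(1L, 2L), n_block, replace = TRUE)[block]
          pick_f <- sample(c(3L, 4L), n_block, replace = TRUE)[block]
          dos[child_row, ] <- par_h[cbind(pick_m, seq_len(m))] +
            par_h[cbind(pick_f, seq_len(m))]
        }
        kin[i1, i2] <- kin[i2, i1] <- 0.5
      }
    }
    if (miss_rate > 0) {
      dos[matrix(runif(length(dos)) < miss_rate, nrow = n)] <- NA
    }
    samples <- tibble::tibble(
      id = sprintf("S%05d", seq_len(n)),
      age = pmin(pmax(round(rnorm(n, 52, 12)), 18), 90),
      sex = sample(c("F", "M"), n, replace = TRUE),
      plate = factor(sprintf("P%02d", (seq_len(n) - 1L) %/% 96L + 1L)),
      # plated in collection order; season blocks of ~150 samples make
      # plate and season largely (not perfectly) correlated
      season = ifelse(((seq_len(n) - 1L) %/% 150L) %% 2L == 0L,
                      "summer", "winter")
    )
    rownames(dos) <- samples$id
    colnames(dos) <- pool$variants$id
    dimnames(kin) <- list(samples$id, samples$id)
    structure(list(dosages = dos, variants = pool$variants,
                   samples = samples, kinship_truth = kin,
                   ref_freq = p_ref),
              class = "pqtl_cohort")
  })
}

# per-entry allele flips moving haplotype frequencies from p to p_new
# while preserving the copying LD structure as far as possible
drift_flip <- function(H, p, p_new) {
  up <- which(p_new > p & p < 1)
  for (j in up) {
    pr <- (p_new[j] - p[j]) / (1 - p[j])
    zero <- H[, j] == 0L
    H[zero, j][runif(sum(zero)) < pr] <- 1L
  }
  down <- which(p_new < p & p > 0)
  for (j in down) {
    pr <- (p[j] - p_new[j]) / p[j]
    one <- H[, j] == 1L
    H[one, j][runif(sum(one)) < pr] <- 0L
  }
  H
}

#' @export
print.pqtl_cohort <- function(x, ...) {
  cat(sprintf("<pqtl_cohort> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Cohort allele-frequency summary
#'
#' @param cohort A `pqtl_cohort`.
#' @return Tibble with per-variant alt-allele frequency, MAF, MAC and
#'   missingness.
#' @export
cohort_freq <- function(cohort) {
  d <- cohort$dosages
  n_ok <- colSums(!is.na(d))
  af <- colSums(d, na.rm = TRUE) / (2 * n_ok)
  tibble::tibble(
    id = cohort$variants$id,
    chrom = cohort$variants$chrom,
    pos = cohort$variants$pos,
    af = af,
    maf = pmin(af, 1 - af),
    mac = pmin(colSums(d, na.rm = TRUE), 2 * n_ok - colSums(d, na.rm = TRUE)),
    miss = 1 - n_ok / nrow(d)
  )
}

#' Effect configuration for protein simulation
#'
#' Describes the genetic and non-genetic architecture of simulated
#' proteins. Genetic effect sizes are per-allele, in units of the
#' phenotype's standard deviation (a variant with per-allele effect b and
#' allele frequency f contributes variance `b^2 * 2 f (1 - f)`).
#'
#' @param cis_effects,trans_effects Tibbles with columns `protein`,
#'   `variant_id`, `beta`.
#' @param burden_effects Tibble with columns `protein`, `gene`,
#'   `variant_id`, `beta` (one row per contributing rare variant).
#' @param h2_poly Polygenic background fraction of variance, in `[0, 1)`;
#'   realized as a multivariate normal with covariance
#'   `h2_poly * kinship_truth`.
#' @param covariate_effects Named list of coefficients on standardized
#'   covariates: `age`, `age2`, `sex`, `season`, and `plate_sd` (SD of
#'   random per-plate shifts).
#' @param lod_quantile Fraction of values recorded below the per-protein
#'   limit of detection, in `[0, 1)`.
#' @param noise_sd Residual noise SD; `NULL` (default) completes the
#'   variance budget to 1.
#' @return An `effect_config` list.
#' @export
effect_config <- function(cis_effects = NULL, trans_effects = NULL,
                          burden_effects = NULL, h2_poly = 0,
                          covariate_effects = list(), lod_quantile = 0,
                          noise_sd = NULL) {
  assert_that(h2_poly >= 0 && h2_poly < 1, "h2_poly must be in [0, 1)")
  assert_that(lod_quantile >= 0 && lod_quantile < 1,
              "lod_quantile must be in [0, 1)")
  empty <- tibble::tibble(protein = character(), variant_id = character(),
                          beta = numeric())
  structure(list(
    cis_effects = cis_effects %||% empty,
    trans_effects = trans_effects %||% empty,
    burden_effects = burden_effects %||%
      tibble::tibble(protein = character(), gene = character(),
                     variant_id = character(), beta = numeric()),
    h2_poly = h2_poly,
    covariate_effects = covariate_effects,
    lod_quantile = lod_quantile,
    noise_sd = noise_sd
  ), class = "effect_config")
}

#' Simulate an NPX protein panel with known genetic architecture
#'
#' Each protein is the sum of covariate effects, per-allele genetic
#' effects (cis, trans and rare-burden), a polygenic term drawn with
#' covariance `h2_poly * kinship_truth`, and Gaussian noise, on a
#' natural-log NPX-like scale. A per-protein limit of detection (LOD) is
#' set at the `lod_quantile` empirical quantile, emulating assay
#' censoring; values below the LOD are retained in the matrix but fall
#' below the recorded LOD.
#'
#' @param cohort A `pqtl_cohort`.
#' @param config An [effect_config()].
#' @param n_proteins Number of proteins to simulate. Proteins mentioned
#'   in the config are created first; the remainder are pure
#'   noise/background proteins.
#' @param seed Integer seed.
#' @return List with `panel` (a [protein_panel()]) and `truth` (tibble of
#'   realized causal effects with expected variance contributions).
#' @export
simulate_proteins <- function(cohort, config, n_proteins = 10, seed = 1) {
  assert_that(inherits(config, "effect_config"), "config must be an effect_config")
  with_seed(seed, {
    n <- nrow(cohort$dosages)
    named <- unique(c(config$cis_effects$protein, config$trans_effects$protein,
                      config$burden_effects$protein))
    prot <- c(named, sprintf("PROT%03d", seq_len(max(0, n_proteins - length(named)))))
    prot <- prot[seq_len(max(n_proteins, length(named)))]
    af <- colMeans(cohort$dosages, na.rm = TRUE) / 2
    ce <- config$covariate_effects
    age_s <- as.numeric(scale(cohort$samples$age))
    sex_s <- as.numeric(cohort$samples$sex == "M") - 0.5
    season_s <- as.numeric(cohort$samples$season == "winter") - 0.5
    plates <- levels(cohort$samples$plate)
    # polygenic factor: one Cholesky shared across proteins
    L <- NULL
    if (config$h2_poly > 0) {
      L <- chol(cohort$kinship_truth + diag(1e-8, n))
    }
    npx <- matrix(NA_real_, n, length(prot),
                  dimnames = list(cohort$samples$id, prot))
    truth <- list()
    for (pr in prot) {
      y <- rep(5, n)  # arbitrary NPX baseline
      if (!is.null(ce$age)) y <- y + ce$age * age_s
      if (!is.null(ce$age2)) y <- y + ce$age2 * (age_s^2 - 1)
      if (!is.null(ce$sex)) y <- y + ce$sex * sex_s
      if (!is.null(ce$season)) y <- y + ce$season * season_s
      if (!is.null(ce$plate_sd) && ce$plate_sd > 0) {
        shift <- rnorm(length(plates), 0, ce$plate_sd)
        y <- y + shift[as.integer(cohort$samples$plate)]
      }
      gen <- dplyr::bind_rows(
        dplyr::mutate(config$cis_effects[config$cis_effects$protein == pr, ],
                      class = "cis"),
        dplyr::mutate(config$trans_effects[config$trans_effects$protein == pr, ],
                      class = "trans"),
        dplyr::mutate(config$burden_effects[config$burden_effects$protein == pr, ],
                      class = "burden")
      )
      var_gen <- 0
      if (nrow(gen) > 0) {
        gen$exp_var <- NA_real_
        miss_v <- setdiff(gen$variant_id, colnames(cohort$dosages))
        if (length(miss_v) > 0) {
          abort(paste0("causal variants absent from cohort: ",
                       paste(miss_v, collapse = ", ")))
        }
        for (k in seq_len(nrow(gen))) {
          v <- gen$variant_id[k]
          d <- cohort$dosages[, v]
          d[is.na(d)] <- mean(d, na.rm = TRUE)
          f <- af[v]
          y <- y + gen$beta[k] * (d - 2 * f)
          gen$exp_var[k] <- gen$beta[k]^2 * 2 * f * (1 - f)
        }
        var_gen <- sum(gen$exp_var)
      }
      if (var_gen + config$h2_poly > 1) {
        abort(sprintf("variance budget exceeded for %s: genetic %.3f + polygenic %.3f > 1",
                      pr, var_gen, config$h2_poly))
      }
      if (!is.null(L)) {
        y <- y + sqrt(config$h2_poly) * as.numeric(crossprod(L, rnorm(n)))
      }
      nsd <- config$noise_sd %||% sqrt(max(1 - var_gen - config$h2_poly, 0.01))
      y <- y + rnorm(n, 0, nsd)
      npx[, pr] <- y
      truth[[pr]] <- if (nrow(gen) > 0) {
        dplyr::select(gen, -dplyr::any_of("protein")) |>
          dplyr::mutate(protein = pr, .before = 1)
      } else NULL
    }
    lod <- vapply(seq_along(prot), function(j) {
      if (config$lod_quantile > 0) {
        as.numeric(quantile(npx[, j], config$lod_quantile))
      } else -Inf
    }, numeric(1))
    names(lod) <- prot
    panel <- protein_panel(npx, lod, cohort$samples$plate)
    truth_tbl <- dplyr::bind_rows(truth)
    if (nrow(truth_tbl) == 0) {
      truth_tbl <- tibble::tibble(protein = character(), variant_id = character(),
                                  beta = numeric(), class = character(),
                                  exp_var = numeric())
    }
    list(panel = panel, truth = truth_tbl)
  })
}

#' Simulate summary statistics of an independent outcome GWAS
#'
#' Draws an outcome phenotype in an independent cohort as
#' `theta` times the genetic protein component (defined by per-allele
#' exposure effects) plus noise, then computes per-variant linear
#' regression summary statistics. Used to emulate the outcome side of a
#' two-sample Mendelian randomization design.
#'
#' @param cohort An independent `pqtl_cohort` drawn from the same pool as
#'   the exposure cohort.
#' @param exposure_effects Tibble with `variant_id`, `beta`: the genetic
#'   architecture of the exposure protein.
#' @param theta Causal effect of the protein on the outcome.
#' @param noise_sd Outcome residual SD.
#' @param variant_ids Variants to report (default: all cohort variants).
#' @param seed Integer seed.
#' @return Tibble: id, ea, oa, beta_out, se_out, p_out, n_out.
#' @export
simulate_outcome_gwas <- function(cohort, exposure_effects, theta,
                                  noise_sd = 1, variant_ids = NULL,
                                  seed = 1) {
  with_seed(seed, {
    n <- nrow(cohort$dosages)
    y <- rnorm(n, 0, noise_sd)
    if (nrow(exposure_effects) > 0 && theta != 0) {
      for (k in seq_len(nrow(exposure_effects))) {
        d <- cohort$dosages[, exposure_effects$variant_id[k]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        y <- y + theta * exposure_effects$beta[k] * (d - mean(d))
      }
    }
    ids <- variant_ids %||% cohort$variants$id
    G <- impute_dosages(cohort$dosages[, ids, drop = FALSE])
    Gc <- sweep(G, 2, colMeans(G))
    yc <- y - mean(y)
    gtg <- colSums(Gc^2)
    ok <- gtg > 0
    num <- as.numeric(crossprod(Gc, yc))
    beta <- ifelse(ok, num / gtg, NA_real_)
    sse <- sum(yc^2) - ifelse(ok, num^2 / gtg, 0)
    se <- ifelse(ok, sqrt(sse / (n - 2) / gtg), NA_real_)
    z2 <- (beta / se)^2
    vmeta <- cohort$variants[match(ids, cohort$variants$id), ]
    tibble::tibble(
      id = ids,
      ea = vmeta$alt, oa = vmeta$ref,
      beta_out = beta, se_out = se,
      p_out = pchisq(z2, 1, lower.tail = FALSE),
      n_out = n
    ) |> dplyr::filter(!is.na(beta_out))
  })
}

# consequence classes in increasing severity order; used by burden masks
.consequence_levels <- c("intergenic", "regulatory", "synonymous",
                         "missense", "splice_donor", "stop_gained",
                         "frameshift")

#' Consequence severity ranking
#'
#' Packaged severity ranks for the consequence classes used by the
#' annotation simulator and the burden masks. Higher is more severe;
#' classes above `missense` are "severe" (protein-truncating/splice).
#'
#' @return Named integer vector of ranks.
#' @export
consequence_severity <- function() {
  setNames(seq_along(.consequence_levels) - 1L, .consequence_levels)
}

#' Simulate a functional annotation table
#'
#' Assigns each cohort variant a consequence class, CADD-like and
#' Eigen-like phred scores, and gene links. Variants inside a gene's
#' coding window receive coding consequences (severe / missense /
#' synonymous) and a link to that gene; each gene also owns a flanking
#' regulatory region whose variants are linked to the gene, emulating
#' documented eQTL overlap of regulatory features.
#'
#' @param cohort A `pqtl_cohort`.
#' @param gene_windows Tibble with `gene`, `chrom`, `start`, `end`
#'   (1-based fully closed coding windows). Gene ids must be unique.
#' @param reg_flank_bp Width of the regulatory region upstream of each
#'   gene window.
#' @param seed Integer seed.
#' @return Tibble: chrom, pos, id, consequence, cadd_phred, eigen_phred,
#'   gene_links (comma-separated, possibly "").
#' @export
simulate_annotations <- function(cohort, gene_windows, reg_flank_bp = 20000L,
                                 seed = 1) {
  if (anyDuplicated(gene_windows$gene)) abort("duplicated gene ids in gene_windows")
  with_seed(seed, {
    v <- cohort$variants
    m <- nrow(v)
    consequence <- rep("intergenic", m)
    links <- vector("list", m)
    for (g in seq_len(nrow(gene_windows))) {
      gw <- gene_windows[g, ]
      in_cod <- v$chrom == gw$chrom & v$pos >= gw$start & v$pos <= gw$end
      in_reg <- v$chrom == gw$chrom & v$pos >= gw$start - reg_flank_bp &
        v$pos < gw$start
      for (i in which(in_cod | in_reg)) links[[i]] <- c(links[[i]], gw$gene)
      consequence[in_cod] <- sample(
        c("splice_donor", "stop_gained", "frameshift", "missense", "synonymous"),
        sum(in_cod), replace = TRUE,
        prob = c(0.04, 0.03, 0.03, 0.40, 0.50))
      consequence[in_reg] <- "regulatory"
    }
    base_cadd <- c(intergenic = 2, regulatory = 8, synonymous = 5,
                   missense = 16, splice_donor = 26, stop_gained = 32,
                   frameshift = 30)
    base_eigen <- c(intergenic = 1, regulatory = 10, synonymous = 4,
                    missense = 13, splice_donor = 22, stop_gained = 26,
                    frameshift = 25)
    cadd <- pmax(base_cadd[consequence] + rnorm(m, 0, 3), 0)
    eigen <- pmax(base_eigen[consequence] + rnorm(m, 0, 3), 0)
    tibble::tibble(
      chrom = v$chrom, pos = v$pos, id = v$id,
      consequence = consequence,
      cadd_phred = round(as.numeric(cadd), 3),
      eigen_phred = round(as.numeric(eigen), 3),
      gene_links = vapply(links, function(x) paste(x, collapse = ","), character(1))
    )
  })
}
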