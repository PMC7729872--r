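# shared fixtures, built lazily once per test run
.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

fx_pool <- function() {
  fx("pool", function() {
    simulate_haplotypes(n_founder = 400, n_blocks = 10, vars_per_block = 30,
                        seed = 101)
  })
}

# 300 samples incl. 25 sib pairs, mild drift
fx_cohort <- function() {
  fx("cohort", function() {
    simulate_cohort(fx_pool(), n = 300, n_families = 25, drift_F = 0.02,
                    miss_rate = 0.002, seed = 102)
  })
}

fx_grm <- function() fx("grm", function() compute_grm(fx_cohort()))

# genome-scale cohort (5000 variants) incl. sib pairs, for calibration
# and GRM-expectation checks
fx_bigcohort <- function() {
  fx("bigcohort", function() {
    pool <- simulate_haplotypes(n_founder = 400, n_blocks = 100,
                                vars_per_block = 50, seed = 91)
    simulate_cohort(pool, n = 300, n_families = 25, seed = 92)
  })
}

fx_biggrm <- function() fx("biggrm", function() compute_grm(fx_bigcohort()))

fx_ld <- function() fx("ld", function() ld_from_cohort(fx_cohort()))

# identity-GRM stand-in (unrelated limit) matching the cohort samples
fx_grm_identity <- function() {
  fx("grm_id", function() {
    coh <- fx_cohort()
    n <- nrow(coh$dosages)
    structure(list(matrix = diag(n), n_variants_used = 0L,
                   sample_id = rownames(coh$dosages)),
              class = "pqtl_grm")
  })
}

# hand-built cohort from an explicit dosage matrix (for designed LD)
make_toy_cohort <- function(dosages, pos, chrom = "1") {
  n <- nrow(dosages); m <- ncol(dosages)
  ids <- colnames(dosages) %||% sprintf("t%03d", seq_len(m))
  colnames(dosages) <- ids
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(dosages) <- sample_ids
  structure(list(
    dosages = dosages,
    variants = tibble::tibble(chrom = chrom, pos = as.integer(pos), id = ids,
                              ref = "A", alt = "G"),
    samples = tibble::tibble(id = sample_ids,
                             age = 50, sex = "F", plate = factor("P01"),
                             season = "summer"),
    kinship_truth = diag(n), ref_freq = colMeans(dosages) / 2
  ), class = "pqtl_cohort")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# assoc-table builder for summary-statistics-level tests
make_assoc <- function(id, p, pos, beta = NULL, se = NULL, chrom = "1",
                       maf = 0.2, mac = 100, n = 500) {
  beta <- beta %||% (qnorm(p / 2, lower.tail = FALSE) * 0.05)
  se <- se %||% rep(0.05, length(id))
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos), id = id,
                        ea = "G", oa = "A", maf = maf, mac = mac, miss = 0,
                        beta = beta, se = se, p = p)
  class(out) <- c("pqtl_assoc", class(out))
  attr(out, "n") <- n
  out
}
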