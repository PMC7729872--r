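#' Construct a protein panel
#'
#' Container for an Olink-style NPX panel: a samples x proteins matrix on
#' the natural-log NPX scale, a per-protein limit of detection (LOD), and
#' per-sample plate assignments.
#'
#' @param npx Numeric matrix (samples x proteins) with row and column
#'   names; may contain missing values.
#' @param lod Named numeric vector of per-protein LODs (use `-Inf` for
#'   proteins without censoring).
#' @param plate Per-sample plate factor/vector.
#' @return A `protein_panel`.
#' @export
protein_panel <- function(npx, lod, plate) {
  assert_that(is.matrix(npx), "npx must be a matrix")
  assert_that(length(lod) == ncol(npx), "one LOD per protein required")
  assert_that(length(plate) == nrow(npx), "one plate per sample required")
  if (is.null(names(lod))) names(lod) <- colnames(npx)
  structure(list(npx = npx, lod = lod, plate = plate),
            class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("<protein_panel> %d samples x %d proteins (%d censored entries)\n",
              nrow(x$npx), ncol(x$npx), sum(x$npx < rep(x$lod, each = nrow(x$npx)), na.rm = TRUE)))
  invisible(x)
}

#' Censor NPX values below the limit of detection
#'
#' Sets every NPX entry strictly below its protein's LOD to missing.
#'
#' @param panel A [protein_panel()].
#' @return The censored panel, with attribute `n_censored` (named per
#'   protein count of newly censored entries).
#' @export
censor_below_lod <- function(panel) {
  below <- sweep(panel$npx, 2, panel$lod, `<`)
  below[is.na(below)] <- FALSE
  n_censored <- colSums(below)
  panel$npx[below] <- NA_real_
  attr(panel, "n_censored") <- n_censored
  panel
}

#' Exclude proteins with excessive missing or below-LOD data
#'
#' Removes proteins whose combined missing-or-below-LOD proportion is
#' strictly greater than `max_bad` (default 40%).
#'
#' @param panel A [protein_panel()] (censored or not; below-LOD values
#'   still present are counted as bad).
#' @param max_bad Exclusion threshold on the bad-entry proportion.
#' @return List with `panel` (retained proteins) and `excluded` (tibble
#'   of excluded proteins and their bad proportions).
#' @export
exclude_proteins <- function(panel, max_bad = 0.40) {
  assert_that(max_bad > 0 && max_bad < 1, "max_bad must be in (0, 1)")
  bad <- is.na(panel$npx) | sweep(panel$npx, 2, panel$lod, `<`)
  bad[is.na(bad)] <- TRUE
  prop_bad <- colMeans(bad)
  drop <- prop_bad > max_bad
  if (all(drop)) abort("all proteins exceed the exclusion threshold")
  excluded <- tibble::tibble(protein = colnames(panel$npx)[drop],
                             prop_bad = unname(prop_bad[drop]))
  panel$npx <- panel$npx[, !drop, drop = FALSE]
  panel$lod <- panel$lod[!drop]
  list(panel = panel, excluded = excluded)
}

# inverse-normal transform of ranks, offset (r - 0.5)/n, average ties
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' Adjust protein phenotypes for covariates and inverse-normal transform
#'
#' For each protein, fits an ordinary least squares regression of NPX on
#' age, age squared, sex, plate indicators, season, and the per-sample
#' mean NPX across all assays in the panel, then maps the residual ranks
#' to normal quantiles (offset `(rank - 0.5)/n`, ties averaged). Samples
#' with missing age are dropped. Redundant (aliased) design columns --
#' e.g. season perfectly confounded with plate -- are dropped with a
#' warning.
#'
#' The per-sample mean NPX is computed on the panel as passed (i.e.
#' after LOD censoring, before any protein exclusion), so pass the full
#' censored panel and subset proteins afterwards if needed.
#'
#' @param panel A censored [protein_panel()].
#' @param covariates Tibble with `id`, `age`, `sex`, `season` matching
#'   panel rows by `id` (plate is taken from the panel).
#' @param proteins Optional subset of proteins to transform.
#' @return Long tibble with columns `protein`, `id`, `value` (marginally
#'   standard-normal prepared phenotype) and `n_used` per protein.
#' @export
adjust_and_transform <- function(panel, covariates, proteins = NULL) {
  ids <- rownames(panel$npx)
  assert_that(all(ids %in% covariates$id),
              "every panel sample needs a covariate row")
  cv <- covariates[match(ids, covariates$id), ]
  keep <- !is.na(cv$age)
  # per-sample mean NPX: leave the focal protein out so that small
  # panels do not regress a protein on (essentially) itself; with many
  # assays this converges to the plain across-assay mean
  row_sum <- rowSums(panel$npx, na.rm = TRUE)
  row_n <- rowSums(!is.na(panel$npx))
  design <- data.frame(
    age = cv$age,
    age2 = cv$age^2,
    sex = as.numeric(factor(cv$sex)),
    plate = factor(panel$plate),
    season = as.numeric(factor(cv$season))
  )
  # single-level factors carry no information; drop them up front
  if (nlevels(design$plate) < 2) design$plate <- NULL
  proteins <- proteins %||% colnames(panel$npx)
  out <- purrr::map(proteins, function(pr) {
    y <- panel$npx[, pr]
    design_p <- design
    if (ncol(panel$npx) > 1) {
      y0 <- ifelse(is.na(y), 0, y)
      design_p$mean_npx <- (row_sum - y0) / pmax(row_n - !is.na(y), 1)
    }
    use <- keep & !is.na(y) & complete.cases(design_p)
    df <- design_p[use, , drop = FALSE]
    fit <- lm(y[use] ~ ., data = df)
    if (fit$rank < length(coef(fit))) {
      warn(sprintf("rank-deficient covariate design for %s; aliased columns dropped (%s)",
                   pr, paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
    }
    tibble::tibble(protein = pr, id = ids[use],
                   value = inverse_normal(residuals(fit)),
                   n_used = sum(use))
  })
  dplyr::bind_rows(out)
}

#' Widen prepared phenotypes to a samples x proteins matrix
#'
#' @param prepared Output of [adjust_and_transform()].
#' @param sample_ids Row order (default: order of appearance).
#' @return Numeric matrix with NA for samples a protein was not prepared
#'   in.
#' @export
prepared_matrix <- function(prepared, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(prepared$id)
  prot <- unique(prepared$protein)
  m <- matrix(NA_real_, length(sample_ids), length(prot),
              dimnames = list(sample_ids, prot))
  m[cbind(match(prepared$id, sample_ids), match(prepared$protein, prot))] <-
    prepared$value
  m
}
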