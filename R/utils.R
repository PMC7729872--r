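#' @importFrom rlang abort warn inform %||%
#' @importFrom stats pchisq pnorm qnorm qchisq rnorm runif rbeta rbinom
#'   median quantile var sd cor lm residuals complete.cases optimize
#'   integrate qbeta setNames binomial coef glm prop.test p.adjust
#'   model.matrix anova deviance predict
#' @importFrom utils head tail
NULL

# run expr with a local, restored RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# minor allele frequency / count from a dosage vector (0/1/2, NA allowed)
maf_of <- function(d) {
  f <- mean(d, na.rm = TRUE) / 2
  min(f, 1 - f)
}

mac_of <- function(d) {
  s <- sum(d, na.rm = TRUE)
  n2 <- 2 * sum(!is.na(d))
  min(s, n2 - s)
}

# mean-impute missing dosages, column-wise
impute_dosages <- function(G) {
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    G[nas] <- mu[nas[, 2]]
  }
  G
}
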