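#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted variance-component model
#'
#' @param x A `pqtl_vc`.
#' @param ... Unused.
#' @return One row per variance component.
#' @export
tidy.pqtl_vc <- function(x, ...) {
  tibble::tibble(
    component = c("genetic", "residual"),
    estimate = c(x$sigma_g2, x$sigma_e2)
  )
}

#' @rdname tidy.pqtl_vc
#' @export
glance.pqtl_vc <- function(x, ...) {
  tibble::tibble(
    sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
    lambda_ratio = x$lambda_ratio, h2 = x$h2,
    loglik_reml = x$loglik_reml, n = x$n,
    identifiable = x$identifiable
  )
}

#' Tidy a conditional/joint model
#'
#' @param x A `pqtl_joint_model`.
#' @param ... Unused.
#' @return The selected-variant table (empty tibble if nothing
#'   selected).
#' @export
tidy.pqtl_joint_model <- function(x, ...) {
  x$selected %||%
    tibble::tibble(id = character(), beta_joint = numeric(),
                   se_joint = numeric(), p_joint = numeric(),
                   beta_marginal = numeric(), se_marginal = numeric(),
                   p_marginal = numeric())
}

#' @rdname tidy.pqtl_joint_model
#' @export
glance.pqtl_joint_model <- function(x, ...) {
  tibble::tibble(
    n_selected = if (is.null(x$selected)) 0L else nrow(x$selected),
    p_threshold = x$p_threshold,
    converged = x$converged %||% TRUE
  )
}

#' Tidy an effective-traits report
#'
#' @param x A `meff_report`.
#' @param ... Unused.
#' @return One row per eigenvalue.
#' @export
tidy.meff_report <- function(x, ...) {
  tibble::tibble(index = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues)
}

#' @rdname tidy.meff_report
#' @export
glance.meff_report <- function(x, ...) {
  tibble::tibble(M = x$M, v_lambda_obs = x$v_lambda_obs, m_eff = x$m_eff,
                 m_eff_rounded = x$m_eff_rounded, threshold = x$threshold)
}
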