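#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted two-state model
#'
#' One row per free model parameter (stationary open frequency, invariant
#' proportion, gamma shape or free-rate categories); branch lengths are on
#' the fitted tree itself.
#'
#' @param x A `bin_ml_fit` from [ml_fit()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.bin_ml_fit <- function(x, ...) {
  m <- x$model
  out <- tibble(term = c("pi_open", "p_inv"),
                estimate = c(m$pi[2], m$p_inv))
  if (!is.null(m$alpha)) {
    out <- bind_rows(out, tibble(term = "gamma_shape", estimate = m$alpha))
  }
  if (length(m$rates) > 1) {
    k <- seq_along(m$rates)
    out <- bind_rows(out,
                     tibble(term = paste0("rate_", k), estimate = m$rates),
                     tibble(term = paste0("weight_", k), estimate = m$weights))
  }
  out
}

#' Glance at a fitted two-state model
#'
#' @param x A `bin_ml_fit`.
#' @param ... Unused.
#' @return One-row tibble with `tag`, `logLik`, `k`, `AIC`, `n_sites`,
#'   `n_patterns`, `converged`, `iterations`.
#' @export
glance.bin_ml_fit <- function(x, ...) {
  tibble(tag = x$model$tag, logLik = x$lnL, k = x$k, AIC = x$AIC,
         n_sites = x$n_sites, n_patterns = x$n_patterns,
         converged = x$converged, iterations = x$iterations)
}

#' Tidy a model-selection table
#'
#' @param x A `bin_model_selection` from [select_model_aic()].
#' @param ... Unused.
#' @return The AIC comparison tibble, best model first.
#' @export
tidy.bin_model_selection <- function(x, ...) {
  arrange(x$table, .data$AIC)
}

#' @rdname tidy.bin_model_selection
#' @export
glance.bin_model_selection <- function(x, ...) {
  glance(x$best)
}
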