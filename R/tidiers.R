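# broom-style accessors for fitted objects

#' Tidy a fitted direct-interaction model
#'
#' @param x A `dia_fit` from [fit_params()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.dia_fit <- function(x, ...) {
  p <- x$params
  out <- tibble(
    term = c("alpha", "alpha2", "beta", "beta2", "tau"),
    estimate = c(p$alpha, p$alpha2, p$beta, p$beta2, p$tau)
  )
  if (!is.null(p$tau_extra)) {
    out <- bind_rows(out, tibble(term = paste0("tau_", names(p$tau_extra)),
                                 estimate = unname(p$tau_extra)))
  }
  if (!is.na(p$x)) {
    out <- bind_rows(out, tibble(term = "x", estimate = p$x))
  }
  out
}

#' @rdname tidy.dia_fit
#' @export
glance.dia_fit <- function(x, ...) {
  tibble(n = x$n, mae = x$mae, rss = x$rss,
         model_kind = x$params$model_kind,
         vdw_form = x$params$vdw_form,
         property = x$params$property)
}

#' @rdname tidy.dia_fit
#' @export
augment.dia_fit <- function(x, ...) {
  mutate(x$data, .fitted = x$fitted, .resid = x$data$dg_exptl - x$fitted)
}

#' Tidy a leave-one-out cross-validation result
#'
#' @param x A `dia_cv` from [loo_cv()].
#' @param ... Unused.
#' @return `tidy()`: the per-complex held-out predictions; `glance()`: a
#'   one-row summary with `mae`, `pearson_r`, `n` and the full-data
#'   parameters' model tags.
#' @export
tidy.dia_cv <- function(x, ...) x$predictions

#' @rdname tidy.dia_cv
#' @export
glance.dia_cv <- function(x, ...) {
  tibble(n = nrow(x$predictions), mae = x$mae, pearson_r = x$pearson_r,
         model_kind = x$fit$params$model_kind,
         vdw_form = x$fit$params$vdw_form,
         property = x$fit$params$property)
}
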