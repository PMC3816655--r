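#' Binding free-energy model parameters
#'
#' The direct-interaction models are linear in their parameters:
#' \describe{
#'   \item{`simple`}{`dG = alpha * sum_vdw + beta * sum_ele` (the
#'     residue-independent reduction shared by solvent-free LIE and
#'     uniform-weight COMBINE).}
#'   \item{`diav`}{adds fluctuation terms and one entropy descriptor:
#'     `dG = alpha * sum_vdw + alpha2 * sum_fluct_vdw + beta * sum_ele +
#'     beta2 * sum_fluct_ele + tau * S_x`.}
#'   \item{`dias`}{as `diav` with the effective-dielectric-scaled
#'     electrostatics `sum_ele_scaled` replacing `sum_ele`; carries the
#'     dielectric regularizer `x`.}
#'   \item{`generalized`}{as `dias`/`diav` with one `tau_x` weight per
#'     selected entropy property.}
#' }
#'
#' @param alpha,beta Weights on the mean vdW and electrostatic sums.
#' @param alpha2,beta2 Weights on the summed per-residue fluctuations.
#' @param tau Weight on the entropy descriptor `S_x`.
#' @param x Dielectric regularizer (required > 0 for `dias`).
#' @param vdw_form Lennard-Jones form tag, see [vdw_forms()].
#' @param property Entropy property for `tau` (`"ASA"`, `"DIH"`, `"VDW"`,
#'   `"ELE"`).
#' @param model_kind One of `"simple"`, `"diav"`, `"dias"`, `"generalized"`.
#' @param tau_extra Named numeric vector of per-property weights for the
#'   generalized model (names among the four properties).
#' @return An object of class `dia_params`.
#' @examples
#' dia_params(alpha = 0.0307, beta = 0.0118, tau = -2.4312e-4,
#'            alpha2 = 0.01, beta2 = -0.00312, x = 0.6,
#'            vdw_form = "8-4", model_kind = "dias")
#' @export
dia_params <- function(alpha = 0, alpha2 = 0, beta = 0, beta2 = 0, tau = 0,
                       x = NA_real_, vdw_form = "8-4", property = "ASA",
                       model_kind = c("diav", "simple", "dias", "generalized"),
                       tau_extra = NULL) {
  model_kind <- match.arg(model_kind)
  vdw_form <- match.arg(vdw_form, vdw_forms())
  property <- match.arg(property, c("ASA", "DIH", "VDW", "ELE"))
  if (model_kind == "simple" && any(c(alpha2, beta2, tau) != 0)) {
    abort("The simple model has only alpha and beta; set alpha2, beta2, tau to 0.",
          class = "diascore_invalid_parameter")
  }
  if (model_kind == "dias" && (is.na(x) || x <= 0)) {
    abort("The dias model requires a positive dielectric regularizer `x`.",
          class = "diascore_invalid_parameter")
  }
  vals <- c(alpha, alpha2, beta, beta2, tau, unname(tau_extra %||% 0))
  if (any(!is.finite(vals))) {
    abort("Model parameters must be finite.", class = "diascore_invalid_parameter")
  }
  structure(
    list(alpha = alpha, alpha2 = alpha2, beta = beta, beta2 = beta2,
         tau = tau, x = x, vdw_form = vdw_form, property = property,
         model_kind = model_kind, tau_extra = tau_extra),
    class = "dia_params"
  )
}

#' @export
print.dia_params <- function(x, ...) {
  cat("<dia_params> ", x$model_kind, " model, LJ ", x$vdw_form,
      ", S_", x$property, "\n", sep = "")
  cat(sprintf("  alpha=%.6g alpha2=%.6g beta=%.6g beta2=%.6g tau=%.6g",
              x$alpha, x$alpha2, x$beta, x$beta2, x$tau))
  if (!is.na(x$x)) cat(sprintf(" x=%.3g", x$x))
  cat("\n")
  if (!is.null(x$tau_extra)) {
    cat("  tau_extra:", paste(names(x$tau_extra),
                              signif(x$tau_extra, 4), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# column names of the linear design for a model kind / property choice
design_columns <- function(model_kind, property, tau_extra_props = NULL) {
  ele_col <- if (model_kind %in% c("dias")) "sum_ele_scaled" else "sum_ele"
  cols <- switch(model_kind,
    simple = c(alpha = "sum_vdw", beta = "sum_ele"),
    diav = c(alpha = "sum_vdw", alpha2 = "sum_fluct_vdw",
             beta = "sum_ele", beta2 = "sum_fluct_ele",
             tau = paste0("S_", property)),
    dias = c(alpha = "sum_vdw", alpha2 = "sum_fluct_vdw",
             beta = "sum_ele_scaled", beta2 = "sum_fluct_ele",
             tau = paste0("S_", property)),
    generalized = {
      props <- tau_extra_props %||% character()
      base <- c(alpha = "sum_vdw", alpha2 = "sum_fluct_vdw",
                beta = ele_col, beta2 = "sum_fluct_ele",
                tau = paste0("S_", property))
      extra <- setNames(paste0("S_", props), paste0("tau_", props))
      c(base, extra)
    }
  )
  cols
}

# design matrix (rows = complexes) for the linear parameters
design_matrix <- function(data, model_kind, property, tau_extra_props = NULL) {
  cols <- design_columns(model_kind, property, tau_extra_props)
  missing <- setdiff(unname(cols), names(data))
  if (length(missing)) {
    abort(paste0("Feature columns missing for the ", model_kind, " model: ",
                 paste(missing, collapse = ", ")),
          class = "diascore_feature_error")
  }
  X <- as.matrix(data[, unname(cols), drop = FALSE])
  if (any(!is.finite(X))) {
    abort("Feature values must be finite for fitting/prediction.",
          class = "diascore_feature_error")
  }
  colnames(X) <- names(cols)
  X
}

#' Predict binding free energies
#'
#' Evaluates the linear direct-interaction model on a feature table.
#'
#' @param features Tibble of complex features (see [extract_features()] /
#'   [make_feature_dataset()]).
#' @param params A [dia_params()] object.
#' @return Numeric vector of predicted binding free energies, kcal/mol
#'   (one per row of `features`).
#' @export
predict_dg <- function(features, params) {
  stopifnot(inherits(params, "dia_params"))
  X <- design_matrix(features, params$model_kind, params$property,
                     names(params$tau_extra))
  theta <- c(alpha = params$alpha, alpha2 = params$alpha2,
             beta = params$beta, beta2 = params$beta2, tau = params$tau,
             params$tau_extra)
  as.numeric(X %*% theta[colnames(X)])
}

#' Fit model parameters by ordinary least squares
#'
#' Minimizes the sum of squared deviations between predicted and
#' experimental binding free energies over the model's linear parameters
#' (no intercept: the models are pure linear combinations of interaction
#' features). For the `dias` model the dielectric regularizer `x` is not
#' linear: when a `features_for_x` callback is supplied, `x` is chosen from
#' `x_grid` by minimum residual sum of squares, re-deriving the scaled
#' electrostatics for each candidate; otherwise the `sum_ele_scaled` column
#' is used as given and `x` is recorded from the `x` argument.
#'
#' @param data Feature tibble with a `dg_exptl` column.
#' @param model_kind,vdw_form,property,tau_extra See [dia_params()];
#'   `tau_extra` here is a character vector of extra generalized-model
#'   properties.
#' @param x Dielectric regularizer to record when no grid search runs.
#' @param x_grid Candidate `x` values for the dias grid search.
#' @param features_for_x Function `function(x)` returning the feature
#'   tibble with `sum_ele_scaled` recomputed at that regularizer value.
#' @return A `dia_fit` object: fitted [dia_params()] plus training
#'   residual statistics. Supports [tidy()], [glance()], [augment()].
#' @export
fit_params <- function(data, model_kind = c("diav", "simple", "dias",
                                            "generalized"),
                       vdw_form = "8-4", property = "ASA",
                       x = 0.6, x_grid = seq(0.1, 2.0, by = 0.1),
                       features_for_x = NULL, tau_extra = NULL) {
  model_kind <- match.arg(model_kind)
  if (!"dg_exptl" %in% names(data) || any(!is.finite(data$dg_exptl))) {
    abort("`data` must carry finite `dg_exptl` values for fitting.",
          class = "diascore_feature_error")
  }
  if (model_kind == "dias" && !is.null(features_for_x)) {
    fits <- lapply(x_grid, function(xv) {
      d <- features_for_x(xv)
      d$dg_exptl <- data$dg_exptl
      fit_linear(d, model_kind, vdw_form, property, xv, tau_extra)
    })
    rss <- vapply(fits, function(f) f$rss, 0)
    fits[[which.min(rss)]]
  } else {
    fit_linear(data, model_kind, vdw_form, property,
               if (model_kind == "dias") x else NA_real_, tau_extra)
  }
}

# OLS on the linear parameters at fixed x
fit_linear <- function(data, model_kind, vdw_form, property, x, tau_extra) {
  X <- design_matrix(data, model_kind, property, tau_extra)
  y <- data$dg_exptl
  if (nrow(X) <= ncol(X)) {
    abort(paste0("Dataset of size ", nrow(X), " cannot determine ",
                 ncol(X), " parameters."),
          class = "diascore_underdetermined_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Collinear feature columns: ", paste(dep, collapse = ", ")),
          class = "diascore_collinearity_error")
  }
  theta <- qr.coef(qrX, y)
  resid <- y - as.numeric(X %*% theta)
  extra <- theta[setdiff(names(theta),
                         c("alpha", "alpha2", "beta", "beta2", "tau"))]
  p <- dia_params(
    alpha = theta[["alpha"]],
    alpha2 = if ("alpha2" %in% names(theta)) theta[["alpha2"]] else 0,
    beta = theta[["beta"]],
    beta2 = if ("beta2" %in% names(theta)) theta[["beta2"]] else 0,
    tau = if ("tau" %in% names(theta)) theta[["tau"]] else 0,
    x = x, vdw_form = vdw_form, property = property,
    model_kind = model_kind,
    tau_extra = if (length(extra))
      setNames(as.numeric(extra), sub("^tau_", "", names(extra)))
  )
  structure(
    list(params = p, rss = sum(resid^2),
         mae = mean(abs(resid)),
         n = nrow(X),
         data = as_tibble(data),
         fitted = y - resid),
    class = "dia_fit"
  )
}

#' @export
print.dia_fit <- function(x, ...) {
  cat("<dia_fit> n =", x$n, " training MAE =", signif(x$mae, 4),
      "kcal/mol\n")
  print(x$params)
  invisible(x)
}

#' Error metrics between predicted and experimental binding free energies
#'
#' @param pred,expt Numeric vectors of equal length (>= 2), kcal/mol.
#' @return One-row tibble with `mae` (mean absolute error, kcal/mol) and
#'   `pearson_r` (sample Pearson correlation).
#' @examples
#' dg_metrics(c(-8, -10.5), c(-8.3, -10))
#' @export
dg_metrics <- function(pred, expt) {
  if (length(pred) != length(expt) || length(pred) < 2) {
    abort("`pred` and `expt` must have equal length >= 2.",
          class = "diascore_shape_error")
  }
  if (sd(pred) == 0 || sd(expt) == 0) {
    abort("Pearson correlation is undefined for zero-variance input.",
          class = "diascore_undefined_correlation")
  }
  tibble(mae = mean(abs(pred - expt)), pearson_r = cor(pred, expt))
}

#' Leave-one-out cross-validation of a binding free-energy model
#'
#' Each complex in turn is held out, the model is refitted on the remaining
#' n-1 complexes, and the held-out binding free energy is predicted. The
#' reported parameter set is the full-data fit. For the `dias` model with a
#' `features_for_x` callback, the regularizer `x` is fitted once on the full
#' data and held fixed across folds (set `refit_x = TRUE` to re-search per
#' fold).
#'
#' @inheritParams fit_params
#' @param refit_x Re-run the dias `x` grid search inside every fold.
#' @return A `dia_cv` object: `predictions` tibble (`complex_id`,
#'   `dg_exptl`, `dg_pred`), `mae`, `pearson_r`, and the full-data `fit`.
#'   Supports [tidy()] and [glance()].
#' @export
loo_cv <- function(data, model_kind = c("diav", "simple", "dias",
                                        "generalized"),
                   vdw_form = "8-4", property = "ASA",
                   x = 0.6, x_grid = seq(0.1, 2.0, by = 0.1),
                   features_for_x = NULL, tau_extra = NULL,
                   refit_x = FALSE) {
  model_kind <- match.arg(model_kind)
  n <- nrow(data)
  if (n < 3) {
    abort("Leave-one-out cross-validation needs at least 3 complexes.",
          class = "diascore_underdetermined_error")
  }
  full <- fit_params(data, model_kind, vdw_form, property, x, x_grid,
                     features_for_x, tau_extra)
  x_full <- full$params$x
  if (model_kind == "dias" && !is.null(features_for_x) && !refit_x) {
    scaled <- features_for_x(x_full)
    scaled$dg_exptl <- data$dg_exptl
    data <- scaled
  }
  preds <- vapply(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    f <- tryCatch(
      if (refit_x && model_kind == "dias" && !is.null(features_for_x)) {
        fit_params(train, model_kind, vdw_form, property, x_full, x_grid,
                   function(xv) features_for_x(xv)[-i, , drop = FALSE])
      } else {
        fit_params(train, model_kind, vdw_form, property, x_full, x_grid,
                   NULL, tau_extra)
      },
      error = function(e) {
        abort(paste0("Fold for held-out complex '",
                     data$complex_id[i] %||% i, "' failed: ",
                     conditionMessage(e)),
              class = "diascore_cv_error", parent = e)
      }
    )
    predict_dg(data[i, , drop = FALSE], f$params)
  }, 0)
  m <- dg_metrics(preds, data$dg_exptl)
  structure(
    list(
      predictions = tibble(
        complex_id = data$complex_id %||% as.character(seq_len(n)),
        dg_exptl = data$dg_exptl,
        dg_pred = preds
      ),
      mae = m$mae, pearson_r = m$pearson_r,
      fit = full
    ),
    class = "dia_cv"
  )
}

#' @export
print.dia_cv <- function(x, ...) {
  cat("<dia_cv> leave-one-out over", nrow(x$predictions), "complexes\n")
  cat(sprintf("  MAE = %.3f kcal/mol, Pearson R = %.3f\n", x$mae, x$pearson_r))
  print(x$fit$params)
  invisible(x)
}

#' Rank candidate binding poses by predicted binding free energy
#'
#' @param pose_features Feature tibble with one row per candidate pose of a
#'   single complex.
#' @param params A [dia_params()] object.
#' @return Tibble sorted by ascending predicted binding free energy (best,
#'   i.e. most negative, first): `pose` (input row number), `dg_pred`,
#'   `rank`. Ties keep input order.
#' @export
rank_poses <- function(pose_features, params) {
  if (nrow(pose_features) < 1) {
    abort("At least one pose is required.", class = "diascore_shape_error")
  }
  dg <- predict_dg(pose_features, params)
  ord <- order(dg)  # stable for ties
  tibble(pose = ord, dg_pred = dg[ord], rank = seq_along(ord))
}

#' Docking success rates at RMSD thresholds
#'
#' Fraction of complexes whose best-ranked pose lies within each RMSD
#' threshold of the reference ligand geometry (a pose is counted when
#' `rmsd < threshold`).
#'
#' @param best_pose_rmsd Numeric vector of best-pose RMSD values, Angstrom.
#' @param thresholds Numeric vector of thresholds, Angstrom (default the
#'   conventional 1, 2, 3).
#' @return Tibble with `threshold` and `success_rate` columns; rates are
#'   non-decreasing in the threshold.
#' @examples
#' success_rates(c(0.5, 1.5, 2.5, 3.5), thresholds = c(1, 2, 3))
#' @export
success_rates <- function(best_pose_rmsd, thresholds = c(1, 2, 3)) {
  if (!length(best_pose_rmsd)) {
    abort("`best_pose_rmsd` must be non-empty.", class = "diascore_shape_error")
  }
  if (any(best_pose_rmsd < 0) || any(thresholds <= 0)) {
    abort("RMSD values must be >= 0 and thresholds > 0.",
          class = "diascore_invalid_parameter")
  }
  tibble(
    threshold = thresholds,
    success_rate = vapply(thresholds,
                          function(t) mean(best_pose_rmsd < t), 0)
  )
}
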