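test_that("prediction is the stated linear combination of features", {
  d <- make_feature_dataset(seed = 41, noise_sd = 0, n = 6)
  p <- reference_params()
  want <- p$alpha * d$sum_vdw + p$alpha2 * d$sum_fluct_vdw +
    p$beta * d$sum_ele + p$beta2 * d$sum_fluct_ele + p$tau * d$S_ASA
  expect_equal(predict_dg(d, p), want)
  # all-zero parameters predict zero; alpha-only projects sum_vdw
  expect_equal(predict_dg(d, dia_params(model_kind = "simple")), rep(0, 6))
  expect_equal(predict_dg(d, dia_params(alpha = 1, model_kind = "simple")),
               d$sum_vdw)
  # linearity in the parameter vector
  p2 <- dia_params(alpha = 3 * p$alpha, alpha2 = 3 * p$alpha2,
                   beta = 3 * p$beta, beta2 = 3 * p$beta2, tau = 3 * p$tau,
                   vdw_form = "8-4", model_kind = "diav")
  expect_equal(predict_dg(d, p2), 3 * predict_dg(d, p))
})

test_that("dias prediction swaps in the dielectric-scaled electrostatics", {
  d <- make_feature_dataset(seed = 42, noise_sd = 0, n = 6)
  p <- reference_params("dias")
  want <- p$alpha * d$sum_vdw + p$alpha2 * d$sum_fluct_vdw +
    p$beta * d$sum_ele_scaled + p$beta2 * d$sum_fluct_ele + p$tau * d$S_ASA
  expect_equal(predict_dg(d, p), want)
})

test_that("missing feature columns raise a feature error", {
  d <- make_feature_dataset(seed = 43, n = 6)
  expect_error(predict_dg(dplyr::select(d, -sum_ele_scaled),
                          reference_params("dias")),
               class = "diascore_feature_error")
})

test_that("parameter constraints are enforced at construction", {
  expect_error(dia_params(tau = 1, model_kind = "simple"),
               class = "diascore_invalid_parameter")
  expect_error(dia_params(model_kind = "dias", x = NA_real_),
               class = "diascore_invalid_parameter")
  expect_error(dia_params(alpha = Inf), class = "diascore_invalid_parameter")
})

test_that("least squares exactly recovers noise-free generating parameters", {
  for (mk in c("simple", "diav", "dias")) {
    truth <- if (mk == "simple") {
      dia_params(alpha = 0.05, beta = 0.0125, model_kind = "simple",
                 vdw_form = "8-4")
    } else {
      reference_params(mk)
    }
    d <- make_feature_dataset(seed = 44, true_params = truth, noise_sd = 0)
    fit <- fit_params(d, mk, x = 0.6)
    expect_equal(fit$params$alpha, truth$alpha, tolerance = 1e-6)
    expect_equal(fit$params$beta, truth$beta, tolerance = 1e-6)
    expect_equal(fit$params$alpha2, truth$alpha2, tolerance = 1e-6)
    expect_equal(fit$params$beta2, truth$beta2, tolerance = 1e-6)
    expect_equal(fit$params$tau, truth$tau, tolerance = 1e-6)
    expect_lt(fit$mae, 1e-8)
  }
})

test_that("the generalized model adds per-property entropy weights", {
  truth <- dia_params(alpha = 0.03, alpha2 = 0.01, beta = 0.01,
                      beta2 = -0.002, tau = -2e-4, model_kind = "diav",
                      vdw_form = "8-4", property = "ASA")
  d <- make_feature_dataset(seed = 45, true_params = truth, noise_sd = 0)
  # add a DIH contribution on top of the ASA term
  d$dg_exptl <- d$dg_exptl - 0.05 * d$S_DIH
  fit <- fit_params(d, "generalized", tau_extra = "DIH")
  expect_equal(fit$params$tau, truth$tau, tolerance = 1e-6)
  expect_equal(unname(fit$params$tau_extra["DIH"]), -0.05, tolerance = 1e-6)
  expect_lt(fit$mae, 1e-8)
})

test_that("fitting is invariant under dataset duplication and rejects bad designs", {
  d <- make_feature_dataset(seed = 46, noise_sd = 0.5)
  f1 <- fit_params(d, "diav")
  f2 <- fit_params(dplyr::bind_rows(d, d), "diav")
  expect_equal(tidy(f1), tidy(f2), tolerance = 1e-12)
  expect_error(fit_params(d[1:4, ], "diav"),
               class = "diascore_underdetermined_error")
  d2 <- d
  d2$sum_fluct_vdw <- 2 * d2$sum_vdw
  err <- tryCatch(fit_params(d2, "diav"), condition = identity)
  expect_s3_class(err, "diascore_collinearity_error")
  expect_match(conditionMessage(err), "sum_fluct_vdw|alpha2")
})

test_that("least-squares fit beats a random-search oracle on training RSS", {
  d <- make_feature_dataset(seed = 47, noise_sd = 1)
  fit <- fit_params(d, "diav")
  withr::with_seed(48, {
    for (k in 1:50) {
      cand <- dia_params(
        alpha = fit$params$alpha * runif(1, 0.5, 1.5),
        alpha2 = fit$params$alpha2 * runif(1, 0.5, 1.5),
        beta = fit$params$beta * runif(1, 0.5, 1.5),
        beta2 = fit$params$beta2 * runif(1, 0.5, 1.5),
        tau = fit$params$tau * runif(1, 0.5, 1.5),
        vdw_form = "8-4", model_kind = "diav")
      rss <- sum((predict_dg(d, cand) - d$dg_exptl)^2)
      expect_gte(rss, fit$rss - 1e-9)
    }
  })
})

test_that("metrics match hand values and guard degenerate input", {
  m <- dg_metrics(c(-1, -2, -3), c(-1, -2, -3))
  expect_equal(m$mae, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(dg_metrics(c(1, 2, 3), c(-1, -2, -3))$pearson_r, -1)
  expect_error(dg_metrics(1:3, 1:2), class = "diascore_shape_error")
  expect_error(dg_metrics(c(1, 1), c(1, 2)),
               class = "diascore_undefined_correlation")
})

test_that("leave-one-out is exact on noise-free data and order invariant", {
  d <- make_feature_dataset(seed = 49, noise_sd = 0)
  cv <- loo_cv(d, "diav")
  expect_lt(cv$mae, 1e-8)
  expect_gt(cv$pearson_r, 1 - 1e-9)
  expect_equal(nrow(cv$predictions), nrow(d))
  perm <- withr::with_seed(50, sample(nrow(d)))
  cv2 <- loo_cv(d[perm, ], "diav")
  expect_equal(cv2$mae, cv$mae, tolerance = 1e-10)
  expect_equal(cv2$pearson_r, cv$pearson_r, tolerance = 1e-10)
  expect_equal(dplyr::arrange(cv2$predictions, complex_id),
               dplyr::arrange(cv$predictions, complex_id), tolerance = 1e-9)
})

test_that("held-out error brackets the injected noise level", {
  sigma <- 1.0
  maes <- vapply(1:20, function(s) {
    d <- make_feature_dataset(seed = 100 + s, n = 10, noise_sd = sigma)
    loo_cv(d, "simple")$mae
  }, 0)
  expect_gt(mean(maes), 0.5 * sigma)
  expect_lt(mean(maes), 2 * sigma)
})

test_that("held-out error is no better than the training error on average", {
  diffs <- vapply(1:20, function(s) {
    d <- make_feature_dataset(seed = 200 + s, noise_sd = 1)
    loo_cv(d, "diav")$mae - fit_params(d, "diav")$mae
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("pose ranking sorts by predicted binding free energy, stably", {
  d <- make_feature_dataset(seed = 51, n = 5, noise_sd = 0)
  p <- reference_params()
  r <- rank_poses(d, p)
  dg <- predict_dg(d, p)
  expect_equal(r$pose, order(dg))
  expect_equal(r$dg_pred, sort(dg))
  expect_equal(r$rank, 1:5)
  # single pose and exact ties
  expect_equal(rank_poses(d[3, ], p)$pose, 1)
  tie <- dplyr::bind_rows(d[2, ], d[2, ], d[1, ])
  rt <- rank_poses(tie, p)
  best_two <- rt$pose[rt$dg_pred == min(rt$dg_pred)]
  expect_true(identical(sort(best_two), which(predict_dg(tie, p) ==
                                                min(predict_dg(tie, p)))))
})

test_that("success rates reproduce counting fractions and monotonicity", {
  r <- success_rates(c(0.5, 1.5, 2.5, 3.5), thresholds = c(1, 2, 3))
  expect_equal(r$success_rate, c(0.25, 0.5, 0.75))
  expect_equal(success_rates(rep(0, 4))$success_rate, rep(1, 3))
  withr::with_seed(52, rmsd <- runif(30, 0, 5))
  th <- seq(0.5, 4.5, by = 0.5)
  expect_true(!is.unsorted(success_rates(rmsd, th)$success_rate))
  expect_error(success_rates(numeric(0)), class = "diascore_shape_error")
  expect_error(success_rates(c(-1, 2)), class = "diascore_invalid_parameter")
})

test_that("tidy, glance and augment expose the fit coherently", {
  d <- make_feature_dataset(seed = 53, noise_sd = 0.3)
  fit <- fit_params(d, "diav")
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "alpha2", "beta", "beta2", "tau"))
  g <- glance(fit)
  expect_equal(g$n, nrow(d))
  expect_equal(g$mae, fit$mae)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, d$dg_exptl)
  cv <- loo_cv(d, "diav")
  expect_equal(nrow(tidy(cv)), nrow(d))
  expect_equal(glance(cv)$pearson_r, cv$pearson_r)
})

test_that("cv and profile plots build without error", {
  d <- make_feature_dataset(seed = 54, noise_sd = 0.5)
  cv <- loo_cv(d, "diav")
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  toy <- make_toy_complex(seed = 9, n_residues = 4, atoms_per_residue = 3,
                          n_ligand_atoms = 4, n_frames = 3)
  prof <- ensemble_interaction_profile(toy$frames, "8-4")
  expect_s3_class(plot_interaction_profile(prof), "ggplot")
  expect_s3_class(plot_success_rates(success_rates(c(0.5, 2.5))), "ggplot")
})
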