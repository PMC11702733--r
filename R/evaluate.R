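#' Run a scenario x model grid over simulation replicates
#'
#' For each replicate of `scenario`, simulates a cohort, builds the analysis
#' frame (homogeneous-weighting PRS, global/local ePRS computed from the
#' generative frequency panel and the analyst-facing ancestry information,
#' the observed PC-like covariate, global proportions, and genotype PCs when
#' a PC model is requested), and fits the requested working models.
#' Association models always receive the homogeneous-weighting PRS, so
#' heterogeneous-weighting scenarios probe model misspecification.
#'
#' Replicate substreams are derived from `(scenario$seed, replicate index)`,
#' so results do not depend on execution order and any single replicate can
#' be reproduced in isolation. Replicate-level fit failures are recorded and
#' excluded; more than 1% failures aborts with diagnostics.
#'
#' @param scenario A [sim_scenario()].
#' @param models Character vector of working-model labels (see
#'   [fit_working_model()]).
#' @param reps Number of replicates (defaults to `scenario$reps`).
#' @param family Outcome family passed to the fits.
#' @return A tibble of class `eprs_eval`, one row per replicate x model x
#'   coefficient: `replicate`, `model_label`, `term`, `estimate`,
#'   `std.error`, `is_prs_term`, `n_used`. Attributes: `truth` (named
#'   generative parameters), `scenario`, `failures`.
#' @export
run_scenario <- function(scenario, models = c("M1_none", "M2_gePRS"),
                         reps = scenario$reps,
                         family = c("linear", "logistic")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  family <- match.arg(family)
  models <- match.arg(models, MODEL_LABELS, several.ok = TRUE)
  fixed <- scenario_fixed_inputs(scenario)
  need_pcs <- any(models %in% c("M6_PC10", "M7_PC20", "PCadjPRS"))
  n_pcs <- if ("M7_PC20" %in% models) 20L else 10L
  need_local <- "M3_lePRS" %in% models

  failures <- list()
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      sim <- simulate_replicate(scenario, r, fixed)
      data <- data.frame(y = sim$outcome, prs = sim$prs)
      ge <- global_eprs(fixed$weights, fixed$panel, sim$gam_obs)
      data$eprs_global <- ge$eprs
      if (need_local) {
        le <- local_eprs(fixed$weights, fixed$panel, sim$lat_obs)
        data$eprs_local <- le$eprs
      }
      if (scenario$confounder != "none") data$conf_pc_star <- sim$conf
      if ("M5_gaProp" %in% models) {
        ga <- gam_matrix(sim$gam_obs)
        colnames(ga) <- paste0("ga_", colnames(ga))
        data <- cbind(data, ga)
      }
      if (need_pcs) {
        pcs <- compute_pcs(sim$genotypes, n_pcs)
        data <- cbind(data, pcs$scores)
      }
      purrr::map(models, function(lab) {
        fit <- fit_working_model(data, lab, family = family)
        dplyr::mutate(fit$coef,
                      replicate = r, model_label = lab,
                      is_prs_term = .data$term == fit$prs_term,
                      n_used = fit$n_used, .before = 1)
      }) |> dplyr::bind_rows()
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(replicate = r,
                                               message = conditionMessage(res))
    } else {
      rows[[r]] <- res
    }
  }
  if (length(failures) > reps * 0.01) {
    msgs <- vapply(head(failures, 5), function(f)
      sprintf("replicate %d: %s", f$replicate, f$message), character(1))
    abort(paste0(sprintf("%d/%d replicates failed; first failures:\n",
                         length(failures), reps),
                 paste(msgs, collapse = "\n")))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- c(beta0 = scenario$beta0, beta1 = scenario$beta1,
                          gamma = scenario$gamma)
  attr(out, "scenario") <- scenario
  attr(out, "failures") <- failures
  class(out) <- c("eprs_eval", class(out))
  out
}

#' Summarize estimator performance over replicates
#'
#' Reduces per-replicate PRS-coefficient estimates to bias, empirical
#' variance, and MSE per model, with a Monte-Carlo standard error for the
#' MSE. Moments use the population denominator (`mean((x - mean(x))^2)`), so
#' `mse = bias^2 + empirical_variance` holds as an identity.
#'
#' @param fits An `eprs_eval` tibble from [run_scenario()], or any tibble
#'   with columns `replicate`, `model_label`, `estimate`, `is_prs_term`.
#' @param truth True generative PRS effect; defaults to the `truth`
#'   attribute recorded by [run_scenario()].
#' @return A tibble, one row per model: `model_label`, `reps_used`,
#'   `mean_beta1_hat`, `bias`, `empirical_variance`, `mse`, `mse_mc_se`.
#' @export
summarize_evaluation <- function(fits, truth = NULL) {
  if (is.null(truth)) {
    tr <- attr(fits, "truth")
    if (is.null(tr)) abort("supply `truth`: fits carry no truth attribute")
    truth <- unname(tr["beta1"])
  }
  b <- dplyr::filter(fits, .data$is_prs_term)
  if (nrow(b) == 0) abort("no PRS-term estimates to summarize")
  if (min(table(b$model_label)) < 2) {
    abort("need at least 2 replicates per model")
  }
  b |>
    dplyr::group_by(.data$model_label) |>
    dplyr::summarise(
      reps_used = dplyr::n(),
      mean_beta1_hat = mean(.data$estimate),
      bias = mean(.data$estimate) - truth,
      empirical_variance = mean((.data$estimate - mean(.data$estimate))^2),
      mse = mean((.data$estimate - truth)^2),
      mse_mc_se = stats::sd((.data$estimate - truth)^2) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Sweep the confounder effect size
#'
#' Re-runs a scenario across a grid of confounder effect sizes `gamma` and
#' summarizes each run, reproducing the design of MSE-versus-gamma
#' analyses: confounding bias (hence MSE) grows with `gamma` for unadjusted
#' models, far more slowly under ePRS adjustment.
#'
#' @param scenario Base [sim_scenario()]; its `gamma` is replaced by each
#'   grid value (same seed, so the scenario-level inputs are shared).
#' @param gammas Numeric vector of confounder effect sizes.
#' @param models Working-model labels.
#' @param reps Replicates per gamma (defaults to `scenario$reps`).
#' @return A tibble: one row per gamma x model with the
#'   [summarize_evaluation()] columns plus `gamma`.
#' @export
gamma_sweep <- function(scenario, gammas, models = c("M1_none", "M2_gePRS"),
                        reps = scenario$reps) {
  if (length(gammas) == 0) abort("`gammas` must be nonempty")
  purrr::map(gammas, function(g) {
    sc <- scenario
    sc$gamma <- g
    fits <- run_scenario(sc, models, reps = reps)
    dplyr::mutate(summarize_evaluation(fits), gamma = g, .before = 1)
  }) |> dplyr::bind_rows()
}
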