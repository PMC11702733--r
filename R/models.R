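MODEL_LABELS <- c("M1_none", "M2_gePRS", "M3_lePRS", "M4_conf_pc_star",
                  "M5_gaProp", "M6_PC10", "M7_PC20", "PCadjPRS")

Z975 <- 1.959964

#' Principal components of the PRS genotype matrix
#'
#' Computes PC scores from the singular value decomposition of the
#' column-centered, column-standardized (sample SD) dosage matrix — the
#' same genetic data used to compute the PRS, as in the PC-adjusted working
#' models. Zero-variance columns are dropped with a warning. Signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param genotypes Individuals-by-variants dosage matrix.
#' @param n_components Number of components to return (<= min(n, p)).
#' @param scale. Standardize columns by their sample SD (default `TRUE`);
#'   set `FALSE` to use covariance-based PCs.
#' @return An object of class `prs_pcs`: list with `scores` (n x J matrix,
#'   columns `PC1..PCJ`, ordered by descending singular value), `rotation`,
#'   `sdev`, and `dropped` (ids of zero-variance columns).
#' @export
compute_pcs <- function(genotypes, n_components, scale. = TRUE) {
  validate_genotypes(genotypes)
  x <- genotypes
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0] %||% character(0)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance column(s) before PCA", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (n_components > min(dim(x))) {
    abort("n_components exceeds min(n, p) after dropping constant columns")
  }
  x <- scale(x, center = TRUE, scale = if (scale.) sds else FALSE)
  sv <- svd(x, nu = n_components, nv = n_components)
  rot <- sv$v
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(n_components), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(sv$u, 2, flip * sv$d[seq_len(n_components)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(genotypes)
  colnames(rot) <- colnames(scores)
  rownames(rot) <- colnames(x)
  structure(list(scores = scores, rotation = rot,
                 sdev = sv$d / sqrt(nrow(x) - 1), dropped = dropped),
            class = "prs_pcs")
}

#' @export
print.prs_pcs <- function(x, ...) {
  cat(sprintf("<PRS genotype PCs: %d components on %d individuals>\n",
              ncol(x$scores), nrow(x$scores)))
  invisible(x)
}

#' Regress PCs out of a PRS
#'
#' Returns the residuals of the linear regression of the PRS on PC scores
#' (intercept included) — the "ancestry-adjusted PRS" comparator. The
#' residuals are orthogonal to every PC column and have SD no larger than
#' the raw PRS; that shrinkage is why per-SD effect sizes from the adjusted
#' score can differ from the raw score's.
#'
#' @param prs Numeric PRS vector.
#' @param pcs A `prs_pcs` object or a bare score matrix.
#' @return Numeric vector of residuals.
#' @export
pc_adjust_prs <- function(prs, pcs) {
  scores <- if (inherits(pcs, "prs_pcs")) pcs$scores else as.matrix(pcs)
  stopifnot(length(prs) == nrow(scores))
  stats::lm.fit(cbind(1, scores), prs)$residuals
}

#' Scale a vector to unit sample SD
#'
#' @param x Numeric vector with positive sample SD (denominator n - 1).
#' @return `x / sd(x)`.
#' @export
standardize_per_sd <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a vector with zero sample SD",
          class = "eprs_validation_error")
  }
  x / s
}

# Assemble the design columns for a working model from an analysis frame.
model_design <- function(data, label) {
  need <- function(cols) {
    missing <- setdiff(cols, names(data))
    if (length(missing)) {
      abort(sprintf("model %s needs column(s): %s", label,
                    paste(missing, collapse = ", ")))
    }
  }
  pc_cols <- function(j) paste0("PC", seq_len(j))
  switch(
    label,
    M1_none = {
      need("prs"); data.frame(prs = data$prs)
    },
    M2_gePRS = {
      need(c("prs", "eprs_global"))
      data.frame(rprs = data$prs - data$eprs_global, eprs = data$eprs_global)
    },
    M3_lePRS = {
      need(c("prs", "eprs_local"))
      data.frame(rprs = data$prs - data$eprs_local, eprs = data$eprs_local)
    },
    M4_conf_pc_star = {
      need(c("prs", "conf_pc_star"))
      data.frame(prs = data$prs, conf_pc_star = data$conf_pc_star)
    },
    M5_gaProp = {
      need("prs")
      ga <- grep("^ga_", names(data), value = TRUE)
      if (length(ga) < 2) {
        abort("model M5_gaProp needs global ancestry columns named ga_<ancestry>")
      }
      # drop the last ancestry column: proportions sum to 1 and would be
      # collinear with the intercept
      cbind(data.frame(prs = data$prs), data[ga[-length(ga)]])
    },
    M6_PC10 = {
      need(c("prs", pc_cols(10)))
      cbind(data.frame(prs = data$prs), data[pc_cols(10)])
    },
    M7_PC20 = {
      need(c("prs", pc_cols(20)))
      cbind(data.frame(prs = data$prs), data[pc_cols(20)])
    },
    PCadjPRS = {
      need(c("prs", pc_cols(10)))
      scores <- as.matrix(data[pc_cols(10)])
      cbind(data.frame(prs_adj = pc_adjust_prs(data$prs, scores)),
            data[pc_cols(10)])
    },
    abort(sprintf("unknown model label '%s'", label))
  )
}

#' Fit a working association model
#'
#' Fits one of the working association models compared in the simulation
#' study, by ordinary least squares (`family = "linear"`) or
#' maximum-likelihood logistic regression (`"logistic"`):
#'
#' * `M1_none` — outcome on PRS, no adjustment;
#' * `M2_gePRS` — global rPRS adjusted for global ePRS;
#' * `M3_lePRS` — local rPRS adjusted for local ePRS;
#' * `M4_conf_pc_star` — PRS adjusted for the *observed* PC-like confounder
#'   (the benchmark when that confounder generated the data);
#' * `M5_gaProp` — PRS adjusted for global ancestry proportions (one
#'   proportion column dropped against the intercept);
#' * `M6_PC10` / `M7_PC20` — PRS adjusted for 10 / 20 genotype PCs;
#' * `PCadjPRS` — the PC-adjusted-PRS comparator: PRS residualized on PCs
#'   used as the exposure, PCs kept in the model.
#'
#' In every model the coefficient of the PRS-role term (PRS or rPRS)
#' estimates the PRS-outcome effect. Constant adjustment columns are
#' dropped with a message (an ePRS that does not vary cannot adjust for
#' anything); remaining rank deficiency is an error naming the collinear
#' terms. Confidence intervals are Wald: estimate +/- 1.959964 SE.
#'
#' @param data A data frame holding the outcome column `y` plus the columns
#'   the chosen model needs: `prs`, and per label `eprs_global`,
#'   `eprs_local`, `conf_pc_star`, `ga_<ancestry>` proportions, or
#'   `PC1..PC20` scores. Extra columns are ignored.
#' @param label Model label: `"M1_none"`, `"M2_gePRS"`, `"M3_lePRS"`,
#'   `"M4_conf_pc_star"`, `"M5_gaProp"`, `"M6_PC10"`, `"M7_PC20"`, or
#'   `"PCadjPRS"`.
#' @param family `"linear"` or `"logistic"` (binary `y`).
#' @param covariates Optional character vector of extra adjustment columns
#'   in `data`.
#' @return An object of class `eprs_fit`; see [tidy.eprs_fit()] and
#'   [glance.eprs_fit()].
#' @export
fit_working_model <- function(data, label = MODEL_LABELS,
                              family = c("linear", "logistic"),
                              covariates = NULL) {
  label <- match.arg(label)
  family <- match.arg(family)
  if (!"y" %in% names(data)) abort("`data` must contain an outcome column `y`")
  design <- model_design(data, label)
  if (!is.null(covariates)) {
    design <- cbind(design, data[covariates])
  }
  prs_term <- names(design)[1]

  const <- vapply(design[-1], function(x) sd(x) == 0, logical(1))
  if (any(const)) {
    inform(sprintf("dropping constant adjustment term(s): %s",
                   paste(names(design[-1])[const], collapse = ", ")))
    design <- design[c(TRUE, !const)]
  }

  df <- cbind(data.frame(y = data$y), design)
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]

  fit <- if (family == "linear") {
    lm(y ~ ., data = df)
  } else {
    f <- glm(y ~ ., data = df, family = stats::binomial())
    if (!f$converged) abort(sprintf("logistic fit for %s did not converge", label))
    f
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("model %s is rank deficient; collinear term(s): %s", label,
                  paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "eprs_validation_error")
  }
  sm <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    conf.low = sm[, 1] - Z975 * sm[, 2],
    conf.high = sm[, 1] + Z975 * sm[, 2]
  )
  structure(list(model_label = label, family = family, coef = coef_tbl,
                 prs_term = prs_term,
                 prs_term_estimate = unname(cf[prs_term]),
                 n_used = nrow(df),
                 sigma = if (family == "linear") summary(fit)$sigma else NA_real_),
            class = "eprs_fit")
}

#' @export
print.eprs_fit <- function(x, ...) {
  cat(sprintf("<%s %s fit: %s coefficient %.4f (n = %d)>\n",
              x$model_label, x$family, x$prs_term, x$prs_term_estimate,
              x$n_used))
  print(x$coef)
  invisible(x)
}

#' Tidy a working-model fit
#'
#' @param x An `eprs_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
#' @importFrom generics tidy
tidy.eprs_fit <- function(x, ...) {
  x$coef
}

#' One-row summary of a working-model fit
#'
#' @param x An `eprs_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model_label`, `family`, `prs_term`,
#'   `prs_term_estimate`, `n_used`, `sigma`.
#' @export
#' @importFrom generics glance
glance.eprs_fit <- function(x, ...) {
  tibble::tibble(model_label = x$model_label, family = x$family,
                 prs_term = x$prs_term,
                 prs_term_estimate = x$prs_term_estimate,
                 n_used = x$n_used, sigma = x$sigma)
}

#' @export
generics::tidy

#' @export
generics::glance
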