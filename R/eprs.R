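#' Compute polygenic risk scores
#'
#' The PRS of individual \eqn{i} is the weighted allele-count sum
#' \eqn{PRS_i = \sum_j \omega_j g_{ij}}. Inputs are expected to be
#' harmonized (see [harmonize()]) so genotypes count the effect allele.
#' Missing genotypes are excluded from the sum for that individual;
#' `n_variants_used` records how many variants contributed.
#'
#' @param genotypes Individuals-by-variants matrix of allele counts.
#' @param weights Weight set tibble; only variants present in both are used.
#' @return A tibble with `individual_id`, `prs`, `n_variants_used`.
#' @export
compute_prs <- function(genotypes, weights) {
  validate_genotypes(genotypes)
  validate_weight_set(weights)
  ids <- intersect(weights$variant_id, colnames(genotypes))
  if (length(ids) == 0) {
    abort("no overlapping variants between genotypes and weights",
          class = "eprs_validation_error")
  }
  g <- genotypes[, ids, drop = FALSE]
  w <- weights$weight[match(ids, weights$variant_id)]
  contrib <- sweep(g, 2, w, `*`)
  tibble::tibble(
    individual_id = rownames(g) %||% as.character(seq_len(nrow(g))),
    prs = unname(rowSums(contrib, na.rm = TRUE)),
    n_variants_used = unname(rowSums(!is.na(g)))
  )
}

#' Expected PRS and PRS variance in a homogeneous population
#'
#' For a single population with allele frequencies \eqn{f_j}, allele counts
#' are Binomial(2, f_j), so the expected PRS is \eqn{2\sum_j \omega_j f_j}
#' and (for independent variants) the PRS variance is
#' \eqn{\sum_j \omega_j^2 \, 2 f_j (1 - f_j)}.
#'
#' @param weights Weight set tibble (or a bare numeric weight vector).
#' @param freqs Numeric vector of counted-allele frequencies, one per variant,
#'   in the same order as `weights`.
#' @return A list with elements `eprs` and `var`.
#' @export
homogeneous_eprs <- function(weights, freqs) {
  w <- if (is.data.frame(weights)) {
    validate_weight_set(weights)
    weights$weight
  } else {
    as.numeric(weights)
  }
  if (length(w) != length(freqs)) {
    abort("weights and frequencies have different lengths")
  }
  if (any(freqs < 0 | freqs > 1)) {
    abort("frequencies must lie in [0, 1]", class = "eprs_validation_error")
  }
  list(eprs = 2 * sum(w * freqs), var = sum(w^2 * 2 * freqs * (1 - freqs)))
}

# align panel columns to an ancestry name vector; error on mismatch
align_panel <- function(panel, ancestries) {
  anc_p <- panel_ancestries(panel)
  if (!setequal(anc_p, ancestries)) {
    abort(sprintf(
      "ancestry mismatch: panel declares {%s}, ancestry calls declare {%s}",
      paste(anc_p, collapse = ", "), paste(ancestries, collapse = ", ")),
      class = "eprs_validation_error")
  }
  freq_matrix(panel)[, ancestries, drop = FALSE]
}

#' Global-ancestry expected PRS and PRS variance
#'
#' Under the admixture mixture model, allele counts of individual \eqn{i}
#' follow \eqn{g_{ij} \sim \sum_k \pi_{ik} Bin(2, f_j^{a_k})} with global
#' ancestry proportions \eqn{\pi_{ik}}. The global ePRS (gePRS) is
#' \eqn{\sum_j \omega_j \sum_k 2 f_j^{a_k} \pi_{ik}} — equivalently a
#' \eqn{\pi}-weighted combination of ancestry-specific ePRSs — and, for
#' independent variants, the PRS variance is
#' \eqn{\sum_j \omega_j^2 \sum_k 2 f_j^{a_k} (1 - f_j^{a_k}) \pi_{ik}}.
#'
#' @param weights Weight set tibble.
#' @param panel Frequency panel covering the weight set's variants.
#' @param gam Global ancestry tibble (rows sum to 1).
#' @return A tibble with `individual_id`, `eprs`, `var_prs`.
#' @export
global_eprs <- function(weights, panel, gam) {
  validate_weight_set(weights)
  validate_frequency_panel(panel)
  validate_global_ancestry(gam)
  ids <- weights$variant_id
  if (!all(ids %in% panel$variant_id)) {
    abort("frequency panel does not cover all weight-set variants",
          class = "eprs_validation_error")
  }
  pan <- panel[match(ids, panel$variant_id), ]
  fmat <- align_panel(pan, gam_ancestries(gam))    # p x K
  pim <- gam_matrix(gam)                            # n x K
  w <- weights$weight
  eprs <- 2 * unname(drop(pim %*% crossprod(fmat, w)))
  var_prs <- unname(drop(pim %*% crossprod(2 * fmat * (1 - fmat), w^2)))
  tibble::tibble(individual_id = gam$individual_id, eprs = eprs,
                 var_prs = var_prs)
}

#' Local-ancestry expected PRS and PRS variance
#'
#' Treats each haplotype copy's local ancestry as known and fixed:
#' \eqn{g_{ijm} \mid a_{ijm} = a_k \sim Ber(f_j^{a_k})}. The local ePRS
#' (lePRS) is \eqn{\sum_j \omega_j (f_j^{a_{ij1}} + f_j^{a_{ij2}})} and, for
#' independent variants and independent chromosomal copies, the variance is
#' \eqn{\sum_j \omega_j^2 [f_j^{a_{ij1}}(1-f_j^{a_{ij1}}) +
#' f_j^{a_{ij2}}(1-f_j^{a_{ij2}})]}.
#'
#' @param weights Weight set tibble.
#' @param panel Frequency panel covering the weight set's variants.
#' @param lat Local ancestry tensor (`n x p x 2` array, see
#'   [read_local_ancestry_msp()] or [sample_local_ancestry()]), with the
#'   variant dimension ordered as `weights`.
#' @return A tibble with `individual_id`, `eprs`, `var_prs`.
#' @export
local_eprs <- function(weights, panel, lat) {
  validate_weight_set(weights)
  validate_frequency_panel(panel)
  validate_lat(lat)
  ids <- weights$variant_id
  if (dim(lat)[2] != length(ids)) {
    abort("local ancestry tensor does not cover the weight set's variants",
          class = "eprs_validation_error")
  }
  if (!all(ids %in% panel$variant_id)) {
    abort("frequency panel does not cover all weight-set variants",
          class = "eprs_validation_error")
  }
  pan <- panel[match(ids, panel$variant_id), ]
  fmat <- align_panel(pan, lat_ancestries(lat))  # p x K, columns in label order
  w <- weights$weight
  f1 <- lookup_freq(fmat, lat[, , 1, drop = FALSE])
  f2 <- lookup_freq(fmat, lat[, , 2, drop = FALSE])
  eprs <- unname(drop((f1 + f2) %*% w))
  var_prs <- unname(drop((f1 * (1 - f1) + f2 * (1 - f2)) %*% w^2))
  tibble::tibble(
    individual_id = dimnames(lat)[[1]] %||% as.character(seq_len(dim(lat)[1])),
    eprs = eprs, var_prs = var_prs
  )
}

# fmat: p x K; labels: n x p (x 1) integer -> n x p matrix of f_j^{a_ij}
lookup_freq <- function(fmat, labels) {
  n <- dim(labels)[1]; p <- dim(labels)[2]
  lab <- matrix(as.integer(labels), n, p)
  jmat <- matrix(rep(seq_len(p), each = n), n, p)
  matrix(fmat[cbind(as.vector(jmat), as.vector(lab))], n, p)
}

#' Residual PRS
#'
#' The rPRS is the deviation of the realized PRS from the expectation
#' implied by the individual's ancestral makeup: `prs - eprs`. It is the
#' ancestry-calibrated exposure used in the working association models.
#'
#' @param prs,eprs Numeric vectors of equal length.
#' @return Numeric vector `prs - eprs`.
#' @export
residual_prs <- function(prs, eprs) {
  if (length(prs) != length(eprs)) {
    abort("prs and eprs have different lengths")
  }
  prs - eprs
}

#' Quantile PRS
#'
#' The qPRS is the percentile of an individual's PRS within their personal
#' PRS distribution: assuming `PRS ~ N(eprs, var)` (a CLT approximation over
#' independent variants), `qprs = pnorm(prs, mean = eprs, sd = sqrt(var))`.
#' Individuals with zero variance (all frequencies 0 or 1) get `NA`: the
#' normal CDF with zero scale is ill-defined.
#'
#' The closed-form variance assumes the score's variants are approximately
#' independent (LD-clumped). Declare `clumped = FALSE` for a score built
#' from correlated variants and the function returns all-`NA` with a
#' warning rather than a miscalibrated percentile.
#'
#' @param prs,eprs,var Numeric vectors of equal length; `var >= 0`.
#' @param clumped Logical; is the weight set LD-clumped (independent
#'   variants)?
#' @param n_variants Optional variant count(s) backing each score; a warning
#'   is emitted below `min_variants`, where the normal approximation thins.
#' @param min_variants Threshold for the small-p warning (default 30).
#' @return Numeric vector of percentiles in (0, 1), `NA` where undefined.
#' @export
quantile_prs <- function(prs, eprs, var, clumped = TRUE, n_variants = NULL,
                         min_variants = 30) {
  if (length(prs) != length(eprs) || length(prs) != length(var)) {
    abort("prs, eprs and var have different lengths")
  }
  if (any(var < 0, na.rm = TRUE)) {
    abort("negative PRS variance", class = "eprs_validation_error")
  }
  if (!clumped) {
    warn(paste("qPRS requires an LD-clumped (independent-variant) score;",
               "returning NA for an un-clumped weight set"))
    return(rep(NA_real_, length(prs)))
  }
  if (!is.null(n_variants) && any(n_variants < min_variants)) {
    warn(sprintf(
      "qPRS normal approximation may be poor: %d score(s) use fewer than %d variants",
      sum(n_variants < min_variants), min_variants))
  }
  out <- rep(NA_real_, length(prs))
  ok <- var > 0
  out[ok] <- pnorm(prs[ok], mean = eprs[ok], sd = sqrt(var[ok]))
  out
}

#' Flag individuals above a qPRS risk threshold
#'
#' Classifies individuals as at-risk when their quantile PRS meets or
#' exceeds `threshold`. Because the qPRS is a within-person percentile, the
#' flagged fraction is approximately `1 - threshold` in every
#' ancestry-composition stratum — risk groups are not driven by ancestral
#' makeup.
#'
#' @param qprs Numeric vector of quantile PRS values in (0, 1).
#' @param threshold Risk threshold in (0, 1); ties flag (`>=`).
#' @return Logical vector (`NA` where `qprs` is `NA`).
#' @export
risk_stratify <- function(qprs, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single number in (0, 1)")
  }
  qprs >= threshold
}

#' Per-individual PRS profile
#'
#' One-stop computation of the PRS and its ancestry-aware companions for
#' each individual: PRS, ePRS, PRS variance, rPRS and qPRS, using global
#' ancestry proportions (`eprs_kind = "global"`), local ancestry calls
#' (`"local"`), or both. Missing genotypes are handled by restricting, per
#' individual, the PRS *and* its ePRS/variance to the same observed variant
#' subset, so the rPRS compares like with like.
#'
#' @inheritParams compute_prs
#' @param panel Frequency panel covering the weight set's variants.
#' @param gam Optional global ancestry tibble.
#' @param lat Optional local ancestry tensor (variant dimension ordered as
#'   the harmonized weight set).
#' @param clumped Passed to [quantile_prs()].
#' @return A tibble with columns `individual_id`, `prs`, `eprs`, `var_prs`,
#'   `rprs`, `qprs`, `n_variants_used`, `eprs_kind`; one row per individual
#'   and per available ePRS kind.
#' @export
prs_profile <- function(genotypes, weights, panel, gam = NULL, lat = NULL,
                        clumped = TRUE) {
  if (is.null(gam) && is.null(lat)) {
    abort("supply at least one of `gam` (global) or `lat` (local) ancestry")
  }
  h <- harmonize(weights, panel, genotypes)
  g <- h$genotypes
  ids <- h$weights$variant_id
  w <- h$weights$weight
  obs <- !is.na(g)
  prs <- unname(rowSums(sweep(g, 2, w, `*`), na.rm = TRUE))
  n_used <- unname(rowSums(obs))
  iid <- rownames(g) %||% as.character(seq_len(nrow(g)))

  profiles <- list()
  if (!is.null(gam)) {
    validate_global_ancestry(gam)
    gam <- gam[match(iid, gam$individual_id), ]
    if (anyNA(gam$individual_id)) {
      abort("global ancestry table does not cover all genotyped individuals",
            class = "eprs_validation_error")
    }
    fmat <- align_panel(h$panel, gam_ancestries(gam))
    pim <- gam_matrix(gam)
    # per-individual sums restricted to observed variants
    e_k <- (obs + 0) %*% (w * fmat)            # n x K
    v_k <- (obs + 0) %*% (w^2 * 2 * fmat * (1 - fmat))
    eprs <- 2 * unname(rowSums(e_k * pim))
    var_prs <- unname(rowSums(v_k * pim))
    profiles$global <- tibble::tibble(individual_id = iid, eprs = eprs,
                                      var_prs = var_prs)
  }
  if (!is.null(lat)) {
    validate_lat(lat)
    if (dim(lat)[2] != length(ids)) {
      abort("local ancestry tensor does not match the harmonized variant set",
            class = "eprs_validation_error")
    }
    fmat <- align_panel(h$panel, lat_ancestries(lat))
    f1 <- lookup_freq(fmat, lat[, , 1, drop = FALSE])
    f2 <- lookup_freq(fmat, lat[, , 2, drop = FALSE])
    eprs <- unname(rowSums((f1 + f2) * rep(w, each = nrow(g)) * obs))
    var_prs <- unname(rowSums((f1 * (1 - f1) + f2 * (1 - f2)) *
                                rep(w^2, each = nrow(g)) * obs))
    profiles$local <- tibble::tibble(individual_id = iid, eprs = eprs,
                                     var_prs = var_prs)
  }

  purrr::imap(profiles, function(pr, kind) {
    dplyr::mutate(
      pr,
      prs = prs,
      rprs = residual_prs(prs, .data$eprs),
      qprs = quantile_prs(prs, .data$eprs, .data$var_prs, clumped = clumped,
                          n_variants = n_used),
      n_variants_used = n_used,
      eprs_kind = kind
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("individual_id", "prs", "eprs", "var_prs", "rprs", "qprs",
                  "n_variants_used", "eprs_kind")
}

#' Write a PRS profile table
#'
#' @param profile Tibble from [prs_profile()].
#' @param path Output TSV path.
#' @export
write_prs_profile <- function(profile, path) {
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(path)
}
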