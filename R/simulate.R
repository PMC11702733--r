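#' Define a simulation scenario
#'
#' Bundles the generative configuration for simulated admixed cohorts: a
#' 3-way admixture model (sequential-uniform global proportions, multinomial
#' local ancestry, Bernoulli alleles from ancestry-specific frequencies), a
#' PRS with homogeneous or ancestry-heterogeneous weights, an optional
#' ancestry-correlated genetic confounder, and a linear outcome model
#' `Y = beta0 + beta1 * PRS + gamma * conf/sd(conf) + N(0, 1)`.
#'
#' Generative defaults follow the source study design: `n = 10000`
#' individuals, `p = 100` clumped variants, `K = 3` ancestries (labels
#' `a1`, `a2`, `a3`, e.g. European / African / Native American components of
#' Hispanic/Latino admixture), `beta0 = 1`, `beta1 = 1.5`, confounder effect
#' `gamma` on the grid 0.5 / 1 / 1.5 (default 1, the grid midpoint), and
#' `reps = 1000` replicates. True variant weights default to iid
#' `N(0, 0.05^2)` stand-ins for clumped GWAS effect estimates; supply
#' `weights` to use a real scoring file. Scenario-level inputs (frequency
#' panels, weights, confounder weights, heterogeneous-weight selection) are
#' drawn once from `seed` and held fixed across replicates, mirroring a
#' study design where the score and reference frequencies are fixed and only
#' the cohort is resampled.
#'
#' @param n Cohort size per replicate.
#' @param p Number of PRS variants.
#' @param K Number of ancestries (the simulator's admixture sampler is
#'   3-way).
#' @param weighting `"homogeneous"` or `"heterogeneous"` generative PRS
#'   weighting. Association models always use the homogeneous-weighting PRS,
#'   so heterogeneous weighting is a model-misspecification scenario.
#' @param confounder One of `"none"`, `"conf_prs1"` (100 confounder variants
#'   sharing the PRS variants' local-ancestry draws), `"conf_prs2"` (100
#'   fresh variants with African-ancestry-enriched frequencies),
#'   `"conf_pc_star"` (an observed PC-like weighted allele sum, the
#'   benchmarking confounder), `"single_variant"`, or `"two_variant"`.
#' @param beta0,beta1 Generative intercept and PRS effect.
#' @param gamma Confounder effect size; ignored when `confounder = "none"`.
#' @param reps Number of simulation replicates.
#' @param seed Root seed; per-replicate substreams are derived from it.
#' @param ancestry_noise Optional list `list(where = "global"|"local",
#'   level = x)` perturbing the ancestry information *given to the analyst*
#'   (the generative draws are untouched), emulating ancestry-inference
#'   error.
#' @param weights Optional weight-set tibble supplying real variant weights.
#' @param p_conf Number of confounder variants for the PRS-like confounders.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 10000, p = 100, K = 3,
                         weighting = c("homogeneous", "heterogeneous"),
                         confounder = c("none", "conf_prs1", "conf_prs2",
                                        "conf_pc_star", "single_variant",
                                        "two_variant"),
                         beta0 = 1, beta1 = 1.5, gamma = 1,
                         reps = 1000, seed = 1, ancestry_noise = NULL,
                         weights = NULL, p_conf = 100) {
  weighting <- match.arg(weighting)
  confounder <- match.arg(confounder)
  if (n < 1 || p < 1 || reps < 1) abort("n, p and reps must all be >= 1")
  if (K < 2) abort("admixture scenarios need K >= 2 ancestries")
  if (K != 3) abort("the admixture sampler is 3-way; K must be 3")
  if (!is.null(weights)) validate_weight_set(weights)
  if (!is.null(ancestry_noise)) {
    if (!is.list(ancestry_noise) ||
        !ancestry_noise$where %in% c("global", "local") ||
        ancestry_noise$level < 0 || ancestry_noise$level > 1) {
      abort("ancestry_noise must be list(where = 'global'|'local', level in [0,1])")
    }
  }
  if (confounder == "conf_prs1") p_conf <- p  # shares the PRS variants' draws
  structure(list(n = n, p = p, K = K, weighting = weighting,
                 confounder = confounder, beta0 = beta0, beta1 = beta1,
                 gamma = gamma, reps = reps, seed = seed,
                 ancestry_noise = ancestry_noise, weights = weights,
                 p_conf = p_conf),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario: n=%d p=%d %s weighting, confounder=%s (gamma=%g), reps=%d, seed=%d>\n",
    x$n, x$p, x$weighting, x$confounder, x$gamma, x$reps, x$seed))
  invisible(x)
}

#' Sample global ancestry proportions (3-way sequential-uniform)
#'
#' Draws `pi_a1 ~ Unif(0, 1)`, `pi_a2 | pi_a1 ~ Unif(0, 1 - pi_a1)`,
#' `pi_a3 = 1 - pi_a1 - pi_a2`, so `a1` is on average the dominant ancestry
#' (mean proportions 1/2, 1/4, 1/4).
#'
#' @param n Number of individuals.
#' @param ancestries Ancestry labels (length 3).
#' @return A global ancestry tibble.
#' @export
sample_global_proportions <- function(n, ancestries = c("a1", "a2", "a3")) {
  stopifnot(length(ancestries) == 3)
  p1 <- runif(n)
  p2 <- runif(n, 0, 1 - p1)
  m <- cbind(p1, p2, 1 - p1 - p2)
  colnames(m) <- ancestries
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(individual_id = sprintf("i%d", seq_len(n)), .before = 1)
}

#' Sample local ancestry labels
#'
#' Each variant x haplotype label is drawn independently from a categorical
#' distribution with the individual's global ancestry proportions (variants
#' and the two chromosomal copies are independent).
#'
#' @param gam Global ancestry tibble.
#' @param p Number of variants.
#' @param variant_ids Optional variant ids for the tensor's dimnames.
#' @return A local ancestry tensor (`n x p x 2` integer array).
#' @export
sample_local_ancestry <- function(gam, p, variant_ids = NULL) {
  validate_global_ancestry(gam)
  pim <- gam_matrix(gam)
  n <- nrow(pim); K <- ncol(pim)
  cumpi <- t(apply(pim, 1, cumsum))
  draw <- function() {
    u <- matrix(runif(n * p), n, p)
    lab <- matrix(1L, n, p)
    for (k in seq_len(K - 1)) lab <- lab + (u > cumpi[, k])
    lab
  }
  arr <- array(0L, dim = c(n, p, 2))
  arr[, , 1] <- draw()
  arr[, , 2] <- draw()
  new_lat(arr, colnames(pim), gam$individual_id, variant_ids)
}

#' Sample genotypes given local ancestry
#'
#' Each haplotype allele is Bernoulli with the ancestry-specific frequency
#' of its local-ancestry label: `g_ij = Ber(f_j^{a_ij1}) + Ber(f_j^{a_ij2})`.
#'
#' @param lat Local ancestry tensor.
#' @param panel Frequency panel covering the tensor's ancestry set; rows
#'   must be ordered as the tensor's variant dimension.
#' @param keep_haplotypes Keep the per-haplotype 0/1 allele matrices as
#'   attributes `hap1`/`hap2` (needed for haplotype-wise heterogeneous
#'   weighting).
#' @return An individuals-by-variants allele count matrix.
#' @export
sample_genotypes <- function(lat, panel, keep_haplotypes = FALSE) {
  validate_lat(lat)
  validate_frequency_panel(panel)
  n <- dim(lat)[1]; p <- dim(lat)[2]
  if (nrow(panel) != p) {
    abort("panel must have one row per tensor variant, in order",
          class = "eprs_validation_error")
  }
  fmat <- align_panel(panel, lat_ancestries(lat))
  f1 <- lookup_freq(fmat, lat[, , 1, drop = FALSE])
  f2 <- lookup_freq(fmat, lat[, , 2, drop = FALSE])
  h1 <- (matrix(runif(n * p), n, p) < f1) + 0
  h2 <- (matrix(runif(n * p), n, p) < f2) + 0
  g <- h1 + h2
  dimnames(g) <- list(dimnames(lat)[[1]], panel$variant_id)
  if (keep_haplotypes) {
    attr(g, "hap1") <- h1
    attr(g, "hap2") <- h2
  }
  g
}

#' Synthesize an ancestry-specific frequency panel
#'
#' Stands in for estimated ancestry-specific frequencies (e.g. GAFA output).
#' The `"generic"` profile draws frequencies iid Uniform(0.05, 0.95) per
#' ancestry. The `"conf_prs2_enriched"` profile emulates variants common in
#' African ancestry but rare in European ancestry: `a2 ~ Unif(0.4, 0.6)`,
#' `a1 ~ Unif(0.01, 0.1)`, all other ancestries Uniform(0.05, 0.95).
#'
#' @param p Number of variants.
#' @param K Number of ancestries.
#' @param profile `"generic"` or `"conf_prs2_enriched"`.
#' @param ancestries Ancestry labels.
#' @param prefix Variant id prefix.
#' @return A frequency panel tibble (counted allele arbitrarily `"A"`).
#' @export
synthesize_frequency_panel <- function(p, K = 3,
                                       profile = c("generic",
                                                   "conf_prs2_enriched"),
                                       ancestries = paste0("a", seq_len(K)),
                                       prefix = "v") {
  profile <- match.arg(profile)
  stopifnot(p >= 1, length(ancestries) == K)
  f <- matrix(runif(p * K, 0.05, 0.95), p, K)
  colnames(f) <- ancestries
  if (profile == "conf_prs2_enriched") {
    if (!all(c("a1", "a2") %in% ancestries)) {
      abort("conf_prs2_enriched profile expects ancestries named a1 and a2")
    }
    f[, "a2"] <- runif(p, 0.4, 0.6)
    f[, "a1"] <- runif(p, 0.01, 0.1)
  }
  tibble::tibble(variant_id = sprintf("%s%d", prefix, seq_len(p)),
                 counted_allele = "A") |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(f)))
}

#' Synthesize a weight set
#'
#' Default stand-in for clumped GWAS effect sizes: iid `N(0, sd^2)` weights
#' on the panel's variants, with the effect allele set to the panel's
#' counted allele (already harmonized).
#'
#' @param panel Frequency panel whose variants to weight.
#' @param sd Weight standard deviation (default 0.05).
#' @return A weight set tibble.
#' @export
synthesize_weights <- function(panel, sd = 0.05) {
  validate_frequency_panel(panel)
  tibble::tibble(
    variant_id = panel$variant_id,
    effect_allele = panel$counted_allele,
    other_allele = ifelse(panel$counted_allele == "A", "G", "A"),
    weight = rnorm(nrow(panel), 0, sd)
  )
}

#' Ancestry-heterogeneous weight table
#'
#' Builds the ancestry-indexed weights for the heterogeneous-weighting PRS:
#' the base weight everywhere, except that the `top_n` variants with the
#' highest `a2` frequency get weight 1.5 on haplotypes whose local ancestry
#' is `a2`, and the `top_n` highest-`a3`-frequency variants (after removing
#' `a2`'s selection) get weight 2 on `a3` haplotypes. Frequency ties break
#' by ascending variant index; overlap resolves `a2`-first.
#'
#' @param weights Base weight set (>= 2 * `top_n` variants).
#' @param panel Frequency panel covering the weight set, with ancestries
#'   `a2` and `a3`.
#' @param top_n Number of selected variants per ancestry (default 10).
#' @param boost_a2,boost_a3 Replacement effect sizes (defaults 1.5 and 2).
#' @return A tibble with `variant_id` and one weight column per ancestry
#'   (`w_a1`, `w_a2`, ...), to be applied haplotype-wise by local ancestry.
#' @export
make_heterogeneous_weights <- function(weights, panel, top_n = 10,
                                       boost_a2 = 1.5, boost_a3 = 2) {
  validate_weight_set(weights)
  validate_frequency_panel(panel)
  if (nrow(weights) < 2 * top_n) {
    abort(sprintf("heterogeneous weighting needs at least %d variants", 2 * top_n))
  }
  pan <- panel[match(weights$variant_id, panel$variant_id), ]
  anc <- panel_ancestries(panel)
  if (!all(c("a2", "a3") %in% anc)) {
    abort("heterogeneous weighting expects ancestries named a2 and a3")
  }
  idx <- seq_len(nrow(weights))
  sel_a2 <- idx[order(-pan$a2, idx)][seq_len(top_n)]
  rest <- setdiff(idx, sel_a2)
  sel_a3 <- rest[order(-pan$a3[rest], rest)][seq_len(top_n)]

  wmat <- matrix(weights$weight, nrow(weights), length(anc),
                 dimnames = list(NULL, paste0("w_", anc)))
  wmat[sel_a2, "w_a2"] <- boost_a2
  wmat[sel_a3, "w_a3"] <- boost_a3
  dplyr::bind_cols(tibble::tibble(variant_id = weights$variant_id),
                   tibble::as_tibble(as.data.frame(wmat)))
}

# Haplotype-wise PRS under ancestry-indexed weights: each haplotype allele is
# weighted by the weight matching its local ancestry.
prs_heterogeneous <- function(genotypes, lat, het_weights) {
  h1 <- attr(genotypes, "hap1")
  h2 <- attr(genotypes, "hap2")
  if (is.null(h1) || is.null(h2)) {
    abort("genotypes must be sampled with keep_haplotypes = TRUE")
  }
  wmat <- as.matrix(het_weights[paste0("w_", lat_ancestries(lat))])
  w1 <- lookup_freq(wmat, lat[, , 1, drop = FALSE])
  w2 <- lookup_freq(wmat, lat[, , 2, drop = FALSE])
  rowSums(w1 * h1 + w2 * h2)
}

#' Build an ancestry-correlated genetic confounder
#'
#' Constructs the unknown genetic factor `U_G` used in confounded outcome
#' scenarios. All PRS-like kinds are weighted allele sums over their own
#' variant set:
#' \describe{
#'   \item{`conf_prs1`}{`p_conf` variants that reuse, variant-for-variant,
#'     the PRS variants' local-ancestry draws (shared ancestry intervals),
#'     with fresh generic frequencies and `N(0, 1)` weights.}
#'   \item{`conf_prs2`}{`p_conf` fresh variants with African-enriched
#'     (`conf_prs2_enriched`) frequencies and `N(0, 1)` weights; the
#'     strong-stratification scenario.}
#'   \item{`conf_pc_star`}{`p_conf` fresh variants, generic frequencies,
#'     `N(0, 1)` weights; treated downstream as an *observed* covariate
#'     (benchmark model M4). It mimics a genetic PC score but is not
#'     computed via PCA.}
#'   \item{`single_variant` / `two_variant`}{1 or 2 variants from the
#'     enriched profile with unit weight.}
#'   \item{`none`}{A zero vector.}
#' }
#'
#' @param kind Confounder kind (see above).
#' @param gam Global ancestry tibble (for drawing fresh local ancestry).
#' @param lat_prs The PRS variants' local ancestry tensor (required for
#'   `conf_prs1`).
#' @param p_conf Number of confounder variants for the PRS-like kinds.
#' @param spec Optional fixed confounder specification (list with `panel`
#'   and `weights`) reused across replicates; when `NULL` a fresh one is
#'   drawn. Returned in the metadata so callers can hold it fixed.
#' @return A list with `value` (length-n numeric), `kind`, and `spec`.
#' @export
build_confounder <- function(kind, gam, lat_prs = NULL, p_conf = 100,
                             spec = NULL) {
  kinds <- c("none", "conf_prs1", "conf_prs2", "conf_pc_star",
             "single_variant", "two_variant")
  if (!kind %in% kinds) {
    abort(sprintf("unknown confounder kind '%s'", kind))
  }
  if (kind == "none") {
    return(list(value = rep(0, nrow(gam)), kind = kind, spec = NULL))
  }
  n_var <- switch(kind, single_variant = 1L, two_variant = 2L, p_conf)
  profile <- switch(kind,
                    conf_prs2 = , single_variant = ,
                    two_variant = "conf_prs2_enriched",
                    "generic")
  if (is.null(spec)) {
    panel <- synthesize_frequency_panel(n_var, K = length(gam_ancestries(gam)),
                                        profile = profile,
                                        ancestries = gam_ancestries(gam),
                                        prefix = "c")
    wts <- if (kind %in% c("single_variant", "two_variant")) {
      rep(1, n_var)
    } else {
      rnorm(n_var)
    }
    spec <- list(panel = panel, weights = wts)
  }
  lat_c <- if (kind == "conf_prs1") {
    if (is.null(lat_prs)) abort("conf_prs1 requires the PRS local-ancestry tensor")
    if (dim(lat_prs)[2] != n_var) {
      abort("conf_prs1 requires p_conf equal to the number of PRS variants")
    }
    lat_prs
  } else {
    sample_local_ancestry(gam, n_var, variant_ids = spec$panel$variant_id)
  }
  g <- sample_genotypes(lat_c, spec$panel)
  list(value = drop(g %*% spec$weights), kind = kind, spec = spec)
}

#' Simulate a continuous outcome
#'
#' `Y = beta0 + beta1 * PRS + gamma * conf / sd(conf) + e`, with
#' `e ~ N(0, error_sd^2)`. The confounder is standardized by its
#' within-replicate sample SD so `gamma` is comparable across confounder
#' kinds; when the scenario's confounder is `"none"` the gamma term is
#' dropped.
#'
#' @param prs Generative PRS vector.
#' @param conf Confounder value vector.
#' @param scenario A [sim_scenario()].
#' @param error_sd Error SD (default 1; 0 gives a noise-free outcome for
#'   exactness checks).
#' @return Outcome vector.
#' @export
simulate_outcome <- function(prs, conf, scenario, error_sd = 1) {
  stopifnot(length(prs) == length(conf))
  n <- length(prs)
  eff <- scenario$beta0 + scenario$beta1 * prs
  if (scenario$confounder != "none") {
    s <- sd(conf)
    if (!is.finite(s) || s == 0) {
      abort("confounder has zero variance; cannot standardize",
            class = "eprs_validation_error")
    }
    eff <- eff + scenario$gamma * conf / s
  }
  eff + rnorm(n, 0, error_sd)
}

#' Perturb ancestry information with random error
#'
#' Emulates error in ancestry inference. For a global ancestry table, each
#' row becomes the convex combination
#' `(1 - level) * pi + level * Dirichlet(1, ..., 1)`; for a local ancestry
#' tensor, each label is independently resampled from the individual's
#' global proportions with probability `level`.
#'
#' @param x A global ancestry tibble or a local ancestry tensor.
#' @param level Noise level in `[0, 1]`; 0 is the identity.
#' @param gam Global proportions used for resampling labels (local method).
#' @param ... Passed to methods.
#' @return A perturbed copy of `x`.
#' @export
inject_ancestry_noise <- function(x, level, ...) {
  if (level < 0 || level > 1) abort("noise level must lie in [0, 1]")
  UseMethod("inject_ancestry_noise")
}

#' @rdname inject_ancestry_noise
#' @export
inject_ancestry_noise.data.frame <- function(x, level, ...) {
  validate_global_ancestry(x)
  if (level == 0) return(x)
  m <- gam_matrix(x)
  K <- ncol(m)
  e <- matrix(stats::rexp(nrow(m) * K), nrow(m), K)  # Dirichlet(1,...,1)
  e <- e / rowSums(e)
  out <- (1 - level) * m + level * e
  res <- tibble::as_tibble(cbind(x["individual_id"], as.data.frame(out)))
  validate_global_ancestry(res)
  res
}

#' @rdname inject_ancestry_noise
#' @export
inject_ancestry_noise.eprs_lat <- function(x, level, gam, ...) {
  validate_lat(x)
  if (level == 0) return(x)
  validate_global_ancestry(gam)
  fresh <- sample_local_ancestry(gam, dim(x)[2], dimnames(x)[[2]])
  n <- dim(x)[1]; p <- dim(x)[2]
  out <- x
  for (m in 1:2) {
    swap <- matrix(runif(n * p) < level, n, p)
    slab <- out[, , m]
    slab[swap] <- fresh[, , m][swap]
    out[, , m] <- slab
  }
  out
}

# Scenario-level fixed inputs, drawn once from the root seed (substream 0).
scenario_fixed_inputs <- function(scenario) {
  set.seed(derive_seed(scenario$seed, 0))
  ancestries <- paste0("a", seq_len(scenario$K))
  panel <- synthesize_frequency_panel(scenario$p, K = scenario$K,
                                      ancestries = ancestries)
  weights <- if (!is.null(scenario$weights)) {
    w <- scenario$weights[seq_len(min(nrow(scenario$weights), scenario$p)), ]
    if (nrow(w) != scenario$p) {
      abort("supplied weight set has fewer variants than scenario p")
    }
    w$variant_id <- panel$variant_id  # align onto the synthetic panel
    w
  } else {
    synthesize_weights(panel)
  }
  het <- if (scenario$weighting == "heterogeneous") {
    make_heterogeneous_weights(weights, panel)
  } else {
    NULL
  }
  conf_spec <- if (scenario$confounder == "none") {
    NULL
  } else {
    # draw the fixed confounder panel/weights via a throwaway gam
    gam0 <- sample_global_proportions(2, ancestries)
    build_confounder(scenario$confounder, gam0,
                     lat_prs = if (scenario$confounder == "conf_prs1") {
                       sample_local_ancestry(gam0, scenario$p_conf)
                     } else NULL,
                     p_conf = scenario$p_conf)$spec
  }
  list(panel = panel, weights = weights, het_weights = het,
       conf_spec = conf_spec, ancestries = ancestries)
}

#' Simulate one cohort replicate
#'
#' Draws a complete replicate of a scenario: global proportions, local
#' ancestry, genotypes, the generative PRS (homogeneous or heterogeneous
#' weighting), the confounder, and the outcome. Replicate `rep_index` is
#' reproducible in isolation: its RNG substream is derived from
#' `(scenario$seed, rep_index)`.
#'
#' @param scenario A [sim_scenario()].
#' @param rep_index Replicate index (1-based).
#' @param fixed Scenario-level fixed inputs; computed from the scenario seed
#'   when `NULL`. Pass the same object across replicates to avoid rework.
#' @return A list with elements `gam`, `lat`, `genotypes`, `panel`,
#'   `weights`, `prs` (homogeneous-weighting PRS used by association
#'   models), `prs_true` (generative PRS), `conf`, `outcome`, `truth`, and
#'   the analyst-facing `gam_obs`/`lat_obs` (noise-perturbed when the
#'   scenario requests it).
#' @export
simulate_replicate <- function(scenario, rep_index = 1, fixed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(fixed)) fixed <- scenario_fixed_inputs(scenario)
  set.seed(derive_seed(scenario$seed, rep_index))

  gam <- sample_global_proportions(scenario$n, fixed$ancestries)
  lat <- sample_local_ancestry(gam, scenario$p, fixed$panel$variant_id)
  g <- sample_genotypes(lat, fixed$panel,
                        keep_haplotypes = scenario$weighting == "heterogeneous")
  prs <- drop(g %*% fixed$weights$weight)
  prs_true <- if (scenario$weighting == "heterogeneous") {
    prs_heterogeneous(g, lat, fixed$het_weights)
  } else {
    prs
  }
  conf <- build_confounder(scenario$confounder, gam, lat_prs = lat,
                           p_conf = scenario$p_conf, spec = fixed$conf_spec)
  outcome <- simulate_outcome(prs_true, conf$value, scenario)

  gam_obs <- gam
  lat_obs <- lat
  noise <- scenario$ancestry_noise
  if (!is.null(noise)) {
    if (noise$where == "global") {
      gam_obs <- inject_ancestry_noise(gam, noise$level)
    } else {
      lat_obs <- inject_ancestry_noise(lat, noise$level, gam)
    }
  }

  list(gam = gam, lat = lat, genotypes = g, panel = fixed$panel,
       weights = fixed$weights, prs = prs, prs_true = prs_true,
       conf = conf$value, outcome = outcome,
       gam_obs = gam_obs, lat_obs = lat_obs,
       truth = c(beta0 = scenario$beta0, beta1 = scenario$beta1,
                 gamma = scenario$gamma))
}
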