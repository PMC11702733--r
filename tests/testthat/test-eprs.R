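test_that("compute_prs matches hand arithmetic and a brute-force loop", {
  ws <- make_weights(2, w = c(1, 2))
  g <- matrix(c(2, 1), 1, 2, dimnames = list("i1", c("v1", "v2")))
  expect_equal(compute_prs(g, ws)$prs, 4)
  expect_equal(compute_prs(g * 0, ws)$prs, 0)

  set.seed(5)
  ws <- make_weights(20, w = rnorm(20))
  g <- matrix(sample(0:2, 50 * 20, replace = TRUE), 50, 20,
              dimnames = list(NULL, ws$variant_id))
  g[sample(length(g), 40)] <- NA
  got <- compute_prs(g, ws)
  oracle <- vapply(1:50, function(i) {
    s <- 0
    for (j in 1:20) if (!is.na(g[i, j])) s <- s + ws$weight[j] * g[i, j]
    s
  }, numeric(1))
  expect_equal(got$prs, oracle)
  expect_equal(got$n_variants_used, rowSums(!is.na(g)))

  expect_error(compute_prs(g, dplyr::mutate(ws, variant_id = paste0("x", variant_id))),
               "overlap", class = "eprs_validation_error")
})

test_that("homogeneous ePRS/variance follow the binomial model and reduce from the global form", {
  out <- homogeneous_eprs(c(1, 1), c(0.5, 0.5))
  expect_equal(out$eprs, 2)
  expect_equal(out$var, 1)
  expect_equal(homogeneous_eprs(c(1, 1), c(0, 0)), list(eprs = 0, var = 0))
  expect_error(homogeneous_eprs(c(1, 1), 0.5), "length")

  # K = 1 global model with pi = 1 is the homogeneous model, exactly
  set.seed(7)
  ws <- make_weights(10, w = rnorm(10))
  f <- runif(10)
  panel <- make_panel(10, K = 1, f = matrix(f, 10, 1),
                      counted = ws$effect_allele)
  gam <- make_gam(matrix(1, 3, 1))
  ge <- global_eprs(ws, panel, gam)
  hom <- homogeneous_eprs(ws, f)
  expect_equal(ge$eprs, rep(hom$eprs, 3))
  expect_equal(ge$var_prs, rep(hom$var, 3))
})

test_that("global ePRS matches the mixture-model expectation", {
  ws <- make_weights(1, w = 1)
  panel <- make_panel(1, K = 2, f = matrix(c(0.2, 0.8), 1, 2),
                      counted = ws$effect_allele)
  gam <- make_gam(matrix(c(0.5, 0.5), 1, 2))
  ge <- global_eprs(ws, panel, gam)
  expect_equal(ge$eprs, 1)             # 2 * (0.2 * 0.5 + 0.8 * 0.5)
  expect_equal(ge$var_prs, 0.32)       # 0.5*2*.2*.8 + 0.5*2*.8*.2

  # pi concentrated on one ancestry reduces to the homogeneous form
  gam1 <- make_gam(matrix(c(1, 0), 1, 2))
  expect_equal(global_eprs(ws, panel, gam1)$eprs,
               homogeneous_eprs(ws, 0.2)$eprs)

  bad_gam <- make_gam(matrix(c(0.5, 0.5), 1, 2), ancestries = c("x1", "x2"))
  expect_error(global_eprs(ws, panel, bad_gam), "mismatch",
               class = "eprs_validation_error")
})

test_that("local ePRS matches fixed-haplotype expectations and degenerate reductions", {
  ws <- make_weights(1, w = 1)
  panel <- make_panel(1, K = 2, f = matrix(c(0.2, 0.8), 1, 2),
                      counted = ws$effect_allele)
  lat <- make_lat(matrix(1L, 1, 1), matrix(2L, 1, 1), c("a1", "a2"))
  le <- local_eprs(ws, panel, lat)
  expect_equal(le$eprs, 1)                       # 0.2 + 0.8
  expect_equal(le$var_prs, 0.2 * 0.8 + 0.8 * 0.2)

  # both haplotypes from one ancestry at every variant = homogeneous form
  set.seed(8)
  ws2 <- make_weights(6, w = rnorm(6))
  f2 <- matrix(runif(12), 6, 2)
  panel2 <- make_panel(6, K = 2, f = f2, counted = ws2$effect_allele)
  lat2 <- make_lat(matrix(2L, 4, 6), matrix(2L, 4, 6), c("a1", "a2"))
  le2 <- local_eprs(ws2, panel2, lat2)
  hom2 <- homogeneous_eprs(ws2, f2[, 2])
  expect_equal(le2$eprs, rep(hom2$eprs, 4))
  expect_equal(le2$var_prs, rep(hom2$var, 4))

  bad <- make_lat(matrix(3L, 1, 6), matrix(1L, 1, 6), c("a1", "a2", "a3"))
  expect_error(local_eprs(ws2, panel2, bad), "mismatch",
               class = "eprs_validation_error")
})

test_that("sampling oracle: simulated PRS moments match the closed forms", {
  # one individual, fixed pi; redraw local ancestry + alleles many times
  set.seed(21)
  p <- 8
  R <- 60000
  ws <- make_weights(p, w = rnorm(p, 0, 0.3))
  panel <- make_panel(p, K = 3, counted = ws$effect_allele)
  pi_i <- c(0.5, 0.3, 0.2)
  gam_rep <- make_gam(matrix(pi_i, R, 3, byrow = TRUE))

  lat <- sample_local_ancestry(gam_rep, p, ws$variant_id)
  g <- sample_genotypes(lat, panel)
  prs <- drop(g %*% ws$weight)

  ge <- global_eprs(ws, panel, make_gam(matrix(pi_i, 1, 3, byrow = TRUE)))
  le <- local_eprs(ws, panel, lat)

  # mean PRS over the mixture matches the global ePRS
  se_mean <- sd(prs) / sqrt(R)
  expect_lt(abs(mean(prs) - ge$eprs), 4 * se_mean)

  # conditional on the local-ancestry draw, mean and variance match the
  # local forms: (PRS - lePRS) is mean-zero with variance Var(PRS | lat)
  resid <- prs - le$eprs
  expect_lt(abs(mean(resid)), 4 * sd(resid) / sqrt(R))
  vbar <- mean(le$var_prs)
  expect_lt(abs(mean(resid^2) - vbar), 4 * sd(resid^2 - le$var_prs) / sqrt(R))

  # the global variance formula is the expected conditional variance:
  # averaging Var(PRS | lat) over local-ancestry draws recovers it
  expect_lt(abs(mean(le$var_prs) - ge$var_prs),
            4 * sd(le$var_prs) / sqrt(R))

  # and the total variance given pi decomposes as expected conditional
  # variance plus the variance of the conditional mean (law of total
  # variance) -- the global formula is the first term only
  total <- ge$var_prs + var(le$eprs)
  expect_lt(abs(var(prs) - total), 4 * var(prs) * sqrt(2 / (R - 1)))
  expect_gt(var(prs), ge$var_prs)

  # law of total expectation: mean lePRS over ancestry draws = gePRS
  expect_lt(abs(mean(le$eprs) - ge$eprs), 4 * sd(le$eprs) / sqrt(R))
})

test_that("residual PRS subtracts elementwise and centers at zero in simulation", {
  expect_equal(residual_prs(c(3, 1.5), c(3, 0)), c(0, 1.5))
  expect_error(residual_prs(1:3, 1:2), "length")

  set.seed(31)
  sc <- sim_scenario(n = 4000, p = 50, reps = 1, seed = 31)
  sim <- simulate_replicate(sc, 1)
  ge <- global_eprs(sim$weights, sim$panel, sim$gam)
  r <- residual_prs(sim$prs, ge$eprs)
  expect_lt(abs(mean(r)), 4 * sd(r) / sqrt(length(r)))
})

test_that("quantile PRS is a calibrated normal percentile with guarded edge cases", {
  expect_equal(quantile_prs(2, 2, 4), 0.5)
  expect_equal(quantile_prs(2 + 1.959964 * 2, 2, 4), 0.975, tolerance = 1e-6)

  # strictly increasing in prs for fixed (eprs, var)
  set.seed(41)
  for (k in 1:5) {
    e <- rnorm(1); v <- runif(1, 0.1, 2)
    q <- quantile_prs(sort(rnorm(20, e, 2)), rep(e, 20), rep(v, 20))
    expect_true(all(diff(q) > 0))
  }

  expect_true(is.na(quantile_prs(1, 1, 0)))
  expect_error(quantile_prs(1, 1, -1), "negative", class = "eprs_validation_error")
  expect_warning(q <- quantile_prs(1, 0, 1, clumped = FALSE), "clumped")
  expect_true(is.na(q))
  expect_warning(quantile_prs(1, 0, 1, n_variants = 10), "fewer than 30")
})

test_that("risk stratification flags the upper qPRS tail with >= ties", {
  expect_equal(risk_stratify(c(0.4, 0.6), 0.5), c(FALSE, TRUE))
  expect_equal(risk_stratify(c(0.5, 0.5), 0.5), c(TRUE, TRUE))
  expect_error(risk_stratify(0.5, 0), "threshold")
  expect_error(risk_stratify(0.5, 1), "threshold")
})

test_that("prs_profile ties PRS and ePRS to the same observed variants", {
  set.seed(51)
  p <- 12; n <- 40
  panel <- synthesize_frequency_panel(p, 3)
  ws <- synthesize_weights(panel)
  gam <- sample_global_proportions(n)
  lat <- sample_local_ancestry(gam, p, panel$variant_id)
  g <- sample_genotypes(lat, panel)
  attr(g, "counted_allele") <- stats::setNames(panel$counted_allele,
                                               panel$variant_id)
  g[sample(length(g), 30)] <- NA

  prof <- suppressWarnings(
    prs_profile(g, ws, panel, gam = gam, lat = lat))
  expect_setequal(unique(prof$eprs_kind), c("global", "local"))
  expect_equal(prof$rprs, prof$prs - prof$eprs)
  expect_true(all(prof$qprs > 0 & prof$qprs < 1, na.rm = TRUE))

  glob <- dplyr::filter(prof, eprs_kind == "global")
  # oracle: recompute one individual's global ePRS over its observed subset
  i <- which(rowSums(is.na(g)) > 0)[1]
  obs <- !is.na(g[i, ])
  fm <- as.matrix(panel[panel_ancestries(panel)])[obs, , drop = FALSE]
  pim <- unlist(gam[i, -1])
  e_manual <- 2 * sum(ws$weight[obs] * (fm %*% pim))
  expect_equal(glob$eprs[i], e_manual)
  expect_equal(glob$n_variants_used[i], sum(obs))
})
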