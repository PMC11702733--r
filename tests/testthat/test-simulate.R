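test_that("global proportions follow the sequential-uniform scheme", {
  set.seed(1)
  a <- sample_global_proportions(5)
  set.seed(1)
  b <- sample_global_proportions(5)
  expect_identical(a, b)

  set.seed(2)
  gam <- sample_global_proportions(100000)
  m <- as.matrix(gam[-1])
  expect_equal(unname(rowSums(m)), rep(1, 100000))
  # E[pi_a1] = 1/2 (U(0,1)); E[pi_a2] = E[(1 - pi_a1)/2] = 1/4
  expect_lt(abs(mean(m[, "a1"]) - 0.5), 4 * sd(m[, "a1"]) / sqrt(1e5))
  expect_lt(abs(mean(m[, "a2"]) - 0.25), 4 * sd(m[, "a2"]) / sqrt(1e5))
})

test_that("local ancestry is multinomial in pi with independent haplotypes", {
  gam1 <- make_gam(matrix(c(1, 0, 0), 1, 3))
  lat <- sample_local_ancestry(gam1, 50)
  expect_true(all(lat == 1L))

  set.seed(3)
  pi_i <- c(0.6, 0.3, 0.1)
  gam <- make_gam(matrix(pi_i, 1, 3, byrow = TRUE))
  p <- 10000
  lat <- sample_local_ancestry(gam, p)
  for (k in 1:3) {
    phat <- mean(lat[1, , 1] == k)
    expect_lt(abs(phat - pi_i[k]), 4 * sqrt(pi_i[k] * (1 - pi_i[k]) / p))
  }
  # haplotype independence: chi-square on the 3x3 joint label table
  tab <- table(factor(lat[1, , 1], 1:3), factor(lat[1, , 2], 1:3))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("genotypes are Bernoulli sums with ancestry-specific frequencies", {
  ws <- make_weights(4)
  lat <- make_lat(matrix(1L, 3, 4), matrix(2L, 3, 4), c("a1", "a2"))
  zero <- make_panel(4, K = 2, f = matrix(0, 4, 2), counted = ws$effect_allele)
  one <- make_panel(4, K = 2, f = matrix(1, 4, 2), counted = ws$effect_allele)
  expect_true(all(sample_genotypes(lat, zero) == 0))
  expect_true(all(sample_genotypes(lat, one) == 2))

  set.seed(4)
  p <- 2000
  f <- matrix(runif(2 * p, 0.2, 0.8), p, 2)
  panel <- make_panel(p, K = 2, f = f, counted = "A")
  lat2 <- make_lat(matrix(1L, 1, p), matrix(2L, 1, p), c("a1", "a2"))
  g <- sample_genotypes(lat2, panel)
  centered <- g[1, ] - (f[, 1] + f[, 2])
  se <- sqrt(sum(f * (1 - f))) / p
  expect_lt(abs(mean(centered)), 4 * se)
})

test_that("synthetic frequency panels respect their profiles and seed", {
  set.seed(5)
  gen <- synthesize_frequency_panel(200, 3)
  m <- as.matrix(gen[panel_ancestries(gen)])
  expect_true(all(m > 0.05 & m < 0.95))

  enr <- synthesize_frequency_panel(200, 3, profile = "conf_prs2_enriched")
  expect_true(all(enr$a2 >= 0.4 & enr$a2 <= 0.6))
  expect_true(all(enr$a1 >= 0.01 & enr$a1 <= 0.1))

  set.seed(6); x <- synthesize_frequency_panel(10, 3)
  set.seed(6); y <- synthesize_frequency_panel(10, 3)
  expect_identical(x, y)
})

test_that("heterogeneous weights boost each ancestry's top-frequency variants", {
  ws <- make_weights(25, w = rep(0.1, 25))
  f <- matrix(0.5, 25, 3)
  # variants 1-10 top in a2; 5-20 tied top in a3 (overlap 5-10 resolved
  # a2-first, ties by ascending index)
  f[1:10, 2] <- 0.9
  f[5:20, 3] <- 0.8
  panel <- make_panel(25, K = 3, f = f, counted = ws$effect_allele)
  het <- make_heterogeneous_weights(ws, panel)
  expect_equal(which(het$w_a2 == 1.5), 1:10)
  # a3 candidates exclude 5-10 (taken by a2); ties 11..20 then by index
  expect_equal(which(het$w_a3 == 2), 11:20)
  expect_true(all(het$w_a1 == 0.1))

  expect_error(make_heterogeneous_weights(make_weights(15), panel[1:15, ]),
               "at least 20")
})

test_that("confounder kinds produce the documented structure", {
  set.seed(7)
  gam <- sample_global_proportions(10000)
  none <- build_confounder("none", gam)
  expect_equal(none$value, rep(0, 10000))

  lat <- sample_local_ancestry(gam, 100)
  c1 <- build_confounder("conf_prs1", gam, lat_prs = lat)
  expect_equal(length(c1$value), 10000)
  expect_equal(nrow(c1$spec$panel), 100)

  # the strong-stratification confounder tracks a2 ancestry: with N(0,1)
  # weights the correlation's sign is seed-dependent but must be nonzero
  c2 <- build_confounder("conf_prs2", gam)
  ct <- stats::cor.test(c2$value, gam$a2)
  expect_lt(ct$p.value, 0.01)
  expect_gt(abs(ct$estimate), 0.05)

  sv <- build_confounder("single_variant", gam)
  expect_equal(sv$spec$weights, 1)
  expect_true(all(sv$value %in% 0:2))

  expect_error(build_confounder("bogus", gam), "unknown")
  expect_error(build_confounder("conf_prs1", gam), "requires")
})

test_that("outcomes follow the generative regression model", {
  sc <- sim_scenario(n = 500, p = 20, confounder = "conf_prs2", gamma = 1.5,
                     seed = 8)
  prs <- rnorm(500)
  conf <- rnorm(500, sd = 3)
  y0 <- simulate_outcome(prs, conf, sc, error_sd = 0)
  expect_equal(y0, 1 + 1.5 * prs + 1.5 * conf / sd(conf))

  # gamma is ignored when the scenario has no confounder
  sc_none <- sim_scenario(n = 500, p = 20, confounder = "none", seed = 8)
  expect_equal(simulate_outcome(prs, rep(0, 500), sc_none, error_sd = 0),
               1 + 1.5 * prs)
  expect_error(simulate_outcome(prs, rep(1, 500), sc, error_sd = 0),
               "zero variance", class = "eprs_validation_error")

  # OLS on the true design recovers (beta0, beta1, gamma) within 4 SEs
  set.seed(9)
  y <- simulate_outcome(prs, conf, sc)
  fit <- summary(lm(y ~ prs + I(conf / sd(conf))))$coefficients
  for (i in 1:3) {
    expect_lt(abs(fit[i, 1] - c(1, 1.5, 1.5)[i]), 4 * fit[i, 2])
  }
})

test_that("ancestry noise perturbs proportions and labels as specified", {
  set.seed(10)
  gam <- sample_global_proportions(5000)
  expect_identical(inject_ancestry_noise(gam, 0), gam)

  half <- inject_ancestry_noise(gam, 0.5)
  m <- as.matrix(half[-1])
  expect_equal(unname(rowSums(m)), rep(1, 5000), tolerance = 1e-12)

  # level 1 replaces rows by Dirichlet(1,1,1): mean 1/3 per component
  full <- inject_ancestry_noise(gam, 1)
  mf <- as.matrix(full[-1])
  expect_lt(abs(mean(mf[, 1]) - 1 / 3), 4 * sd(mf[, 1]) / sqrt(5000))

  lat <- sample_local_ancestry(gam, 20)
  expect_identical(inject_ancestry_noise(lat, 0, gam), lat)
  noisy <- inject_ancestry_noise(lat, 0.3, gam)
  expect_equal(dim(noisy), dim(lat))
  frac_changed <- mean(noisy != lat)
  # a resampled label can coincide with the old one, so the changed fraction
  # is below 0.3 but well above zero
  expect_gt(frac_changed, 0.05)
  expect_lt(frac_changed, 0.3)
})

test_that("replicates are deterministic and reproducible in isolation", {
  sc <- sim_scenario(n = 200, p = 30, confounder = "conf_prs2", gamma = 1,
                     reps = 3, seed = 11)
  a <- simulate_replicate(sc, 2)
  b <- simulate_replicate(sc, 2)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$conf, b$conf)

  # different replicate index, different draws; same fixed inputs
  c2 <- simulate_replicate(sc, 3)
  expect_false(identical(a$outcome, c2$outcome))
  expect_identical(a$weights, c2$weights)
  expect_identical(a$panel, c2$panel)
})

test_that("heterogeneous weighting changes the generative PRS only", {
  sc <- sim_scenario(n = 300, p = 40, weighting = "heterogeneous", seed = 12)
  sim <- simulate_replicate(sc, 1)
  expect_false(identical(sim$prs, sim$prs_true))

  # hand-check one individual: haplotype-wise weight lookup
  fixed <- eprs:::scenario_fixed_inputs(sc)
  het <- fixed$het_weights
  wmat <- as.matrix(het[paste0("w_", c("a1", "a2", "a3"))])
  h1 <- attr(sim$genotypes, "hap1"); h2 <- attr(sim$genotypes, "hap2")
  i <- 7
  manual <- sum(wmat[cbind(1:40, sim$lat[i, , 1])] * h1[i, ]) +
    sum(wmat[cbind(1:40, sim$lat[i, , 2])] * h2[i, ])
  expect_equal(sim$prs_true[i], manual)
})
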