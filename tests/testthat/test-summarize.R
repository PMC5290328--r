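test_that("regional summary follows the two-step order", {
  # one GCM: median equals its statistic, zero range
  s1 <- regional_summary(c(1, 3, 5), gcm = rep("g1", 3),
                         region = rep("A", 3), zone = rep("stable", 3))
  expect_equal(s1$median, 3)
  expect_equal(s1$gcm_min, 3)
  expect_equal(s1$gcm_max, 3)

  # constructed 3-GCM, 4-cell set: brute-force two-step computation
  set.seed(9)
  vals <- c(g1 = list(c(1, 2, 3, 10)), g2 = list(c(2, 2, 4, 8)),
            g3 = list(c(0, 5, 5, 9)))
  value <- unlist(vals)
  gcm <- rep(c("g1", "g2", "g3"), each = 4)
  s <- regional_summary(value, gcm, region = rep("A", 12),
                        zone = rep("stable", 12))
  step1 <- vapply(vals, median, numeric(1))
  expect_equal(s$median, median(step1))
  expect_equal(s$gcm_min, min(step1))
  expect_equal(s$gcm_max, max(step1))
  expect_equal(s$n_gcm, 3L)

  # the two-step result differs from the pooled shortcut in general
  pooled <- median(value)
  expect_false(isTRUE(all.equal(s$median, pooled)))

  # identical values are invariant to membership
  s2 <- regional_summary(rep(7, 12), gcm, rep(c("A", "B"), 6),
                         zone = rep("stable", 12))
  expect_true(all(s2$median == 7 & s2$gcm_min == 7 & s2$gcm_max == 7))
})

test_that("empty GCM strata are excluded from step two", {
  value <- c(1, 2, 9)
  gcm <- c("g1", "g1", "g2")
  region <- c("A", "A", "B")
  zone <- rep("stable", 3)
  s <- regional_summary(value, gcm, region, zone)
  a <- s[s$region == "A", ]
  expect_equal(a$n_gcm, 1L)            # g2 has no cells in A
  expect_equal(a$median, 1.5)
})

test_that("variance partition attributes pure single-factor signals", {
  d <- expand.grid(cell = 1:6, gcm = paste0("g", 1:4))
  y <- as.numeric(factor(d$gcm)) * 10
  vp <- variance_partition(y, data.frame(gcm = d$gcm, cell = d$cell))
  expect_equal(vp$percent[vp$factor == "gcm"], 100, tolerance = 1e-9)
  expect_equal(vp$percent[vp$factor == "cell"], 0, tolerance = 1e-9)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
})

test_that("balanced additive designs match direct ANOVA sums of squares", {
  d <- expand.grid(region = c("A", "B", "C"), gcm = paste0("g", 1:4))
  f <- c(A = 0, B = 5, C = 9)
  g <- c(g1 = 0, g2 = 1, g3 = -2, g4 = 4)
  y <- f[as.character(d$region)] + g[as.character(d$gcm)]
  vp <- variance_partition(y, d)
  # direct SS for a balanced orthogonal design
  tot <- sum((y - mean(y))^2)
  ss_region <- 4 * sum((tapply(y, d$region, mean) - mean(y))^2)
  ss_gcm <- 3 * sum((tapply(y, d$gcm, mean) - mean(y))^2)
  expect_equal(vp$percent[vp$factor == "region"], 100 * ss_region / tot,
               tolerance = 1e-9)
  expect_equal(vp$percent[vp$factor == "gcm"], 100 * ss_gcm / tot,
               tolerance = 1e-9)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
})

test_that("variance partition components always sum to 100", {
  set.seed(10)
  d <- expand.grid(cell = 1:5, region = c("A", "B"), gcm = c("g1", "g2"),
                   rcp = c("r1", "r2"))
  y <- rnorm(nrow(d))
  vp <- variance_partition(y, d)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
  expect_warning(variance_partition(rep(1, nrow(d)), d), "constant")
})

test_that("the Fuh curve matches a frozen high-precision oracle", {
  # values computed once with 40-digit arithmetic
  expect_equal(fuh_curve(2, 2.6), 0.87904649891427302, tolerance = 1e-12)
  expect_equal(fuh_curve(0.5, 3.0), 0.45995808847404794, tolerance = 1e-12)
  expect_equal(fuh_curve(5, 1.7), 0.81180452620718514, tolerance = 1e-12)
  expect_equal(fuh_curve(0, 2.6), 0)
  expect_equal(fuh_curve(c(0.3, 1, 4), 1), rep(0, 3))
  expect_error(fuh_curve(1, -2), "omega")
})

test_that("omega is recovered from clean and noisy synthetic cells", {
  set.seed(11)
  ai_b <- runif(50, 0.5, 6)
  p <- runif(50, 150, 500)
  f_true <- fuh_curve(ai_b, 3.0)
  fit <- fit_omega(aet = f_true * p, pet = ai_b * p, p = p)
  expect_lt(abs(fit$omega - 3.0), 1e-6)

  # SSE at the optimum is no worse than a 0.01-step grid scan
  grid <- seq(1.01, 20, by = 0.01)
  sse_grid <- vapply(grid, function(om)
    sum((f_true - fuh_curve(ai_b, om))^2), numeric(1))
  expect_lte(fit$sse, min(sse_grid) + 1e-12)

  noisy <- f_true * exp(rnorm(50, 0, 0.02))
  fit2 <- fit_omega(noisy * p, ai_b * p, p)
  expect_lt(abs(fit2$omega - 3.0), 0.15)
  expect_error(fit_omega(1:2, 1:2, 1:2), "3 cells")
})

test_that("lambda satisfies its agreement-index contract", {
  set.seed(12)
  x <- rnorm(40, 10, 3)
  expect_equal(duveiller_lambda(x, x), 1)
  y <- x + rnorm(40, 0, 1)
  expect_equal(duveiller_lambda(x, y), duveiller_lambda(y, x))
  l0 <- duveiller_lambda(x, y)
  expect_true(l0 >= 0 && l0 <= 1)
  # constant offset strictly decreases agreement
  expect_lt(duveiller_lambda(x, y + 2), l0)
  # more noise decreases agreement
  expect_lt(duveiller_lambda(x, x + rnorm(40, 0, 6)),
            duveiller_lambda(x, x + rnorm(40, 0, 0.1)))
  expect_true(is.na(duveiller_lambda(rep(1, 5), rep(3, 5))))
  expect_error(duveiller_lambda(1:3, 1:4), "equal length")
})

test_that("simulated cells respect the Budyko limits", {
  # F <= min(1, AI_b) holds at steady state; a finite window carries a small
  # soil-storage imbalance, so allow ~3% on the water limit (storage cycling
  # of a few tens of mm against multi-year precipitation totals)
  for (seed in c(31, 32)) {
    sim <- tiny_sim(years = 6, seed = seed)
    keep <- sim$year > min(sim$year)
    p_tot <- sum(sim$fluxes$precip[keep])
    aet_tot <- sum(sim$fluxes$evap[keep] + sim$fluxes$transp[keep] +
                     sim$fluxes$interception[keep])
    pet_tot <- sum(sim$fluxes$pet[keep])
    f <- aet_tot / p_tot
    ai_b <- pet_tot / p_tot
    expect_lte(f, min(1.03, ai_b))
  }
})
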