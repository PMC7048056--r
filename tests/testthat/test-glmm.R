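test_that("with variances fixed at zero the fit matches plain IRLS regression", {
  set.seed(99)
  sam <- make_sample_frame(8, n_occasions = 2)
  n <- nrow(sam)
  tot <- rep(5000L, n)
  eta <- c(plaque = -3, buccal = -2.5, tongue = -2.2, saliva = -4)[sam$niche]
  y <- rbinom(n, tot, plogis(eta))
  f0 <- fit_binomial_glmm(y, tot, sam, var_fixed = c(0, 0))
  nf <- factor(sam$niche, levels = NICHES)
  g <- glm(cbind(y, tot - y) ~ 0 + nf, family = binomial)
  expect_lt(max(abs(unname(coef(f0)) - unname(coef(g)))), 1e-3)
  expect_true(f0$converged)
  expect_equal(f0$var_dog, 0)
  expect_equal(f0$var_day, 0)
})

test_that("estimated variances stay near zero when data carry none", {
  set.seed(100)
  sam <- make_sample_frame(8, n_occasions = 2)
  tot <- rep(5000L, nrow(sam))
  y <- rbinom(nrow(sam), tot, plogis(-3))
  f <- fit_binomial_glmm(y, tot, sam)
  expect_true(f$converged)
  expect_lt(f$var_dog, 0.02)
  expect_lt(f$var_day, 0.02)
  nf <- factor(sam$niche, levels = NICHES)
  g <- glm(cbind(y, tot - y) ~ 0 + nf, family = binomial)
  expect_lt(max(abs(unname(coef(f)) - unname(coef(g)))), 0.05)
})

test_that("two-group odds ratio matches the closed form", {
  sam2 <- data.frame(sample_id = c("a", "b"), dog_id = c("D1", "D2"),
                     niche = c("plaque", "buccal"), occasion = c(1, 1),
                     side = "none")
  f <- fit_binomial_glmm(c(30, 10), c(100, 100), sam2, var_fixed = c(0, 0))
  ctr <- pairwise_contrasts(f)
  expect_equal(ctr$odds_ratio, (30 / 70) / (10 / 90), tolerance = 0.01)
  expect_equal(ctr$odds_ratio, exp(ctr$log_odds_diff))
  expect_true(ctr$ci_lo < ctr$odds_ratio & ctr$odds_ratio < ctr$ci_hi)
})

test_that("the animal variance component is recovered across replicates", {
  set.seed(7)
  dogs <- sprintf("D%02d", 1:14)
  sam <- make_sample_frame(14, reps = c(plaque = 2, buccal = 2, tongue = 1, saliva = 1))
  rec <- replicate(50, {
    u <- rnorm(14, 0, 0.5)
    v <- rnorm(3, 0, 0.25)
    eta <- -3 + u[match(sam$dog_id, dogs)] + v[sam$occasion]
    tot <- rep(10000L, nrow(sam))
    y <- rbinom(nrow(sam), tot, plogis(eta))
    fit_binomial_glmm(y, tot, sam)$var_dog
  })
  expect_lt(abs(mean(rec) - 0.25), 0.05)   # within 20% of sigma_dog^2
})

test_that("fit agrees with an independent Laplace GLMM implementation", {
  sim <- small_sim(seed = 3)
  qc <- exclude_low_count_samples(sim$counts, sim$samples)
  sam <- qc$samples[match(colnames(qc$counts), qc$samples$sample_id), ]
  tot <- colSums(qc$counts)
  y <- as.integer(qc$counts[2, ])   # abundant taxon, no separation
  f <- fit_binomial_glmm(y, tot, sam)
  dfm <- data.frame(y = y, tot = tot, niche = factor(sam$niche, levels = NICHES),
                    dog = sam$dog_id, occ = sam$occasion)
  gm <- suppressMessages(lme4::glmer(
    cbind(y, tot - y) ~ 0 + niche + (1 | dog) + (1 | occ),
    data = dfm, family = binomial))
  expect_equal(unname(coef(f)), unname(lme4::fixef(gm)), tolerance = 0.02)
  # the two Laplace schemes differ in how beta enters the profiled deviance,
  # so variance components agree only approximately
  vc <- unname(vapply(lme4::VarCorr(gm), function(v) v[1], numeric(1)))
  expect_equal(f$var_dog, vc[1], tolerance = 0.2)
})

test_that("input validation rejects degenerate designs", {
  sam1 <- data.frame(sample_id = c("a", "b"), dog_id = "D1", niche = "plaque",
                     occasion = 1, side = "left")
  expect_error(fit_binomial_glmm(c(1, 2), c(10, 10), sam1), "two niches")
  sam2 <- data.frame(sample_id = c("a", "b"), dog_id = "D1",
                     niche = c("plaque", "buccal"), occasion = 1, side = "none")
  expect_error(fit_binomial_glmm(c(1, 2), c(10, 0), sam2), "positive")
  expect_error(fit_binomial_glmm(c(11, 2), c(10, 10), sam2), "0, total")
})

test_that("accessor methods are coherent", {
  sim <- small_sim(seed = 3)
  qc <- exclude_low_count_samples(sim$counts, sim$samples)
  sam <- qc$samples[match(colnames(qc$counts), qc$samples$sample_id), ]
  tot <- colSums(qc$counts)
  f <- fit_binomial_glmm(as.integer(qc$counts[1, ]), tot, sam)
  expect_named(coef(f), NICHES)
  expect_identical(dim(vcov(f)), c(4L, 4L))
  expect_length(fitted(f), ncol(qc$counts))
  expect_true(all(fitted(f) > 0 & fitted(f) < 1))
  expect_length(residuals(f), ncol(qc$counts))
  expect_true(all(f$niche_means$ci_lo <= f$niche_means$mean_proportion &
                    f$niche_means$mean_proportion <= f$niche_means$ci_hi))
  expect_output(print(f), "GLMM")
  expect_output(print(summary(f)), "odds ratios")
})
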