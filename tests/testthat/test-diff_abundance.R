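test_that("BH adjustment matches hand step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone in the order statistics and never below the raw p
  set.seed(2)
  p <- runif(50)
  a <- bh_adjust(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_true(all(a >= p))
  # fixed points: fully tied adjusted vectors re-adjust to themselves
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("category aggregation sums counts and drops unknowns", {
  m <- rbind(o1 = c(3, 5), o2 = c(1, 2), o3 = c(7, 1), o4 = c(2, 2))
  colnames(m) <- c("s1", "s2")
  taxa <- data.frame(otu_id = rownames(m),
                     phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", "Firmicutes"),
                     gram = c("positive", "positive", "unknown", "negative"),
                     oxygen = "unknown", stringsAsFactors = FALSE)
  ag <- aggregate_counts(count_table(m), taxa, "phylum")
  expect_equal(unname(ag["Firmicutes", ]), c(6L, 9L))
  expect_equal(unname(ag["Bacteroidetes", ]), c(7L, 1L))
  ag2 <- aggregate_counts(count_table(m), taxa, "gram")
  expect_equal(sort(rownames(ag2)), c("negative", "positive"))
  expect_equal(unname(ag2["positive", ]), c(4L, 7L))
  expect_error(aggregate_counts(count_table(m), taxa, "oxygen"), "unknown")
})

test_that("differential pipeline returns a coherent result object", {
  sim <- small_sim(seed = 3, n_dogs = 5, n_otus = 15)
  pp <- preprocess(sim$counts, sim$samples, sim$taxa)
  da <- diff_abundance(pp$counts, pp$samples, n_perm = 19, seed = 5,
                       control = list(nm_reltol = 1e-5))
  r <- da$results
  expect_equal(sort(unique(r$pair)),
               sort(nichecompare:::.niche_pairs(NICHES)$pair))
  expect_equal(nrow(r), nrow(pp$counts) * 6)
  expect_true(all(r$perm_p >= 1 / 20 & r$perm_p <= 1))
  expect_true(all(r$adj_p >= r$perm_p - 1e-12))
  expect_equal(r$odds_ratio, exp(r$log_odds_diff))
  expect_true(all(r$ci_lo <= r$odds_ratio & r$odds_ratio <= r$ci_hi))
  ps <- pairwise_summary(da)
  expect_equal(ps$n_units, rep(nrow(pp$counts), 6))
  expect_output(print(da), "Differential abundance")
})

test_that("pairwise summary counts only adjusted-significant units", {
  fake <- structure(list(
    results = data.frame(unit = rep(c("u1", "u2"), each = 2),
                         pair = rep(c("plaque-buccal", "plaque-tongue"), 2),
                         perm_p = c(0.001, 0.2, 0.5, 1),
                         adj_p = c(0.004, 0.4, 1, 1)),
    n_units = 2L, alpha = 0.05), class = "niche_diff")
  ps <- pairwise_summary(fake)
  expect_equal(ps$n_significant[ps$pair == "plaque-buccal"], 1L)
  expect_equal(ps$n_significant[ps$pair == "plaque-tongue"], 0L)
  expect_equal(pairwise_summary(fake, alpha = 1e-6)$n_significant, c(0L, 0L))
})

test_that("a planted Gram-positive shift in plaque is detected at category level", {
  K <- 20
  base <- niche_profile_ranked(K, 1)
  gram <- rep(c("positive", "negative"), length.out = K)
  prof <- matrix(base, K, 4, dimnames = list(sprintf("OTU%04d", 1:K), NICHES))
  boost <- plogis(qlogis(base) + ifelse(gram == "positive", 0.7, 0))
  prof[, "plaque"] <- boost / sum(boost)   # Gram-positive odds doubled in plaque
  cfg <- sim_config(n_dogs = 10, n_otus = K, niche_profiles = prof,
                    dirichlet_concentration = c(plaque = 200, buccal = 200,
                                                tongue = 200, saliva = 200),
                    missing_saliva = 0,
                    fail_amp = c(plaque = 0, buccal = 0, tongue = 0, saliva = 0),
                    low_count = c(plaque = 0, buccal = 0, tongue = 0, saliva = 0))
  sim <- simulate_dataset(cfg, seed = 17)
  taxa <- sim$taxa
  taxa$gram <- gram
  da <- diff_abundance(sim$counts, sim$samples, taxa, level = "gram",
                       n_perm = 99, seed = 29, control = list(nm_reltol = 1e-5))
  pos <- da$results[da$results$unit == "positive" &
                      da$results$pair == "plaque-buccal", ]
  expect_gt(pos$odds_ratio, 1.5)
  expect_lt(pos$adj_p, 0.05)
})

test_that("aggregation-level pipeline refuses all-unknown annotations", {
  sim <- small_sim(seed = 3, n_dogs = 4, n_otus = 10)
  taxa <- sim$taxa
  taxa$gram <- "unknown"
  expect_error(diff_abundance(sim$counts, sim$samples, taxa, level = "gram",
                              n_perm = 9, seed = 1), "unknown")
})
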