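test_that("default design yields the study's sample bookkeeping", {
  sim <- simulate_dataset(sim_config(), seed = 1)
  expect_equal(nrow(sim$samples), 251L)
  expect_equal(sum(sim$samples$amplified), 243L)
  expect_equal(ncol(sim$counts), 243L)
  expect_equal(nrow(sim$counts), 224L)
  # forced sub-threshold depths occur exactly where configured
  tot <- sim$samples$total_reads[sim$samples$amplified]
  expect_equal(sum(tot < 1000), 5L)
  low <- sim$samples[!is.na(sim$samples$total_reads) & sim$samples$total_reads < 1000, ]
  expect_equal(unname(table(factor(low$niche, levels = NICHES))[c(1, 3, 4)]),
               c(2L, 1L, 2L), ignore_attr = TRUE)
  # column totals equal the drawn depths
  expect_equal(unname(colSums(sim$counts)),
               sim$samples$total_reads[match(colnames(sim$counts),
                                             sim$samples$sample_id)])
})

test_that("the same seed reproduces the dataset byte for byte", {
  a <- simulate_dataset(sim_config(n_dogs = 4, n_otus = 30), seed = 9)
  b <- simulate_dataset(sim_config(n_dogs = 4, n_otus = 30), seed = 9)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$samples, b$samples)
  d <- simulate_dataset(sim_config(n_dogs = 4, n_otus = 30), seed = 10)
  expect_false(identical(unclass(a$counts), unclass(d$counts)))
})

test_that("empirical niche means recover the profiles without noise sources", {
  # no random intercepts, near-degenerate Dirichlet: only multinomial noise
  K <- 40
  cfg <- sim_config(n_dogs = 12, n_otus = K, sigma_dog = 0, sigma_day = 0,
                    dirichlet_concentration = c(plaque = 1e7, buccal = 1e7,
                                                tongue = 1e7, saliva = 1e7),
                    missing_saliva = 0,
                    fail_amp = c(plaque = 0, buccal = 0, tongue = 0, saliva = 0),
                    low_count = c(plaque = 0, buccal = 0, tongue = 0, saliva = 0))
  sim <- simulate_dataset(cfg, seed = 21)
  prop <- to_proportions(sim$counts)
  sam <- sim$samples
  for (nn in NICHES) {
    cols <- which(sam$niche[match(colnames(prop), sam$sample_id)] == nn)
    est <- rowMeans(prop[, cols, drop = FALSE])
    se <- apply(prop[, cols, drop = FALSE], 1L, sd) / sqrt(length(cols))
    diff <- abs(est - cfg$niche_profiles[, nn])
    expect_true(all(diff <= 3 * se + 1e-5),
                info = sprintf("niche %s, max standardized dev %.2f", nn,
                               max(diff / (se + 1e-12))))
  }
})

test_that("degenerate designs produce empty outputs", {
  sim <- simulate_dataset(sim_config(n_dogs = 0), seed = 1)
  expect_equal(ncol(sim$counts), 0L)
  expect_equal(nrow(sim$samples), 0L)
  expect_equal(nrow(sim$truth$differential), 0L)
})

test_that("null datasets have no differential truth and shared profiles", {
  nd <- null_dataset(sim_config(n_dogs = 4, n_otus = 30), seed = 2)
  expect_equal(nrow(nd$truth$differential), 0L)
  prof <- nd$truth$profiles
  for (nn in NICHES) expect_equal(prof[, nn], prof[, "buccal"])
  nd2 <- null_dataset(sim_config(n_dogs = 4, n_otus = 30), seed = 3)
  expect_identical(nd$truth$profiles, nd2$truth$profiles)
  expect_false(identical(unclass(nd$counts), unclass(nd2$counts)))
})

test_that("planted effects appear in the exported truth", {
  eff <- data.frame(otu = c("OTU0003", "OTU0007"), niche_a = "plaque",
                    niche_b = "buccal", log_odds = c(0.7, 1.4))
  cfg <- flat_config(n_otus = 20, n_dogs = 4, effect_otus = eff)
  sim <- simulate_dataset(cfg, seed = 4)
  expect_equal(sim$truth$differential$otu, eff$otu)
  expect_equal(sim$truth$differential$log_odds, eff$log_odds)
})

test_that("saliva is the most variable niche between dogs", {
  sim <- simulate_dataset(sim_config(), seed = 31)
  qc <- exclude_low_count_samples(sim$counts, sim$samples)
  prop <- to_proportions(qc$counts)
  sam <- qc$samples[match(colnames(prop), qc$samples$sample_id), ]
  dog_dist <- sapply(NICHES, function(nn) {
    cols <- which(sam$niche == nn)
    dm <- rowsum(t(prop[, cols, drop = FALSE]), sam$dog_id[cols])
    dm <- dm / as.vector(table(sam$dog_id[cols]))
    mean(dist(dm))
  })
  expect_true(dog_dist[["saliva"]] > max(dog_dist[c("plaque", "buccal", "tongue")]))
})

test_that("datasets round trip through a directory of TSVs", {
  sim <- small_sim(seed = 12)
  dir <- tempfile()
  write_dataset(sim, dir)
  ct <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(unclass(ct), unclass(sim$counts))
  sam <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_equal(sam$sample_id, sim$samples$sample_id)
})
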