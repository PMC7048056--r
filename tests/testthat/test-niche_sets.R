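# one sample per niche keeps per-niche means equal to the sample proportions
.one_per_niche <- function() {
  data.frame(sample_id = NICHES, dog_id = "D01", niche = NICHES,
             occasion = 1L,
             side = ifelse(NICHES %in% c("plaque", "buccal"), "left", "none"),
             stringsAsFactors = FALSE)
}

test_that("presence uses a strict inequality and exclusive intersections", {
  sam <- .one_per_niche()
  m <- rbind(exact = rep(0.005, 4),       # exactly the threshold -> absent
             everywhere = rep(0.006, 4))  # above everywhere -> 4-way cell only
  m <- rbind(m, filler = 1 - colSums(m))
  colnames(m) <- NICHES
  um <- upset_membership(m, sam)
  expect_false(any(um$presence["exact", ]))
  expect_true(all(um$presence["everywhere", ]))
  inter <- um$intersections
  # "everywhere" and the filler row both land in the 4-way exclusive cell only
  expect_equal(inter$n_otus[inter$combination == "plaque&buccal&tongue&saliva"], 2L)
  expect_equal(sum(inter$n_otus[inter$degree < 4]), 0L)
  expect_equal(sum(inter$n_otus), sum(rowSums(um$presence) > 0))
})

test_that("exclusive intersection counts match a power-set oracle", {
  set.seed(14)
  sam <- make_sample_frame(3)
  m <- matrix(rgamma(20 * nrow(sam), 0.6), 20, nrow(sam),
              dimnames = list(sprintf("OTU%02d", 1:20), sam$sample_id))
  prop <- sweep(m, 2, colSums(m), `/`)
  um <- upset_membership(prop, sam, threshold = 0.05)

  pres <- sapply(NICHES, function(nn)
    rowMeans(prop[, sam$niche == nn, drop = FALSE]) > 0.05)
  for (i in seq_len(nrow(um$intersections))) {
    combo <- strsplit(um$intersections$combination[i], "&", fixed = TRUE)[[1]]
    oracle <- sum(apply(pres, 1, function(r) all(r == (NICHES %in% combo))))
    expect_equal(um$intersections$n_otus[i], oracle)
  }
  expect_equal(sum(um$intersections$n_otus), sum(rowSums(pres) > 0))
})

test_that("set membership is invariant to sample and OTU order", {
  set.seed(15)
  sam <- make_sample_frame(2)
  m <- matrix(rgamma(12 * nrow(sam), 0.8), 12, nrow(sam),
              dimnames = list(sprintf("OTU%02d", 1:12), sam$sample_id))
  prop <- sweep(m, 2, colSums(m), `/`)
  u1 <- upset_membership(prop, sam, threshold = 0.05)
  ps <- sample(ncol(prop)); po <- sample(nrow(prop))
  u2 <- upset_membership(prop[po, ps], sam, threshold = 0.05)
  expect_equal(u1$presence[order(rownames(u1$presence)), ],
               u2$presence[order(rownames(u2$presence)), ])
  expect_equal(u1$intersections[order(u1$intersections$combination), "n_otus"],
               u2$intersections[order(u2$intersections$combination), "n_otus"])
})

test_that("core detection is inclusive and prevalence uses a ceiling", {
  # 41 samples in one niche
  sam <- data.frame(sample_id = paste0("s", 1:41), dog_id = "D01",
                    niche = "saliva", occasion = 1L, side = "none")
  m <- matrix(0, 3, 41, dimnames = list(c("always", "thirty", "never"), sam$sample_id))
  m["always", ] <- 0.005                       # exactly at detection -> core
  m["thirty", 1:30] <- 0.02                    # 30 of 41 samples
  m["never", ] <- 0.001
  m <- rbind(m, filler = 1 - colSums(m))
  core <- core_microbiota(m, sam, prevalence = c(1, 0.75, 0.5))
  sal <- core$per_niche$saliva
  expect_true("always" %in% sal$prev_1)
  expect_false("thirty" %in% sal$prev_0.75)    # needs ceiling(0.75*41) = 31
  expect_true("thirty" %in% sal$prev_0.5)      # 30 >= ceiling(0.5*41) = 21
  expect_false("never" %in% sal$prev_0.5)
  # prevalence lists are nested
  expect_true(all(sal$prev_1 %in% sal$prev_0.75))
  expect_true(all(sal$prev_0.75 %in% sal$prev_0.5))
  expect_error(core_microbiota(m, sam, prevalence = 0), "prevalence")
})

test_that("raising the detection threshold never grows a core list", {
  sim <- small_sim(seed = 22)
  qc <- exclude_low_count_samples(sim$counts, sim$samples)
  prop <- to_proportions(qc$counts)
  sam <- qc$samples
  lo <- core_microbiota(prop, sam, detection = 0.002)
  hi <- core_microbiota(prop, sam, detection = 0.01)
  for (nn in names(lo$per_niche)) for (q in names(lo$per_niche[[nn]])) {
    expect_true(all(hi$per_niche[[nn]][[q]] %in% lo$per_niche[[nn]][[q]]))
  }
  for (q in names(lo$cross_niche))
    expect_true(all(hi$cross_niche[[q]] %in% lo$cross_niche[[q]]))
})

test_that("cross-niche core equals a per-sample brute-force count", {
  set.seed(16)
  sam <- make_sample_frame(2)
  m <- matrix(rgamma(8 * nrow(sam), 1), 8, nrow(sam),
              dimnames = list(sprintf("OTU%02d", 1:8), sam$sample_id))
  prop <- sweep(m, 2, colSums(m), `/`)
  core <- core_microbiota(prop, sam, detection = 0.1, prevalence = 0.5)
  oracle <- rownames(prop)[rowSums(prop >= 0.1) >= ceiling(0.5 * ncol(prop))]
  expect_setequal(core$cross_niche$prev_0.5, oracle)
})
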