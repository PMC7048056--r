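#' Ranked (power-law) community profile
#'
#' Deterministic expected composition with abundances proportional to
#' `rank^-gamma`: small `gamma` gives an even (diverse) community, large
#' `gamma` a steep, concentrated one.
#'
#' @param n_otus number of taxa.
#' @param gamma positive decay exponent of the rank-abundance curve.
#' @return numeric vector of length `n_otus` summing to 1 (taxon `i` holds
#'   rank `i`).
#' @export
niche_profile_ranked <- function(n_otus, gamma) {
  stopifnot(n_otus >= 1, gamma > 0)
  w <- (seq_len(n_otus))^(-gamma)
  w / sum(w)
}

#' Default niche composition profiles
#'
#' Builds four deterministic expected compositions over a shared taxon panel
#' that reproduce the qualitative structure of the canine oral niches:
#' supragingival plaque is the most even (most diverse) and has a partially
#' distinct set of dominant taxa; buccal and tongue dorsum mucosa are
#' near-identical; saliva is the steepest (least diverse) with its own
#' dominant set drawn from taxa that are minor elsewhere. A low-abundance tail is shared by all niches: the last ~8%
#' of taxa sit below typical rare-grouping cutoffs in every niche, and the
#' last ~2% are essentially absent (exercising the presence-based rare rule).
#'
#' @param n_otus number of taxa (>= 10).
#' @return an `n_otus x 4` matrix of per-niche profiles, columns named by
#'   [NICHES], each column summing to 1.
#' @export
default_niche_profiles <- function(n_otus = 224) {
  stopifnot(n_otus >= 10)
  K <- n_otus
  rot <- function(m) c((m + 1):K, seq_len(m))        # taxon order by rank
  swap_pairs <- function() {
    o <- seq_len(K)
    k <- seq(1L, K - 1L, by = 2L)
    o[c(k, k + 1L)] <- o[c(k + 1L, k)]
    o
  }
  orders <- list(
    plaque = rot(max(1L, round(0.05 * K))),
    buccal = seq_len(K),
    tongue = swap_pairs(),
    saliva = rot(max(2L, round(0.30 * K)))
  )
  gammas <- c(plaque = 0.85, buccal = 1.05, tongue = 1.05, saliva = 1.45)
  damp1 <- seq_len(K) > floor(0.92 * K)   # below rare cutoff everywhere
  damp2 <- seq_len(K) > floor(0.98 * K)   # essentially absent
  prof <- sapply(NICHES, function(nn) {
    w <- niche_profile_ranked(K, gammas[[nn]])
    p <- numeric(K)
    p[orders[[nn]]] <- w                   # taxon orders[[nn]][j] has rank j
    p[damp1] <- p[damp1] * 0.02
    p[damp2] <- p[damp2] * 1e-6
    p / sum(p)
  })
  rownames(prof) <- sprintf("OTU%04d", seq_len(K))
  prof
}

#' Simulation configuration
#'
#' Defines the study design and generative parameters of the synthetic
#' dataset. Defaults mirror the repeated-measures design of the motivating
#' study: 14 dogs sampled on 3 occasions, duplicate left/right samples for
#' plaque and buccal mucosa, single samples for tongue and saliva, one
#' never-collected saliva sample, 8 amplification failures (2 buccal,
#' 6 tongue) and 5 forced low-depth samples (2 plaque, 1 tongue, 2 saliva).
#'
#' Counts are generated hierarchically: for each sample a composition is
#' drawn from a Dirichlet centred on the niche profile after logit-scale
#' perturbation by per-dog and per-occasion random intercepts (and any
#' planted taxon effects), and reads are drawn multinomially at a log-normal
#' depth. Replicate left/right samples share the dog/day intercepts but are
#' otherwise independent draws, so niche labels are exchangeable within dog
#' under the null.
#'
#' @param n_dogs,n_occasions,n_otus design dimensions.
#' @param depth_log_mean,depth_log_sd meanlog/sdlog of the log-normal read
#'   depth (reads); depths are floored at `qc_threshold` so that sub-threshold
#'   depths occur only where forced by `low_count`.
#' @param dirichlet_concentration named per-niche Dirichlet precision; lower
#'   values give more sample-to-sample compositional noise (saliva default is
#'   lowest, making it the most variable niche).
#' @param niche_profiles `n_otus x 4` matrix of expected compositions
#'   (columns ordered as [NICHES], each summing to 1).
#' @param effect_otus `NULL` or a data frame with columns `otu`, `niche_a`,
#'   `niche_b`, `log_odds`: taxon `otu` is shifted by `+log_odds/2` on the
#'   logit scale in `niche_a` and `-log_odds/2` in `niche_b`, so the a-vs-b
#'   contrast equals `log_odds`.
#' @param sigma_dog,sigma_day standard deviations (logit scale) of the
#'   per-dog-per-taxon and per-occasion-per-taxon random intercepts.
#' @param missing_saliva number of saliva samples never collected.
#' @param fail_amp named per-niche counts of amplification failures.
#' @param low_count named per-niche counts of forced sub-threshold samples.
#' @param qc_threshold read-depth exclusion threshold (default 1000).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_dogs = 14, n_occasions = 3, n_otus = 224,
                       depth_log_mean = log(13000), depth_log_sd = 0.6,
                       dirichlet_concentration = c(plaque = 300, buccal = 150,
                                                   tongue = 150, saliva = 1),
                       niche_profiles = default_niche_profiles(n_otus),
                       effect_otus = NULL,
                       sigma_dog = 0.5, sigma_day = 0.25,
                       missing_saliva = 1,
                       fail_amp = c(plaque = 0, buccal = 2, tongue = 6, saliva = 0),
                       low_count = c(plaque = 2, buccal = 0, tongue = 1, saliva = 2),
                       qc_threshold = 1000) {
  if (!is.matrix(niche_profiles) || nrow(niche_profiles) != n_otus ||
      ncol(niche_profiles) != 4L)
    stop("niche_profiles must be an n_otus x 4 matrix")
  if (is.null(colnames(niche_profiles))) colnames(niche_profiles) <- NICHES
  if (!all(abs(colSums(niche_profiles) - 1) < 1e-8))
    stop("each niche profile must sum to 1")
  if (any(niche_profiles < 0)) stop("niche profiles must be non-negative")
  stopifnot(sigma_dog >= 0, sigma_day >= 0,
            all(dirichlet_concentration > 0),
            all(names(dirichlet_concentration) == NICHES),
            all(names(fail_amp) == NICHES), all(names(low_count) == NICHES))
  if (!is.null(effect_otus)) {
    need <- c("otu", "niche_a", "niche_b", "log_odds")
    if (!all(need %in% names(effect_otus)))
      stop("effect_otus needs columns: ", paste(need, collapse = ", "))
    if (!all(effect_otus$otu %in% rownames(niche_profiles)))
      stop("effect_otus refers to unknown OTU identifiers")
    if (!all(c(effect_otus$niche_a, effect_otus$niche_b) %in% NICHES))
      stop("effect_otus niches must be in NICHES")
  }
  structure(list(
    n_dogs = n_dogs, n_occasions = n_occasions, n_otus = n_otus,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    dirichlet_concentration = dirichlet_concentration,
    niche_profiles = niche_profiles, effect_otus = effect_otus,
    sigma_dog = sigma_dog, sigma_day = sigma_day,
    missing_saliva = missing_saliva, fail_amp = fail_amp,
    low_count = low_count, qc_threshold = qc_threshold
  ), class = "sim_config")
}

.planned_samples <- function(cfg) {
  rows <- list()
  for (d in seq_len(cfg$n_dogs)) {
    dog <- sprintf("D%02d", d)
    for (t in seq_len(cfg$n_occasions)) {
      for (nn in NICHES) {
        sides <- if (nn %in% c("plaque", "buccal")) c("left", "right") else "none"
        for (s in sides) {
          suffix <- switch(s, left = ".L", right = ".R", "")
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s.O%d.%s%s", dog, t, nn, suffix),
            dog_id = dog, niche = nn, occasion = t, side = s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a synthetic oral-niche dataset
#'
#' Generates an OTU count table, sample metadata, taxon annotations and the
#' ground truth of the generative model (profiles, realized random intercepts,
#' planted differential effects) under a [sim_config()] design. All sources of
#' randomness derive from `seed`; the same seed yields byte-identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return a list of class `"niche_sim"` with elements `counts`
#'   ([count_table()] over amplified samples), `samples` (metadata for all
#'   collected samples, with `amplified`, `total_reads`, `qc_pass`), `taxa`
#'   (annotation data frame) and `truth` (class `"sim_truth"`).
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_otus
  otu_ids <- rownames(cfg$niche_profiles)
  taxa <- .default_taxa(otu_ids)
  if (cfg$n_dogs == 0L) {
    counts <- matrix(integer(), K, 0, dimnames = list(otu_ids, character(0)))
    samples <- data.frame(sample_id = character(), dog_id = character(),
                          niche = character(), occasion = integer(),
                          side = character(), amplified = logical(),
                          total_reads = integer(), qc_pass = logical(),
                          stringsAsFactors = FALSE)
    truth <- structure(list(profiles = cfg$niche_profiles,
                            dog_intercepts = matrix(0, 0, K),
                            day_intercepts = matrix(0, 0, K),
                            differential = .truth_differential(cfg),
                            config = cfg, seed = seed),
                       class = "sim_truth")
    return(structure(list(counts = counts, samples = samples, taxa = taxa,
                          truth = truth), class = "niche_sim"))
  }
  set.seed(as.integer(seed))
  samples <- .planned_samples(cfg)

  # never-collected saliva sample(s): removed from the collected set
  if (cfg$missing_saliva > 0) {
    sal <- which(samples$niche == "saliva")
    drop <- sal[sample.int(length(sal), cfg$missing_saliva)]
    samples <- samples[-drop, , drop = FALSE]
  }
  # amplification failures, per niche, at seeded positions
  samples$amplified <- TRUE
  for (nn in NICHES) {
    k <- cfg$fail_amp[[nn]]
    if (k > 0) {
      idx <- which(samples$niche == nn)
      samples$amplified[idx[sample.int(length(idx), k)]] <- FALSE
    }
  }
  # forced low-depth samples among the amplified, per niche
  samples$force_low <- FALSE
  for (nn in NICHES) {
    k <- cfg$low_count[[nn]]
    if (k > 0) {
      idx <- which(samples$niche == nn & samples$amplified)
      samples$force_low[idx[sample.int(length(idx), k)]] <- TRUE
    }
  }

  U <- matrix(rnorm(cfg$n_dogs * K, 0, cfg$sigma_dog), cfg$n_dogs, K,
              dimnames = list(sprintf("D%02d", seq_len(cfg$n_dogs)), otu_ids))
  V <- matrix(rnorm(cfg$n_occasions * K, 0, cfg$sigma_day), cfg$n_occasions, K,
              dimnames = list(sprintf("O%d", seq_len(cfg$n_occasions)), otu_ids))

  eff <- cfg$effect_otus
  base_logit <- qlogis(pmin(pmax(cfg$niche_profiles, 1e-12), 1 - 1e-12))

  # Dirichlet mean per (dog, occasion, niche); the composition itself is
  # drawn per sample, so left/right replicates share the intercepts only
  means <- vector("list", cfg$n_dogs * cfg$n_occasions * 4L)
  dim(means) <- c(cfg$n_dogs, cfg$n_occasions, 4L)
  for (d in seq_len(cfg$n_dogs)) for (t in seq_len(cfg$n_occasions)) {
    for (v in seq_along(NICHES)) {
      nn <- NICHES[v]
      eta <- base_logit[, nn] + U[d, ] + V[t, ]
      if (!is.null(eff)) {
        ia <- which(eff$niche_a == nn)
        if (length(ia)) eta[eff$otu[ia]] <- eta[eff$otu[ia]] + eff$log_odds[ia] / 2
        ib <- which(eff$niche_b == nn)
        if (length(ib)) eta[eff$otu[ib]] <- eta[eff$otu[ib]] - eff$log_odds[ib] / 2
      }
      m <- plogis(eta)
      means[[d, t, v]] <- m / sum(m)
    }
  }

  amp <- which(samples$amplified)
  counts <- matrix(0L, K, length(amp),
                   dimnames = list(otu_ids, samples$sample_id[amp]))
  totals <- integer(length(amp))
  for (j in seq_along(amp)) {
    i <- amp[j]
    depth <- if (samples$force_low[i]) {
      sample.int(cfg$qc_threshold - 100L, 1L) + 99L      # 100 .. threshold-1
    } else {
      max(cfg$qc_threshold,
          round(exp(rnorm(1, cfg$depth_log_mean, cfg$depth_log_sd))))
    }
    d <- match(samples$dog_id[i], rownames(U))
    t <- samples$occasion[i]
    v <- match(samples$niche[i], NICHES)
    m <- means[[d, t, v]]
    g <- rgamma(K, shape = cfg$dirichlet_concentration[[samples$niche[i]]] * m)
    comp <- if (sum(g) > 0) g / sum(g) else m
    counts[, j] <- as.integer(rmultinom(1, depth, comp))
    totals[j] <- depth
  }
  samples$force_low <- NULL
  samples$total_reads <- NA_integer_
  samples$total_reads[amp] <- totals
  samples$qc_pass <- samples$amplified & !is.na(samples$total_reads) &
    samples$total_reads >= cfg$qc_threshold

  truth <- structure(list(profiles = cfg$niche_profiles, dog_intercepts = U,
                          day_intercepts = V,
                          differential = .truth_differential(cfg),
                          config = cfg, seed = as.integer(seed)),
                     class = "sim_truth")
  structure(list(counts = count_table(counts), samples = samples, taxa = taxa,
                 truth = truth), class = "niche_sim")
}

.truth_differential <- function(cfg) {
  if (is.null(cfg$effect_otus))
    return(data.frame(otu = character(), niche_a = character(),
                      niche_b = character(), log_odds = numeric()))
  cfg$effect_otus[, c("otu", "niche_a", "niche_b", "log_odds")]
}

.default_taxa <- function(otu_ids) {
  i <- seq_along(otu_ids)
  phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Fusobacteria", "Synergistetes", "Spirochaetes", "Tenericutes",
             "Chlorobi")
  gram <- ifelse(i %% 13 == 0, "unknown", ifelse(i %% 2 == 0, "positive", "negative"))
  oxy <- ifelse(i %% 17 == 0, "unknown",
                c("aerobe", "anaerobe", "facultative")[(i %% 3) + 1L])
  data.frame(
    otu_id = otu_ids,
    taxonomy = sprintf("Bacterium sp. %04d", i),
    phylum = phyla[((i - 1L) %% length(phyla)) + 1L],
    percent_identity = 100 - ((i * 7) %% 60) / 10,
    oral_taxon = ifelse(i %% 3 == 0, sprintf("COT-%03d", i), NA_character_),
    gram = gram, oxygen = oxy,
    is_rare = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a null dataset
#'
#' As [simulate_dataset()] but with an identical composition distribution in
#' all four niches: one shared profile, one shared Dirichlet concentration and
#' no planted effects, so niche labels are exchangeable within dog and the
#' ground-truth differential set is empty.
#'
#' @param cfg a [sim_config()]; its buccal profile becomes the shared profile
#'   and the shared concentration is 150 unless all four are already equal.
#' @param seed integer RNG seed.
#' @return a `"niche_sim"` list; `truth$differential` has zero rows.
#' @export
null_dataset <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  prof <- cfg$niche_profiles
  shared <- prof[, "buccal"]
  prof[] <- shared
  conc <- cfg$dirichlet_concentration
  if (length(unique(conc)) > 1L) conc[] <- 150
  cfg$niche_profiles <- prof
  cfg$dirichlet_concentration <- conc
  cfg$effect_otus <- NULL
  simulate_dataset(cfg, seed)
}

#' @export
print.niche_sim <- function(x, ...) {
  cat(sprintf("Synthetic niche dataset: %d OTUs, %d collected samples (%d amplified), seed %d\n",
              nrow(x$counts), nrow(x$samples), sum(x$samples$amplified),
              x$truth$seed))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.tsv`, `samples.tsv` and `taxa.tsv` (tab-separated text).
#'
#' @param sim a `"niche_sim"` object.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "niche_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_result_tsv(sim$samples, file.path(dir, "samples.tsv"), seed = sim$truth$seed)
  write_result_tsv(sim$taxa, file.path(dir, "taxa.tsv"), seed = sim$truth$seed)
  invisible(dir)
}
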