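# small deterministic fixtures shared across test files

# balanced sample frame: each dog x occasion x niche gets `reps` samples
make_sample_frame <- function(n_dogs, n_occasions = 3,
                              reps = c(plaque = 1, buccal = 1, tongue = 1, saliva = 1)) {
  rows <- list()
  for (d in seq_len(n_dogs)) for (t in seq_len(n_occasions)) for (nn in NICHES) {
    for (r in seq_len(reps[[nn]])) {
      side <- if (nn %in% c("plaque", "buccal"))
        c("left", "right")[((r - 1L) %% 2L) + 1L] else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("D%02d.O%d.%s.%d", d, t, nn, r),
        dog_id = sprintf("D%02d", d), niche = nn, occasion = t, side = side,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# toy count table with explicit columns; rows named OTU01..
toy_counts <- function(mat, sample_ids = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("OTU%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- if (is.null(sample_ids)) sprintf("s%02d", seq_len(ncol(mat))) else sample_ids
  count_table(mat)
}

# a small simulated dataset used by several files
small_sim <- function(seed = 3, n_dogs = 6, n_otus = 40) {
  simulate_dataset(sim_config(n_dogs = n_dogs, n_otus = n_otus,
                              fail_amp = c(plaque = 0, buccal = 1, tongue = 1, saliva = 0),
                              low_count = c(plaque = 1, buccal = 0, tongue = 0, saliva = 1),
                              missing_saliva = 1),
                   seed = seed)
}

# equal-profile configuration (no niche differences) on a small panel
flat_config <- function(n_otus = 40, n_dogs = 14, conc = 150, ...) {
  prof <- niche_profile_ranked(n_otus, 1.05)
  profm <- matrix(prof, n_otus, 4,
                  dimnames = list(sprintf("OTU%04d", seq_len(n_otus)), NICHES))
  sim_config(n_dogs = n_dogs, n_otus = n_otus, niche_profiles = profm,
             dirichlet_concentration = c(plaque = conc, buccal = conc,
                                         tongue = conc, saliva = conc), ...)
}
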