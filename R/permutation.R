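#' Permutation p-value from observed and permuted statistics
#'
#' Two-sided comparison of absolute statistics. The default add-one estimator
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)` is strictly positive and gives
#' exact finite-sample type-I control; `"proportion"` is the plain fraction
#' of permuted statistics at least as extreme.
#'
#' @param stat_obs observed statistic (scalar).
#' @param stat_perm vector of permuted statistics.
#' @param estimator `"add_one"` or `"proportion"`.
#' @return a p-value in (0, 1] (or 0 to 1 for `"proportion"`).
#' @export
perm_pvalue <- function(stat_obs, stat_perm,
                        estimator = c("add_one", "proportion")) {
  estimator <- match.arg(estimator)
  k <- sum(abs(stat_perm) >= abs(stat_obs))
  if (estimator == "add_one") (1 + k) / (length(stat_perm) + 1) else k / length(stat_perm)
}

# niche-label permutations within animal. Returns a character matrix
# (n_samples x n_perm). With block = TRUE, left/right replicate pairs are
# kept together: within each dog, labels are shuffled among experimental
# units (a unit is a (occasion, niche, pair) block), separately within each
# unit-size class so the label multiset per size is preserved.
.gen_perms <- function(dog, niche, occasion, side, n_perm, seed,
                       block = FALSE) {
  set.seed(as.integer(seed))
  n <- length(niche)
  out <- matrix(NA_character_, n, n_perm)
  dogs <- unique(dog)
  if (!block) {
    for (b in seq_len(n_perm)) {
      lab <- niche
      for (d in dogs) {
        idx <- which(dog == d)
        lab[idx] <- lab[idx][sample.int(length(idx))]
      }
      out[, b] <- lab
    }
    return(out)
  }
  pair_of <- ifelse(side %in% c("left", "right"),
                    paste(dog, occasion, niche, sep = "|"),
                    paste(dog, occasion, niche, seq_along(niche), sep = "|"))
  for (b in seq_len(n_perm)) {
    lab <- niche
    for (d in dogs) {
      idx <- which(dog == d)
      units <- split(idx, pair_of[idx])
      sizes <- lengths(units)
      for (s in unique(sizes)) {
        us <- units[sizes == s]
        labs <- vapply(us, function(i) niche[i[1L]], character(1))
        labs <- labs[sample.int(length(labs))]
        for (k in seq_along(us)) lab[us[[k]]] <- labs[k]
      }
    }
    out[, b] <- lab
  }
  out
}

#' Within-animal permutation test for niche contrasts
#'
#' For each permutation the niche labels are shuffled across each animal's
#' samples (preserving that animal's multiset of labels; left/right
#' replicates are permuted as individual samples unless `block = TRUE`), the
#' GLMM is refitted, and the six pairwise Wald statistics extracted. The
#' permutation p-value per niche pair compares the observed absolute
#' statistic with the permuted ones via [perm_pvalue()].
#'
#' @inheritParams fit_binomial_glmm
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param estimator p-value estimator, see [perm_pvalue()].
#' @param block permute left/right pairs as single units.
#' @param perms optional precomputed label matrix from an earlier call (one
#'   column per permutation), e.g. to share permutations across taxa.
#' @return a list with `p` (named per-pair p-values), `contrasts` (observed
#'   pairwise contrast table), `z_obs`, `n_used`, `n_failed`, and the fitted
#'   observed model's variance components.
#' @export
permutation_test <- function(y, totals, samples, n_perm = 999, seed = 1,
                             estimator = c("add_one", "proportion"),
                             block = FALSE, perms = NULL, beta_sd = 10,
                             control = list()) {
  estimator <- match.arg(estimator)
  stopifnot(n_perm >= 1)
  obs <- .bglmm_raw(y, totals, samples$niche, samples$dog_id, samples$occasion,
                    beta_sd = beta_sd, control = control)
  ctr <- .contrasts_raw(obs)
  if (is.null(perms)) {
    side <- if ("side" %in% names(samples)) samples$side else rep("none", nrow(samples))
    perms <- .gen_perms(samples$dog_id, samples$niche, samples$occasion,
                        side, n_perm, seed, block = block)
  }
  zp <- .perm_stats(y, totals, samples, perms, obs,
                    beta_sd = beta_sd, control = control)
  n_failed <- sum(!zp$ok)
  if (n_failed > 0.2 * ncol(perms))
    stop(sprintf("%d of %d permutation refits failed", n_failed, ncol(perms)))
  z <- zp$z[zp$ok, , drop = FALSE]
  p <- vapply(seq_len(nrow(ctr)), function(j)
    perm_pvalue(ctr$wald_z[j], z[, j], estimator = estimator), numeric(1))
  list(p = setNames(p, ctr$pair), contrasts = ctr,
       z_obs = setNames(ctr$wald_z, ctr$pair),
       n_used = sum(zp$ok), n_failed = n_failed,
       var_dog = obs$sd_dog^2, var_day = obs$sd_day^2,
       converged = obs$converged, estimator = estimator)
}

# refit under each permuted labelling; z matrix (n_perm x n_pairs)
.perm_stats <- function(y, totals, samples, perms, obs, beta_sd, control) {
  npair <- length(obs$niche_levels) * (length(obs$niche_levels) - 1) / 2
  z <- matrix(NA_real_, ncol(perms), npair)
  ok <- logical(ncol(perms))
  sd_init <- pmax(c(obs$sd_dog, obs$sd_day), 0.05)
  for (b in seq_len(ncol(perms))) {
    res <- tryCatch({
      raw <- .bglmm_raw(y, totals, perms[, b], samples$dog_id,
                        samples$occasion, beta_sd = beta_sd,
                        sd_init = sd_init, control = control)
      .contrasts_raw(raw)$wald_z
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res)) && length(res) == npair) {
      z[b, ] <- res
      ok[b] <- TRUE
    }
  }
  list(z = z, ok = ok)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity (delegates to [stats::p.adjust()]), applied across all
#' analysis units within one niche-pair comparison family.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
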