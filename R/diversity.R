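#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over the nonzero proportions of one sample, in
#' nats by default (`base = exp(1)`); use `base = 2` for bits.
#'
#' @param p vector of proportions summing to 1.
#' @param base logarithm base.
#' @return the Shannon index (scalar).
#' @export
shannon <- function(p, base = exp(1)) {
  if (length(p) == 0L) stop("empty proportion vector")
  if (anyNA(p) || any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Shannon index for every sample of a proportion table
#'
#' @param prop_table proportion matrix (OTUs x samples), e.g. from
#'   [to_proportions()].
#' @param base logarithm base.
#' @return named numeric vector, one index per sample.
#' @export
shannon_samples <- function(prop_table, base = exp(1)) {
  apply(prop_table, 2L, shannon, base = base)
}

#' Linear mixed model for Shannon diversity
#'
#' Fits `H ~ 0 + niche + (1 | dog) + (1 | occasion)` by REML via
#' [lme4::lmer()], and reports per-niche model means and all pairwise
#' differences with Wald confidence intervals and significance flags.
#'
#' @param indices named numeric vector of per-sample Shannon indices.
#' @param samples sample metadata covering those samples (`sample_id`,
#'   `niche`, `dog_id`, `occasion`).
#' @param level confidence level.
#' @param alpha significance level for the pairwise flags.
#' @return an object of class `"diversity_lmm"` with `means` (per-niche mean,
#'   CI), `pairwise` (difference, CI, z, p, significant), `var_dog`,
#'   `var_day`, `converged` and the underlying fit.
#' @export
diversity_lmm <- function(indices, samples, level = 0.95, alpha = 0.05) {
  sam <- samples[match(names(indices), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some indices")
  niches <- NICHES[NICHES %in% unique(sam$niche)]
  if (length(niches) < 2L) stop("at least two niches are required")
  df <- data.frame(H = as.numeric(indices),
                   niche = factor(sam$niche, levels = niches),
                   dog = factor(sam$dog_id),
                   occasion = factor(sam$occasion))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(H ~ 0 + niche + (1 | dog) + (1 | occasion), data = df,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  names(b) <- sub("^niche", "", names(b))
  zq <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(V))
  means <- data.frame(niche = names(b), mean = unname(b),
                      ci_lo = unname(b - zq * se), ci_hi = unname(b + zq * se))
  prs <- .niche_pairs(names(b))
  ia <- match(prs$a, names(b)); ib <- match(prs$b, names(b))
  d <- b[ia] - b[ib]
  sed <- sqrt(pmax(diag(V)[ia] + diag(V)[ib] - 2 * V[cbind(ia, ib)], 0))
  # a numerically zero SE (degenerate, constant-response fit) carries no
  # evidence; do not let it manufacture huge z statistics
  sed[sed < 1e-10] <- 0
  z <- ifelse(sed > 0, d / sed, 0)
  pw <- data.frame(pair = prs$pair, difference = unname(d),
                   ci_lo = unname(d - zq * sed), ci_hi = unname(d + zq * sed),
                   z = unname(z), p = unname(2 * pnorm(-abs(z))))
  pw$significant <- pw$p < alpha
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(means = means, pairwise = pw,
                 var_dog = vc$vcov[vc$grp == "dog"],
                 var_day = vc$vcov[vc$grp == "occasion"],
                 converged = conv, fit = fit, level = level),
            class = "diversity_lmm")
}

#' @export
print.diversity_lmm <- function(x, ...) {
  cat("Shannon diversity linear mixed model",
      if (x$converged) "" else " [NOT CONVERGED]", "\n", sep = "")
  print(x$means, row.names = FALSE, digits = 4)
  cat("\nPairwise differences:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
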