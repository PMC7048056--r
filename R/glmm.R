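#' Fit a binomial logit GLMM for one taxon
#'
#' Models the per-sample count of a taxon out of the sample's total reads as
#' binomial with a logit link, with niche as the fixed effect (cell-means
#' coding: one log-odds per niche) and crossed Gaussian random intercepts for
#' animal and sampling day (occasion). Random-effect integrals are
#' approximated by the Laplace method; the two random-intercept standard
#' deviations are profiled out by Nelder-Mead on the Laplace deviance. A weak
#' Gaussian stabilizing penalty (sd `beta_sd`, default 10) on the fixed
#' effects keeps estimates finite under separation. Non-convergence is
#' flagged, never silent.
#'
#' @param y taxon read counts per sample (successes).
#' @param totals total reads per sample; all must be positive.
#' @param samples data frame with one row per element of `y`, columns
#'   `niche`, `dog_id`, `occasion`.
#' @param var_fixed `NULL` (variances estimated) or numeric length-2
#'   `c(var_dog, var_day)` to hold both variance components fixed (e.g.
#'   `c(0, 0)` reduces the model to an ordinary penalized binomial
#'   regression).
#' @param beta_sd standard deviation of the Gaussian penalty on the fixed
#'   effects (logit scale).
#' @param sd_init starting values for the two random-intercept SDs.
#' @param control list overriding `nm_maxit`, `nm_reltol`, `newton_maxit`.
#' @param level confidence level for reported intervals.
#' @return an object of class `"bglmm"` with the per-niche log-odds
#'   (`coefficients`), their Wald covariance (`vcov`), variance components
#'   `var_dog`/`var_day`, fitted per-niche mean proportions with confidence
#'   intervals (`niche_means`), `converged`, `loglik` and the model frame.
#' @seealso [pairwise_contrasts()] for the six niche contrasts,
#'   [permutation_test()] for permutation inference.
#' @export
fit_binomial_glmm <- function(y, totals, samples, var_fixed = NULL,
                              beta_sd = 10, sd_init = c(0.3, 0.15),
                              control = list(), level = 0.95) {
  stopifnot(length(y) == length(totals), nrow(samples) == length(y))
  if (any(totals <= 0)) stop("all sample totals must be positive")
  if (any(y < 0) || any(y > totals)) stop("counts must lie in [0, total]")
  raw <- .bglmm_raw(y, totals, samples$niche, samples$dog_id, samples$occasion,
                    var_fixed = var_fixed, beta_sd = beta_sd,
                    sd_init = sd_init, control = control)
  beta <- raw$beta
  se <- sqrt(pmax(diag(raw$vcov_beta), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  niche_means <- data.frame(
    niche = raw$niche_levels,
    log_odds = beta,
    mean_proportion = plogis(beta),
    ci_lo = plogis(beta - zq * se),
    ci_hi = plogis(beta + zq * se),
    row.names = NULL
  )
  eta <- beta[match(samples$niche, raw$niche_levels)] +
    if (length(raw$u)) raw$u[match(samples$dog_id, raw$dog_levels)] else 0
  eta <- eta + if (length(raw$v)) raw$v[match(as.character(samples$occasion),
                                             raw$day_levels)] else 0
  structure(list(
    coefficients = setNames(beta, raw$niche_levels),
    vcov = raw$vcov_beta,
    var_dog = raw$sd_dog^2, var_day = raw$sd_day^2,
    ranef = list(dog = setNames(raw$u, raw$dog_levels),
                 day = setNames(raw$v, raw$day_levels)),
    niche_means = niche_means,
    converged = raw$converged,
    loglik = -raw$deviance / 2,
    level = level,
    beta_sd = beta_sd,
    data = list(y = y, totals = totals, niche = samples$niche,
                dog = samples$dog_id, occasion = samples$occasion,
                eta = eta),
    call = match.call()
  ), class = "bglmm")
}

# shared fast path for fitting and permutation refits
.bglmm_raw <- function(y, totals, niche, dog, occasion, var_fixed = NULL,
                       beta_sd = 10, sd_init = c(0.3, 0.15), control = list()) {
  ctl <- modifyList(list(nm_maxit = 200L, nm_reltol = 1e-6, newton_maxit = 50L),
                    control)
  niche_levels <- NICHES[NICHES %in% unique(niche)]
  if (length(niche_levels) == 0L) niche_levels <- sort(unique(niche))
  if (length(niche_levels) < 2L)
    stop("at least two niches are required to fit niche contrasts")
  ni <- match(niche, niche_levels) - 1L
  dog_levels <- sort(unique(as.character(dog)))
  day_levels <- sort(unique(as.character(occasion)))
  di <- match(as.character(dog), dog_levels) - 1L
  ti <- match(as.character(occasion), day_levels) - 1L
  fix <- !is.null(var_fixed)
  if (fix && (length(var_fixed) != 2L || any(var_fixed < 0)))
    stop("var_fixed must be c(var_dog, var_day), both >= 0")
  out <- .bglmm_fit_cpp(as.numeric(y), as.numeric(totals),
                        as.integer(ni), as.integer(di), as.integer(ti),
                        length(niche_levels), length(dog_levels),
                        length(day_levels), beta_sd,
                        as.numeric(sd_init), fix,
                        if (fix) sqrt(as.numeric(var_fixed)) else c(0, 0),
                        as.integer(ctl$nm_maxit), ctl$nm_reltol,
                        as.integer(ctl$newton_maxit))
  out$beta <- as.numeric(out$beta)
  out$u <- as.numeric(out$u)
  out$v <- as.numeric(out$v)
  out$vcov_beta <- matrix(as.numeric(out$vcov_beta), length(niche_levels),
                          dimnames = list(niche_levels, niche_levels))
  out$niche_levels <- niche_levels
  out$dog_levels <- dog_levels
  out$day_levels <- day_levels
  out
}

# ordered niche pairs ("a-b" with a before b in NICHES order)
.niche_pairs <- function(levels) {
  cmb <- combn(levels, 2L)
  data.frame(a = cmb[1L, ], b = cmb[2L, ],
             pair = paste(cmb[1L, ], cmb[2L, ], sep = "-"),
             stringsAsFactors = FALSE)
}

# pairwise Wald contrasts from a raw fit
.contrasts_raw <- function(raw, level = 0.95) {
  prs <- .niche_pairs(raw$niche_levels)
  ia <- match(prs$a, raw$niche_levels)
  ib <- match(prs$b, raw$niche_levels)
  d <- raw$beta[ia] - raw$beta[ib]
  v <- diag(raw$vcov_beta)[ia] + diag(raw$vcov_beta)[ib] -
    2 * raw$vcov_beta[cbind(ia, ib)]
  se <- sqrt(pmax(v, 0))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(pair = prs$pair,
             log_odds_diff = d, se = se,
             wald_z = ifelse(se > 0, d / se, 0),
             odds_ratio = exp(d),
             ci_lo = exp(d - zq * se), ci_hi = exp(d + zq * se),
             stringsAsFactors = FALSE)
}

#' Pairwise niche contrasts from a fitted GLMM
#'
#' Extracts, for every niche pair, the log-odds difference, its Wald standard
#' error and z statistic, and the odds ratio with confidence interval.
#'
#' @param fit a [fit_binomial_glmm()] object.
#' @param level confidence level.
#' @return a data frame with one row per niche pair.
#' @export
pairwise_contrasts <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bglmm"))
  raw <- list(beta = unname(fit$coefficients), vcov_beta = fit$vcov,
              niche_levels = names(fit$coefficients))
  .contrasts_raw(raw, level = level)
}

#' @export
print.bglmm <- function(x, ...) {
  cat("Binomial logit GLMM (Laplace), niche fixed effect,",
      "crossed dog/day random intercepts\n")
  cat(sprintf("  var_dog = %.4g, var_day = %.4g, logLik = %.2f%s\n",
              x$var_dog, x$var_day, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$niche_means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.bglmm <- function(object, ...) {
  out <- list(fit = object, contrasts = pairwise_contrasts(object))
  class(out) <- "summary.bglmm"
  out
}

#' @export
print.summary.bglmm <- function(x, ...) {
  print(x$fit)
  cat("\nPairwise niche contrasts (odds ratios):\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.bglmm <- function(object, ...) object$coefficients

#' @export
vcov.bglmm <- function(object, ...) object$vcov

#' @export
fitted.bglmm <- function(object, ...) plogis(object$data$eta)

#' @export
residuals.bglmm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- plogis(object$data$eta)
  r <- object$data$y - object$data$totals * p
  if (type == "pearson")
    r / sqrt(object$data$totals * p * (1 - p))
  else r / object$data$totals
}

#' @export
logLik.bglmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2, class = "logLik")
}
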