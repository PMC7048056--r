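#' Sum counts within annotation categories
#'
#' Collapses the OTU rows of a count table into category rows (phylum,
#' Gram-stain status or oxygen requirement). Rows annotated `"unknown"` (or
#' missing) are excluded from every category sum, not imputed.
#'
#' @param ct a [count_table()].
#' @param taxa taxon annotation table covering the table's OTUs.
#' @param level `"phylum"`, `"gram"` or `"oxygen"`.
#' @return a [count_table()] with one row per category.
#' @export
aggregate_counts <- function(ct, taxa, level = c("phylum", "gram", "oxygen")) {
  level <- match.arg(level)
  ann <- taxa[[level]][match(rownames(ct), taxa$otu_id)]
  if (all(is.na(ann))) stop("no ", level, " annotation for the table's OTUs")
  keep <- !is.na(ann) & ann != "unknown" & ann != ""
  if (!any(keep)) stop("all ", level, " annotations are unknown; nothing to aggregate")
  m <- .strip_ct(ct)[keep, , drop = FALSE]
  cat_f <- factor(ann[keep])
  out <- rowsum(m, cat_f)
  empty <- rowSums(out) == 0
  if (any(empty)) {
    warning("empty ", level, " categor(ies) skipped: ",
            paste(rownames(out)[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  count_table(out)
}

#' Differential abundance across niches
#'
#' The central inference pipeline: for every analysis unit (OTU row, or
#' annotation category when `level != "otu"`) a binomial logit GLMM with
#' crossed animal/day random intercepts is fitted, six pairwise niche
#' contrasts are extracted, and within-animal permutation p-values are
#' computed by refitting the model under shuffled niche labels (one shared
#' permutation stream across units). P-values are then Benjamini-Hochberg
#' adjusted across all units within each niche-pair family.
#'
#' @param ct a QC'd [count_table()] (typically from [preprocess()]).
#' @param samples sample metadata covering the table's columns.
#' @param taxa taxon annotations (required when `level != "otu"`).
#' @param level analysis level: `"otu"` (default), `"phylum"`, `"gram"` or
#'   `"oxygen"`.
#' @param n_perm number of permutations (default 999).
#' @param alpha significance level used by [pairwise_summary()].
#' @param seed integer seed for the permutation stream (mandatory for
#'   reproducibility).
#' @param estimator permutation p-value estimator, see [perm_pvalue()].
#' @param block permute left/right pairs as single units.
#' @param beta_sd stabilizing penalty SD for the GLMM fixed effects.
#' @param control optimizer control passed to the GLMM engine.
#' @return an object of class `"niche_diff"`: a list with `results` (one row
#'   per unit x niche pair: log-odds difference, odds ratio with CI, Wald z,
#'   permutation p, BH-adjusted p), `fits` (per-unit variance components and
#'   convergence flags), and the call parameters.
#' @export
diff_abundance <- function(ct, samples, taxa = NULL,
                           level = c("otu", "phylum", "gram", "oxygen"),
                           n_perm = 999, alpha = 0.05, seed = 1,
                           estimator = c("add_one", "proportion"),
                           block = FALSE, beta_sd = 10, control = list()) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  if (level != "otu") {
    if (is.null(taxa)) stop("taxa annotations are required for level = ", level)
    ct <- aggregate_counts(ct, taxa, level = level)
  }
  sam <- samples[match(colnames(ct), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some table columns")
  totals <- colSums(.strip_ct(ct))
  side <- if ("side" %in% names(sam)) sam$side else rep("none", nrow(sam))
  perms <- .gen_perms(sam$dog_id, sam$niche, sam$occasion, side,
                      n_perm, seed, block = block)
  units <- rownames(ct)
  res <- vector("list", length(units))
  fits <- vector("list", length(units))
  for (i in seq_along(units)) {
    y <- .strip_ct(ct)[i, ]
    pt <- permutation_test(y, totals, sam, n_perm = n_perm, seed = seed,
                           estimator = estimator, perms = perms,
                           beta_sd = beta_sd, control = control)
    res[[i]] <- data.frame(unit = units[i], pt$contrasts, perm_p = unname(pt$p),
                           stringsAsFactors = FALSE)
    fits[[i]] <- data.frame(unit = units[i], var_dog = pt$var_dog,
                            var_day = pt$var_day, converged = pt$converged,
                            n_perm_used = pt$n_used,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  results$adj_p <- NA_real_
  for (pr in unique(results$pair)) {
    j <- results$pair == pr
    results$adj_p[j] <- bh_adjust(results$perm_p[j])
  }
  structure(list(results = results, fits = do.call(rbind, fits),
                 level = level, n_perm = n_perm, alpha = alpha,
                 seed = seed, estimator = estimator,
                 n_units = length(units), call = match.call()),
            class = "niche_diff")
}

#' Count significant units per niche pair
#'
#' Tabulates, for each of the six niche pairs, the number of analysis units
#' whose BH-adjusted permutation p-value falls below `alpha` — the
#' "significantly differing OTUs out of N units" summary.
#'
#' @param x a [diff_abundance()] result.
#' @param alpha significance level (default: the level stored in `x`).
#' @return a data frame with columns `pair`, `n_significant`, `n_units`.
#' @export
pairwise_summary <- function(x, alpha = NULL) {
  stopifnot(inherits(x, "niche_diff"))
  if (is.null(alpha)) alpha <- x$alpha
  pairs <- unique(x$results$pair)
  n_sig <- vapply(pairs, function(pr)
    sum(x$results$adj_p[x$results$pair == pr] < alpha), integer(1))
  data.frame(pair = pairs, n_significant = unname(n_sig),
             n_units = x$n_units, stringsAsFactors = FALSE)
}

#' @export
print.niche_diff <- function(x, ...) {
  cat(sprintf("Differential abundance (%s level): %d units, %d permutations, %s estimator\n",
              x$level, x$n_units, x$n_perm, x$estimator))
  print(pairwise_summary(x), row.names = FALSE)
  nc <- sum(!x$fits$converged)
  if (nc > 0) cat(sprintf("note: %d unit fit(s) flagged non-converged\n", nc))
  invisible(x)
}

#' @export
summary.niche_diff <- function(object, ...) {
  s <- pairwise_summary(object)
  top <- object$results[order(object$results$adj_p), ]
  list(pairwise = s, top = utils::head(top, 20))
}
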