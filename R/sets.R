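#' Niche-sharing set membership (UpSet-style)
#'
#' Flags an OTU as present in a niche when its average proportion over that
#' niche's samples strictly exceeds `threshold` (default 0.5%), then counts
#' the exclusive intersections of the four presence sets over the full niche
#' power set.
#'
#' @param prop_table QC'd proportion matrix (OTUs x samples).
#' @param samples sample metadata covering the table's columns.
#' @param threshold strict presence cutoff on the per-niche mean proportion.
#' @return an object of class `"set_membership"`: `presence` (logical OTUs x
#'   niches matrix), `intersections` (data frame: combination, exclusive
#'   count), `threshold`.
#' @export
upset_membership <- function(prop_table, samples, threshold = 0.005) {
  m <- as.matrix(prop_table)
  sam <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some table columns")
  niches <- NICHES[NICHES %in% unique(sam$niche)]
  presence <- sapply(niches, function(nn)
    rowMeans(m[, sam$niche == nn, drop = FALSE]) > threshold)
  if (is.null(dim(presence))) presence <- matrix(presence, ncol = 1L,
                                                 dimnames = list(rownames(m), niches))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(niches)))
  names(combos) <- niches
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- apply(combos, 1L, function(pat)
    sum(apply(presence, 1L, function(row) all(row == pat))))
  label <- apply(combos, 1L, function(pat) paste(niches[as.logical(pat)], collapse = "&"))
  inter <- data.frame(combination = label, degree = rowSums(combos),
                      n_otus = as.integer(counts), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$n_otus, inter$degree), ]
  rownames(inter) <- NULL
  structure(list(presence = presence, intersections = inter,
                 threshold = threshold), class = "set_membership")
}

#' @export
print.set_membership <- function(x, ...) {
  cat(sprintf("Niche set membership (presence > %.3g mean proportion)\n", x$threshold))
  cat(sprintf("  %d OTU(s) present in at least one niche\n", sum(rowSums(x$presence) > 0)))
  print(utils::head(x$intersections[x$intersections$n_otus > 0, ], 15), row.names = FALSE)
  invisible(x)
}

#' Core microbiota at detection/prevalence thresholds
#'
#' Within a niche, an OTU is core at prevalence `q` iff its proportion is at
#' least `detection` (inclusive, default 0.5%) in at least
#' `ceiling(q * n_samples)` of the niche's samples. The cross-niche core is
#' computed the same way over the pooled QC-passing sample set.
#'
#' @param prop_table QC'd proportion matrix (OTUs x samples).
#' @param samples sample metadata covering the table's columns.
#' @param detection inclusive abundance detection threshold.
#' @param prevalence vector of required sample fractions in `(0, 1]`.
#' @return an object of class `"core_report"`: `per_niche` (niche ->
#'   prevalence -> OTU id vector), `cross_niche` (prevalence -> OTU ids),
#'   `n_samples` per niche.
#' @export
core_microbiota <- function(prop_table, samples, detection = 0.005,
                            prevalence = c(1, 0.75, 0.5)) {
  if (any(prevalence <= 0 | prevalence > 1)) stop("prevalence must lie in (0, 1]")
  m <- as.matrix(prop_table)
  sam <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some table columns")
  hit <- m >= detection
  core_of <- function(cols) {
    n <- length(cols)
    k <- rowSums(hit[, cols, drop = FALSE])
    lapply(setNames(prevalence, sprintf("prev_%g", prevalence)), function(q)
      rownames(m)[k >= ceiling(q * n)])
  }
  niches <- NICHES[NICHES %in% unique(sam$niche)]
  per_niche <- lapply(setNames(niches, niches), function(nn)
    core_of(which(sam$niche == nn)))
  cross <- core_of(seq_len(ncol(m)))
  structure(list(per_niche = per_niche, cross_niche = cross,
                 detection = detection, prevalence = prevalence,
                 n_samples = setNames(vapply(niches, function(nn)
                   sum(sam$niche == nn), integer(1)), niches)),
            class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("Core microbiota (detection >= %.3g)\n", x$detection))
  for (nn in names(x$per_niche)) {
    sizes <- vapply(x$per_niche[[nn]], length, integer(1))
    cat(sprintf("  %-7s (n=%d): %s\n", nn, x$n_samples[[nn]],
                paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  }
  sizes <- vapply(x$cross_niche, length, integer(1))
  cat(sprintf("  all niches:   %s\n",
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}
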