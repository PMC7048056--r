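#' Exclude samples with low read depth
#'
#' Removes samples whose total read count is strictly below `threshold`
#' (default 1000 reads) from the count table and records the exclusions.
#'
#' @param ct a [count_table()].
#' @param samples optional sample metadata; when given, its `qc_pass` column
#'   is (re)set for the table's samples and the filtered copy is returned.
#' @param threshold positive read-count exclusion threshold; a sample is
#'   removed iff its total is `< threshold`.
#' @return a list with `counts` (filtered table), `samples` (filtered
#'   metadata or `NULL`) and `report` (class `"filter_report"`).
#' @export
exclude_low_count_samples <- function(ct, samples = NULL, threshold = 1000) {
  stopifnot(threshold >= 0)
  tot <- colSums(.strip_ct(ct))
  drop <- tot < threshold
  if (all(drop)) stop("all samples fall below the read-count threshold")
  report <- structure(list(
    excluded_samples = data.frame(sample_id = colnames(ct)[drop],
                                  total_reads = as.integer(tot[drop]),
                                  reason = rep(sprintf("total_reads < %g", threshold),
                                               sum(drop)),
                                  stringsAsFactors = FALSE),
    rare_otus = character(),
    n_units_after = sum(!drop)
  ), class = "filter_report")
  out_ct <- count_table(.strip_ct(ct)[, !drop, drop = FALSE])
  if (!is.null(samples)) {
    keep_ids <- colnames(out_ct)
    samples <- samples[samples$sample_id %in% keep_ids, , drop = FALSE]
    samples$qc_pass <- TRUE
  }
  list(counts = out_ct, samples = samples, report = report)
}

#' Group rare taxa into a single pooled unit
#'
#' An OTU is rare iff its average proportion is below `prop_cutoff` in every
#' niche, or it has a nonzero count in fewer than `min_samples` samples.
#' All rare rows are summed into one `"RARE"` row appended to the table, so
#' column totals are conserved. Intended to run after sample QC.
#'
#' @param ct a QC'd [count_table()].
#' @param samples sample metadata covering the table's columns (for niche
#'   assignment).
#' @param prop_cutoff proportion cutoff (default 5e-4, i.e. 0.05%).
#' @param min_samples minimum number of samples with a nonzero count
#'   (default 2).
#' @param average how the per-niche average proportion is computed:
#'   `"per_sample"` (unweighted mean of per-sample proportions, default) or
#'   `"pooled"` (niche-pooled count ratio).
#' @param taxa optional taxon annotation table; when given, returned with
#'   `is_rare` updated and a synthetic `"RARE"` record appended.
#' @return list with `counts` (grouped table), `taxa` (updated annotations or
#'   `NULL`) and `report` (class `"filter_report"` listing `rare_otus`).
#' @export
group_rare_taxa <- function(ct, samples, prop_cutoff = 5e-4, min_samples = 2,
                            average = c("per_sample", "pooled"), taxa = NULL) {
  average <- match.arg(average)
  m <- .strip_ct(ct)
  storage.mode(m) <- "double"
  sam <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some table columns")
  niche_of <- sam$niche
  present_niches <- unique(niche_of)

  mean_prop <- sapply(present_niches, function(nn) {
    cols <- which(niche_of == nn)
    sub <- m[, cols, drop = FALSE]
    if (average == "per_sample") {
      rowMeans(sweep(sub, 2L, colSums(sub), `/`))
    } else {
      rowSums(sub) / sum(sub)
    }
  })
  if (is.null(dim(mean_prop))) mean_prop <- matrix(mean_prop, ncol = 1L)

  low_everywhere <- apply(mean_prop < prop_cutoff, 1L, all)
  n_present <- rowSums(m >= 1)
  rare <- (low_everywhere | n_present < min_samples) & rownames(m) != "RARE"

  rare_ids <- rownames(m)[rare]
  if (any(rare)) {
    pooled <- colSums(m[rare, , drop = FALSE])
    kept <- m[!rare, , drop = FALSE]
    if ("RARE" %in% rownames(kept)) {
      kept["RARE", ] <- kept["RARE", ] + pooled
      out <- kept
    } else {
      out <- rbind(kept, RARE = pooled)
    }
  } else {
    out <- m
  }
  report <- structure(list(
    excluded_samples = data.frame(sample_id = character(),
                                  total_reads = integer(),
                                  reason = character(), stringsAsFactors = FALSE),
    rare_otus = rare_ids,
    n_units_after = nrow(out)
  ), class = "filter_report")

  if (!is.null(taxa)) {
    taxa$is_rare <- taxa$otu_id %in% rare_ids
    taxa <- taxa[taxa$otu_id %in% rownames(out), , drop = FALSE]
    if (any(rare) && !"RARE" %in% taxa$otu_id) {
      rec <- taxa[0, , drop = FALSE]
      rec[1, "otu_id"] <- "RARE"
      rec$taxonomy <- "pooled rare taxa"
      rec$phylum <- "mixed"
      rec$percent_identity <- NA_real_
      rec$oral_taxon <- NA_character_
      rec$gram <- "unknown"
      rec$oxygen <- "unknown"
      rec$is_rare <- FALSE
      taxa <- rbind(taxa, rec)
    }
  }
  list(counts = count_table(out), taxa = taxa, report = report)
}

#' Run sample QC and rare-taxon grouping
#'
#' Convenience wrapper applying [exclude_low_count_samples()] followed by
#' [group_rare_taxa()], yielding the analysis-ready unit table.
#'
#' @inheritParams exclude_low_count_samples
#' @inheritParams group_rare_taxa
#' @return list with `counts`, `samples`, `taxa` and `report` (merged
#'   `"filter_report"`).
#' @export
preprocess <- function(ct, samples, taxa = NULL, threshold = 1000,
                       prop_cutoff = 5e-4, min_samples = 2,
                       average = c("per_sample", "pooled")) {
  qc <- exclude_low_count_samples(ct, samples, threshold = threshold)
  gr <- group_rare_taxa(qc$counts, qc$samples, prop_cutoff = prop_cutoff,
                        min_samples = min_samples, average = average,
                        taxa = taxa)
  report <- structure(list(
    excluded_samples = qc$report$excluded_samples,
    rare_otus = gr$report$rare_otus,
    n_units_after = gr$report$n_units_after
  ), class = "filter_report")
  list(counts = gr$counts, samples = qc$samples, taxa = gr$taxa, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d sample(s) excluded, %d rare OTU(s) pooled, %d analysis units\n",
              nrow(x$excluded_samples), length(x$rare_otus), x$n_units_after))
  invisible(x)
}
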