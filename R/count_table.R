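#' @useDynLib nichecompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef vcov fitted residuals plogis qlogis qnorm pnorm
#'   qchisq cov optim rmultinom rgamma rnorm runif p.adjust setNames sd
#'   quantile aggregate logLik
#' @importFrom utils read.delim write.table combn packageVersion modifyList head
NULL

#' Oral niche labels
#'
#' The four oral sampling niches, in the canonical order used throughout the
#' package: supragingival plaque, buccal mucosa, tongue dorsum mucosa and
#' stimulated saliva.
#' @export
NICHES <- c("plaque", "buccal", "tongue", "saliva")

#' Construct a validated OTU count table
#'
#' A count table is an integer matrix of sequencing read counts with OTUs as
#' rows and samples as columns; row names are OTU identifiers and column names
#' sample identifiers, both unique.
#'
#' @param counts numeric matrix of non-negative integer-valued read counts,
#'   with unique row (OTU) and column (sample) names.
#' @return an integer matrix of class `"count_table"`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("count table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU identifiers in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count table")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(matrix()))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("OTU count table: %d OTUs x %d samples, %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

.strip_ct <- function(x) {
  # plain matrix view (drop the count_table class for arithmetic)
  class(x) <- "matrix"
  x
}

#' Read an OTU count table
#'
#' Reads a count table from tab-separated text (OTUs as rows, first column
#' `otu_id`, remaining columns one per sample) or from BIOM format 1.0 JSON
#' (dense), via the biomformat package.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    if (file.size(path) == 0L) stop("empty count table file: ", path)
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     comment.char = "#", colClasses = "character",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("count table must have an otu_id column and at least one sample")
    if (names(df)[1L] != "otu_id") stop("first column of a count table must be 'otu_id'")
    ids <- df[[1L]]
    if (anyDuplicated(ids)) stop("duplicate OTU identifiers in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
    if (anyNA(num)) stop("unparseable count cell(s) in ", path)
    rownames(num) <- ids
    count_table(num)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    count_table(m)
  }
}

#' Write an OTU count table
#'
#' @param ct a [count_table()].
#' @param path output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @export
write_count_table <- function(ct, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(otu_id = rownames(ct), .strip_ct(ct),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(.strip_ct(ct))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Convert counts to proportions
#'
#' In `"sample"` mode every sample (column) is divided by its own total read
#' count; samples with a zero total are dropped and recorded in the
#' `"dropped_samples"` attribute. In `"study"` mode a single vector of
#' study-wide proportions is returned: each OTU's total reads over the grand
#' total across all samples.
#'
#' @param ct a [count_table()].
#' @param mode `"sample"` (per-sample proportions, the modelling scale) or
#'   `"study"` (pooled study-wide proportions, the reporting scale).
#' @return for `"sample"`, a numeric matrix of class `"proportion_table"`
#'   whose columns each sum to 1; for `"study"`, a named numeric vector.
#' @export
to_proportions <- function(ct, mode = c("sample", "study")) {
  mode <- match.arg(mode)
  m <- .strip_ct(ct)
  storage.mode(m) <- "double"
  tot <- colSums(m)
  if (all(tot == 0)) stop("all samples have zero total counts")
  if (mode == "study") {
    return(rowSums(m) / sum(m))
  }
  dropped <- colnames(m)[tot == 0]
  if (length(dropped)) {
    warning(sprintf("%d sample(s) with zero total dropped from proportions", length(dropped)))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(m, 2L, tot, `/`)
  attr(p, "dropped_samples") <- dropped
  class(p) <- c("proportion_table", class(matrix()))
  p
}

#' Read a sample metadata table
#'
#' Expected columns: `sample_id`, `dog_id`, `niche`, `occasion`, `side`;
#' optional `total_reads`, `qc_pass`, `amplified`.
#'
#' @param path tab-separated file.
#' @return a validated data frame.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_samples(df)
}

#' Validate a sample metadata table
#'
#' Checks identifier uniqueness, niche labels, occasion indices and the
#' side convention (left/right only for duplicated niches, `none` otherwise).
#'
#' @param samples data frame of per-sample metadata.
#' @return the validated data frame (invisibly unchanged).
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "dog_id", "niche", "occasion", "side")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample identifiers")
  if (!all(samples$niche %in% NICHES))
    stop("niche must be one of: ", paste(NICHES, collapse = ", "))
  dup <- samples$niche %in% c("plaque", "buccal")
  if (!all(samples$side[dup] %in% c("left", "right")))
    stop("plaque and buccal samples must have side 'left' or 'right'")
  if (!all(samples$side[!dup] == "none"))
    stop("tongue and saliva samples must have side 'none'")
  if (!all(samples$occasion == round(samples$occasion)) || any(samples$occasion < 1))
    stop("occasion must be a positive integer index")
  samples
}

#' Read a taxon annotation table
#'
#' Expected columns: `otu_id`, `taxonomy`, `phylum`, `percent_identity`,
#' `oral_taxon`, `gram`, `oxygen`.
#'
#' @param path tab-separated file.
#' @return a data frame.
#' @export
read_taxon_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("otu_id", "taxonomy", "phylum", "percent_identity", "oral_taxon",
            "gram", "oxygen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxon table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("duplicate OTU identifiers in taxon table")
  ok_gram <- c("positive", "negative", "unknown")
  ok_oxy <- c("aerobe", "anaerobe", "facultative", "unknown")
  if (!all(df$gram %in% ok_gram)) stop("gram must be one of: ", paste(ok_gram, collapse = ", "))
  if (!all(df$oxygen %in% ok_oxy)) stop("oxygen must be one of: ", paste(ok_oxy, collapse = ", "))
  df
}

#' Summarize the sampling design by stage
#'
#' Tabulates samples per niche at each stage of the study: collected,
#' amplified (equivalently, sequenced) and passing the read-depth QC.
#' Stages are read from the logical columns `amplified` and `qc_pass` when
#' present; absent columns default to all-true (collected implies amplified)
#' except `qc_pass`, which defaults to `amplified`.
#'
#' @param samples sample metadata data frame (one row per collected sample).
#' @return a data frame of class `"design_summary"` with one row per niche
#'   plus a `total` row and columns `collected`, `sequenced`, `qc_pass`.
#' @export
summarize_design <- function(samples) {
  if (nrow(samples) == 0L) {
    out <- data.frame(niche = c(NICHES, "total"), collected = 0L,
                      sequenced = 0L, qc_pass = 0L)
    class(out) <- c("design_summary", "data.frame")
    return(out)
  }
  validate_samples(samples)
  amp <- if ("amplified" %in% names(samples)) as.logical(samples$amplified) else rep(TRUE, nrow(samples))
  qc <- if ("qc_pass" %in% names(samples)) as.logical(samples$qc_pass) else amp
  tab <- function(flag) {
    x <- table(factor(samples$niche[flag], levels = NICHES))
    as.integer(x)
  }
  out <- data.frame(
    niche = NICHES,
    collected = tab(rep(TRUE, nrow(samples))),
    sequenced = tab(amp),
    qc_pass = tab(qc & amp)
  )
  out <- rbind(out, data.frame(niche = "total",
                               collected = sum(out$collected),
                               sequenced = sum(out$sequenced),
                               qc_pass = sum(out$qc_pass)))
  class(out) <- c("design_summary", "data.frame")
  out
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Sampling design summary (samples per niche by stage)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a result table as annotated TSV
#'
#' Writes a data frame as tab-separated text with a header comment line
#' recording the package version and, when given, the RNG seed used.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed optional integer seed to record.
#' @export
write_result_tsv <- function(df, path, seed = NULL) {
  hdr <- sprintf("# nichecompare %s%s", as.character(packageVersion("nichecompare")),
                 if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
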