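#' Type-I (community-level) mean-variance point set
#'
#' One point per sample: `M` is the mean abundance across all OTUs in that
#' sample (zeros included — an OTU absent from a sample is abundance 0) and
#' `V` is the variance across the same values. The slope of `ln V` on `ln M`
#' over these points is the community spatial heterogeneity exponent b1.
#'
#' Points with `M = 0` or `V = 0` cannot enter the log-log regression and are
#' dropped; the drop count is retained so the total number of sampling units
#' stays auditable.
#'
#' @param counts OTU matrix (rows = OTUs, columns = samples) or `ple_study`.
#' @param sample_subset Optional character vector of sample ids to restrict to.
#' @param variance `"sample"` (denominator n-1, default) or `"population"`
#'   (denominator n).
#' @param group_label Label stored on the result (defaults to `"all"`).
#' @return A `mean_variance_set`: list with `level`, `group_label`, `pairs`
#'   (data.frame `unit_id`, `M`, `V`, `n_values`) and `n_dropped`.
#' @export
type1_mean_variance <- function(counts, sample_subset = NULL,
                                variance = c("sample", "population"),
                                group_label = "all") {
  variance <- match.arg(variance)
  counts <- study_counts(counts, sample_subset)
  if (nrow(counts) < 2L) stop("Type-I needs >= 2 OTUs (variance undefined)")
  if (ncol(counts) < 1L) stop("Type-I needs >= 1 sample")
  M <- colMeans(counts)
  V <- col_vars(counts, variance)
  new_mv_set("type_I", group_label, colnames(counts), M, V, nrow(counts))
}

#' Type-III (mixed-species population) mean-variance point set
#'
#' One point per OTU: `M` is the mean of that OTU's abundances across the
#' samples and `V` the variance across the same values. Pooling conspecific
#' (same-OTU) populations across sampling units forms the mixed-species
#' population; the log-log slope b3 over these points measures its spatial
#' heterogeneity. Zero-mean and zero-variance points are dropped as for
#' [type1_mean_variance()].
#'
#' @inheritParams type1_mean_variance
#' @return A `mean_variance_set` with `level = "type_III"`.
#' @export
type3_mean_variance <- function(counts, sample_subset = NULL,
                                variance = c("sample", "population"),
                                group_label = "all") {
  variance <- match.arg(variance)
  counts <- study_counts(counts, sample_subset)
  if (ncol(counts) < 2L) stop("Type-III needs >= 2 samples (variance undefined)")
  if (nrow(counts) < 1L) stop("Type-III needs >= 1 OTU")
  M <- rowMeans(counts)
  V <- col_vars(t(counts), variance)
  new_mv_set("type_III", group_label, rownames(counts), M, V, ncol(counts))
}

new_mv_set <- function(level, group_label, unit_id, M, V, n_values) {
  keep <- M > 0 & V > 0
  pairs <- data.frame(unit_id = unit_id[keep], M = unname(M[keep]),
                      V = unname(V[keep]), n_values = n_values,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  out <- list(level = level, group_label = group_label, pairs = pairs,
              n_dropped = sum(!keep))
  class(out) <- "mean_variance_set"
  out
}

# column-wise variance without apply() overhead; x is OTUs x samples
col_vars <- function(x, variance = "sample") {
  n <- nrow(x)
  m <- colMeans(x)
  ss <- colSums(x^2) - n * m^2
  ss <- pmax(ss, 0)  # guard tiny negative round-off for constant columns
  if (variance == "sample") ss / (n - 1) else ss / n
}

study_counts <- function(counts, sample_subset = NULL) {
  if (inherits(counts, "ple_study")) counts <- counts$counts
  counts <- validate_otu_table(counts)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(counts))
    if (length(missing)) {
      stop("sample(s) not in table: ", paste(missing, collapse = ", "))
    }
    counts <- counts[, sample_subset, drop = FALSE]
  }
  counts
}

#' @export
print.mean_variance_set <- function(x, ...) {
  cat(sprintf("%s mean-variance set [%s]: %d pairs retained, %d dropped (M=0 or V=0)\n",
              x$level, x$group_label, nrow(x$pairs), x$n_dropped))
  invisible(x)
}
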