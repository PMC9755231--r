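#' Shannon alpha diversity of one sample
#'
#' `H = -sum(p_k * ln p_k)` over the positive proportions of the abundance
#' vector, in nats (natural log). Computed through [vegan::diversity()].
#'
#' @param x Non-negative abundance vector with at least one positive entry.
#' @return Shannon index H (nats).
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("all-zero abundance vector: Shannon undefined")
  unname(vegan::diversity(x, index = "shannon", base = exp(1)))
}

#' Per-sample Shannon diversity of an OTU table
#'
#' @param counts OTU matrix (rows = OTUs, columns = samples) or `ple_study`.
#' @return Data.frame `sample_id`, `shannon`.
#' @export
sample_shannon <- function(counts) {
  counts <- study_counts(counts)
  data.frame(sample_id = colnames(counts),
             shannon = apply(counts, 2L, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of a per-sample statistic across groups
#'
#' Rank-based test (with tie correction) of whether a scalar, e.g. per-sample
#' Shannon diversity, differs across host species; p-value from the
#' chi-squared approximation with k - 1 degrees of freedom. Wraps
#' [stats::kruskal.test()].
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group labels, same length as `values`.
#' @return List with `H` (statistic), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values and groups differ in length")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups")
  if (length(unique(values)) == 1L) {
    # all observations tied: no rank separation, tie correction degenerates
    return(list(H = 0, df = length(tab) - 1L, p_value = 1,
                n_groups = length(tab)))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n_groups = length(tab))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum_k |x_ki - x_kj| / sum_k (x_ki + x_kj)` over OTUs k, through
#' [vegan::vegdist()]. A pair of all-zero samples has an undefined ratio; it
#' is defined as 0 with a warning so degenerate fixtures stay usable.
#'
#' @param counts OTU matrix (rows = OTUs, columns = samples) or `ple_study`.
#' @param relative Divide each sample by its total first (default `FALSE`:
#'   raw abundances).
#' @return A `dist` object labeled with the sample ids.
#' @export
bray_curtis <- function(counts, relative = FALSE) {
  counts <- study_counts(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (relative) {
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    counts <- sweep(counts, 2L, tot, "/")
  }
  # vegdist warns about empty rows itself; the NA policy below covers them
  d <- withCallingHandlers(
    vegan::vegdist(t(counts), method = "bray"),
    warning = function(w) {
      if (grepl("empty|missing values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (anyNA(d)) {
    warning("pair(s) of all-zero samples: Bray-Curtis defined as 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. With midranks `r` of all pairwise
#' distances over `N` samples,
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{N(N-1)/4},}
#' so `R` lies in \[-1, 1\] and is 1 when every between-group distance
#' exceeds every within-group distance. Group labels are permuted with the
#' distances fixed; the p-value uses the add-one estimator
#' `p = (1 + #\{R* >= R\}) / (1 + n_permutations)`, which never returns 0.
#'
#' With `exact = TRUE` the full permutation distribution is enumerated
#' (feasible for small N) and `p = #\{R* >= R\} / N!` over all label
#' orderings, the observed one included; `n_permutations` and `seed` are then
#' ignored.
#'
#' @param d A `dist` object or square symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample in `d`.
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Integer RNG seed; required, so runs are reproducible.
#' @param exact Enumerate all permutations instead of sampling (N <= 10).
#' @return An `anosim_result`: list with `R`, `p_value`, `n_permutations`,
#'   `seed`, `exact`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed, exact = FALSE) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
      stop("d must be a dist object or square symmetric matrix")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match the number of samples")
  if (length(unique(groups)) < 2L) stop("ANOSIM needs >= 2 groups")
  if (!any(table(groups) >= 2L)) stop("no group has >= 2 members: no within-group pairs")
  r <- rank(as.vector(d))  # midranks for ties, required for R in [-1, 1]
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    within <- pair_within(g)
    (mean(r[!within]) - mean(r[within])) / denom
  }
  R_obs <- r_stat(groups)
  if (exact) {
    if (n > 10L) stop("exact enumeration limited to N <= 10 samples")
    perms <- all_permutations(n)
    R_perm <- vapply(seq_len(ncol(perms)),
                     function(k) r_stat(groups[perms[, k]]), numeric(1))
    p <- sum(R_perm >= R_obs - 1e-12) / ncol(perms)
    out <- list(R = R_obs, p_value = p, n_permutations = ncol(perms),
                seed = NA_integer_, exact = TRUE)
  } else {
    if (missing(seed)) stop("seed is required for permutation ANOSIM")
    if (n_permutations < 1L) stop("n_permutations must be >= 1")
    set.seed(seed)
    hits <- 0L
    for (k in seq_len(n_permutations)) {
      if (r_stat(sample(groups)) >= R_obs - 1e-12) hits <- hits + 1L
    }
    out <- list(R = R_obs, p_value = (1 + hits) / (1 + n_permutations),
                n_permutations = as.integer(n_permutations),
                seed = as.integer(seed), exact = FALSE)
  }
  class(out) <- "anosim_result"
  out
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p_value, if (x$exact) "exact" else "sampled",
              x$n_permutations))
  invisible(x)
}

# logical vector over the lower-triangle pair order of dist:
# TRUE where both members of the pair share a group
pair_within <- function(groups) {
  n <- length(groups)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  groups[i] == groups[j]
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n, ncol = n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    for (s in seq_len(ncol(sub))) {
      col <- col + 1L
      rest <- seq_len(n)[-k]
      out[, col] <- c(k, rest[sub[, s]])
    }
  }
  out
}
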