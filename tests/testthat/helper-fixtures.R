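# shared fixtures and independent oracles

# small OTU matrix with dimnames
make_counts <- function(m, otus = NULL, samples = NULL) {
  if (is.null(otus)) otus <- sprintf("OTU%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(otus, samples)
  m
}

make_meta <- function(sample_ids, species = "Frog_A", site = "site_01",
                      a = 12, b = 10, h = 40) {
  data.frame(sample_id = sample_ids,
             host_species = rep_len(species, length(sample_ids)),
             site_id = rep_len(site, length(sample_ids)),
             head_length_mm = rep_len(a, length(sample_ids)),
             head_width_mm = rep_len(b, length(sample_ids)),
             body_length_mm = rep_len(h, length(sample_ids)),
             stringsAsFactors = FALSE)
}

# closed-form two-variable least squares, independent of lm()
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# ANOSIM R statistic computed directly from the definition, independent of
# the package's vectorized pair bookkeeping
anosim_R_oracle <- function(dmat, groups) {
  n <- nrow(dmat)
  dv <- dmat[lower.tri(dmat)]
  r <- rank(dv)
  within <- outer(groups, groups, "==")[lower.tri(dmat)]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# a mean-variance set built straight from raw pairs, for fit-only tests
mv_from_pairs <- function(M, V, level = "type_III", group = "test") {
  out <- list(level = level, group_label = group,
              pairs = data.frame(unit_id = sprintf("u%d", seq_along(M)),
                                 M = M, V = V, n_values = 10L),
              n_dropped = 0L)
  class(out) <- "mean_variance_set"
  out
}
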