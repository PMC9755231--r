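#' Fit Taylor's power law V = a * M^b on the log-log scale
#'
#' Ordinary least squares of `ln V` on `ln M` (natural logarithm), the
#' conventional treatment of the power law `V = a M^b`. The slope `b` is the
#' heterogeneity scaling parameter; the intercept `ln a` reflects sampling
#' effort and carries little ecological meaning. A two-sided confidence
#' interval for `b` comes from the t distribution with `n - 2` degrees of
#' freedom.
#'
#' Reduced major axis regression is available behind `method = "rma"` for
#' sensitivity analysis; the default follows the standard log-linear OLS fit.
#'
#' @param mv A `mean_variance_set` from [type1_mean_variance()] or
#'   [type3_mean_variance()].
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @param method `"ols"` (default) or `"rma"` (reduced major axis).
#' @return A `ple_fit`: list with `level`, `group_label`, `b`, `ln_a`,
#'   `r_squared`, `b_ci`, `n_points`, `n_dropped`, `p_value`, `conf_level`,
#'   `method`.
#' @export
fit_ple <- function(mv, conf_level = 0.95, method = c("ols", "rma")) {
  method <- match.arg(method)
  stopifnot(inherits(mv, "mean_variance_set"))
  pairs <- mv$pairs
  if (nrow(pairs) < 3L) {
    stop(sprintf("insufficient data for PLE fit [%s/%s]: %d pair(s), need >= 3",
                 mv$level, mv$group_label, nrow(pairs)))
  }
  x <- log(pairs$M)
  y <- log(pairs$V)
  if (stats::sd(x) == 0) {
    stop(sprintf("degenerate design for PLE fit [%s/%s]: all means identical",
                 mv$level, mv$group_label))
  }
  fit <- stats::lm(y ~ x)
  # exact log-linear point sets trigger summary.lm's perfect-fit warning;
  # they are a legitimate input here (r^2 = 1, zero-width CI)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  b <- unname(stats::coef(fit)[2L])
  ln_a <- unname(stats::coef(fit)[1L])
  if (method == "rma") {
    # slope magnitude sd(y)/sd(x), sign from the correlation
    b <- sign(stats::cor(x, y)) * stats::sd(y) / stats::sd(x)
    ln_a <- mean(y) - b * mean(x)
  }
  se_b <- sm$coefficients[2L, 2L]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = length(x) - 2L)
  out <- list(level = mv$level,
              group_label = mv$group_label,
              b = b,
              ln_a = ln_a,
              r_squared = sm$r.squared,
              b_ci = c(b - tcrit * se_b, b + tcrit * se_b),
              n_points = length(x),
              n_dropped = mv$n_dropped,
              p_value = sm$coefficients[2L, 4L],
              conf_level = conf_level,
              method = method)
  class(out) <- "ple_fit"
  out
}

#' @export
print.ple_fit <- function(x, ...) {
  cat(sprintf("PLE fit (%s) [%s]: b = %.4f (%d%% CI %.4f..%.4f), ln a = %.4f\n",
              x$level, x$group_label, x$b, round(100 * x$conf_level),
              x$b_ci[1], x$b_ci[2], x$ln_a))
  cat(sprintf("  n = %d points (%d dropped), r^2 = %.4f, p = %.3g\n",
              x$n_points, x$n_dropped, x$r_squared, x$p_value))
  invisible(x)
}

#' Fit PLE models for every group of a study
#'
#' Fits [fit_ple()] at the requested level either once on the whole study
#' (`group_by = "all"`) or once per host species. Groups that cannot be
#' fitted (too few log-transformable points) are reported in the `skipped`
#' attribute rather than silently discarded.
#'
#' @param study A `ple_study` from [join_tables()].
#' @param level `"type_I"` or `"type_III"`.
#' @param group_by `"all"` or `"host_species"`.
#' @param normalize `"none"` (raw abundances, default) or `"relative"`
#'   (each sample divided by its total).
#' @inheritParams type1_mean_variance
#' @inheritParams fit_ple
#' @return Named list of `ple_fit` objects, with attribute `skipped`: a
#'   data.frame of group labels and failure reasons (possibly empty).
#' @export
grouped_fits <- function(study, level = c("type_I", "type_III"),
                         group_by = c("all", "host_species"),
                         variance = c("sample", "population"),
                         normalize = c("none", "relative"),
                         conf_level = 0.95) {
  level <- match.arg(level)
  group_by <- match.arg(group_by)
  variance <- match.arg(variance)
  normalize <- match.arg(normalize)
  stopifnot(inherits(study, "ple_study"))
  counts <- study$counts
  if (normalize == "relative") {
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    counts <- sweep(counts, 2L, tot, "/")
  }
  groups <- if (group_by == "all") {
    list(all = colnames(counts))
  } else {
    study$species_index
  }
  constructor <- if (level == "type_I") type1_mean_variance else type3_mean_variance
  fits <- list()
  skipped <- data.frame(group_label = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (g in names(groups)) {
    res <- tryCatch({
      mv <- constructor(counts, sample_subset = groups[[g]],
                        variance = variance, group_label = g)
      fit_ple(mv, conf_level = conf_level)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped, data.frame(group_label = g,
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      fits[[g]] <- res
    }
  }
  if (length(fits) == 0L) {
    stop("no group could be fitted at level ", level, ": ",
         paste(skipped$reason, collapse = "; "))
  }
  attr(fits, "skipped") <- skipped
  fits
}

#' Classify spatial heterogeneity from a fitted slope
#'
#' The ecological reading of the heterogeneity scaling parameter: `b < 1`
#' means the abundances are uniformly (regularly) distributed in space,
#' `b = 1` random, and `b > 1` highly aggregated. With
#' `basis = "point_estimate"` the point estimate alone is classified
#' (equality to 1 within a 1e-12 tolerance); with `basis = "ci_test"` the
#' community is called aggregated only when the whole confidence interval
#' exceeds 1, uniform only when it lies below 1, and random otherwise.
#'
#' @param fit A `ple_fit`.
#' @param basis `"point_estimate"` or `"ci_test"`.
#' @return A `heterogeneity_class`: list with `category` (one of `"uniform"`,
#'   `"random"`, `"aggregated"`) and `basis`.
#' @export
classify_heterogeneity <- function(fit, basis = c("point_estimate", "ci_test")) {
  basis <- match.arg(basis)
  stopifnot(inherits(fit, "ple_fit"))
  category <- if (basis == "point_estimate") {
    if (abs(fit$b - 1) <= 1e-12) "random"
    else if (fit$b > 1) "aggregated"
    else "uniform"
  } else {
    if (fit$b_ci[1] > 1) "aggregated"
    else if (fit$b_ci[2] < 1) "uniform"
    else "random"
  }
  structure(list(category = category, basis = basis),
            class = "heterogeneity_class")
}

#' @export
print.heterogeneity_class <- function(x, ...) {
  cat(sprintf("heterogeneity: %s (basis: %s)\n", x$category, x$basis))
  invisible(x)
}

#' Tabulate a list of PLE fits
#'
#' @param fits List of `ple_fit` objects (e.g. from [grouped_fits()]).
#' @param basis Classification basis passed to [classify_heterogeneity()].
#' @return Data.frame with one row per fit: group label, level, point counts,
#'   slope and CI, intercept, r^2, p-value and heterogeneity class.
#' @export
ple_fit_table <- function(fits, basis = "ci_test") {
  if (inherits(fits, "ple_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    data.frame(group_label = f$group_label, level = f$level,
               n_points = f$n_points, n_dropped = f$n_dropped,
               b = f$b, b_ci_low = f$b_ci[1], b_ci_high = f$b_ci[2],
               ln_a = f$ln_a, r2 = f$r_squared, p_value = f$p_value,
               class = classify_heterogeneity(f, basis)$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
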