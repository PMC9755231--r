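#' Trend of the heterogeneity exponent b against host skin area
#'
#' Tests whether the fitted heterogeneity scaling parameter varies with host
#' body size: OLS of per-species `b` on the species-mean skin area (2D or 3D
#' model, so the two geometric models cross-validate each other). A slope
#' indistinguishable from zero supports scale invariance of b.
#'
#' @param fits Named list of per-species `ple_fit` objects at one level
#'   (from [grouped_fits()] with `group_by = "host_species"`).
#' @param areas Species-mean areas from [species_mean_area()].
#' @param area_kind `"A3"` (3D model, default) or `"A2"` (2D silhouette).
#' @param log_area Regress on `log(area)` instead of area.
#' @return A `b_area_trend`: list with `slope`, `intercept`, `p_value`,
#'   `r_squared`, `n_species`, `level`, `area_kind`, and the `points`
#'   data.frame (`host_species`, `area`, `b`).
#' @export
b_vs_area <- function(fits, areas, area_kind = c("A3", "A2"),
                      log_area = FALSE) {
  area_kind <- match.arg(area_kind)
  if (inherits(fits, "ple_fit")) fits <- list(fits)
  species <- vapply(fits, function(f) f$group_label, character(1))
  b <- vapply(fits, function(f) f$b, numeric(1))
  level <- unique(vapply(fits, function(f) f$level, character(1)))
  if (length(level) != 1L) stop("fits mix Type-I and Type-III levels")
  col <- paste0(area_kind, "_mm2")
  idx <- match(species, areas$host_species)
  ok <- !is.na(idx)
  if (sum(ok) < 3L) stop("need >= 3 species with both a fit and an area")
  pts <- data.frame(host_species = species[ok],
                    area = areas[[col]][idx[ok]],
                    b = b[ok], stringsAsFactors = FALSE)
  if (any(pts$area <= 0)) stop("species-mean areas must be positive")
  x <- if (log_area) log(pts$area) else pts$area
  fit <- stats::lm(pts$b ~ x)
  # constant or exactly linear b over area is a legitimate degenerate input
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  # a flat response (all b equal) has zero slope and no explainable variance
  r2 <- if (stats::sd(pts$b) == 0) 0 else sm$r.squared
  p <- if (stats::sd(pts$b) == 0) 1 else sm$coefficients[2L, 4L]
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              p_value = p,
              r_squared = r2,
              n_species = nrow(pts),
              level = level,
              area_kind = area_kind,
              log_area = log_area,
              points = pts)
  class(out) <- "b_area_trend"
  out
}

#' @export
print.b_area_trend <- function(x, ...) {
  cat(sprintf("b vs %s (%s, %d species): slope = %.3g, p = %.3g, r^2 = %.3f\n",
              x$area_kind, x$level, x$n_species, x$slope, x$p_value,
              x$r_squared))
  invisible(x)
}

#' PLE fits restricted to the dominant phyla
#'
#' Ranks phyla by total abundance summed over all samples (ties broken
#' alphabetically), restricts the OTU table to each of the `top_k` dominant
#' phyla in turn, and fits both the Type-I and the Type-III model on each
#' restricted table. Phylum subsets that cannot be fitted are reported in the
#' `unfitted` attribute, not fatal.
#'
#' @param study A `ple_study`.
#' @param taxonomy Named character vector OTU id -> phylum
#'   (see [read_taxonomy()]).
#' @param top_k Number of dominant phyla to fit (default 6).
#' @inheritParams grouped_fits
#' @return List of `ple_fit` objects named `<phylum>.<level>`, with
#'   attributes `phyla` (the ranked dominant phyla) and `unfitted`
#'   (data.frame of phylum/level/reason).
#' @export
dominant_phyla_fits <- function(study, taxonomy, top_k = 6,
                                variance = c("sample", "population"),
                                conf_level = 0.95) {
  variance <- match.arg(variance)
  stopifnot(inherits(study, "ple_study"))
  counts <- study$counts
  mapped <- intersect(rownames(counts), names(taxonomy))
  if (length(mapped) == 0L) stop("taxonomy covers no OTU of the study")
  phylum <- taxonomy[mapped]
  totals <- tapply(rowSums(counts[mapped, , drop = FALSE]), phylum, sum)
  ranked <- names(totals)[order(-totals, names(totals))]
  if (length(ranked) < top_k) {
    stop(sprintf("taxonomy covers %d phylum(a), top_k = %d requested",
                 length(ranked), top_k))
  }
  top <- ranked[seq_len(top_k)]
  fits <- list()
  unfitted <- data.frame(phylum = character(), level = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (ph in top) {
    sub <- counts[mapped[phylum == ph], , drop = FALSE]
    for (level in c("type_I", "type_III")) {
      constructor <- if (level == "type_I") type1_mean_variance else type3_mean_variance
      res <- tryCatch({
        mv <- constructor(sub, variance = variance, group_label = ph)
        fit_ple(mv, conf_level = conf_level)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        unfitted <- rbind(unfitted,
                          data.frame(phylum = ph, level = level,
                                     reason = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      } else {
        fits[[paste(ph, level, sep = ".")]] <- res
      }
    }
  }
  attr(fits, "phyla") <- top
  attr(fits, "unfitted") <- unfitted
  fits
}
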