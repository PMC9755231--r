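#' Three-dimensional skin surface area of a frog body model
#'
#' The host body is idealized as a cone (head) sitting on a cylinder (trunk):
#' the cone has base diameter equal to the head width `b` and height equal to
#' the head length `a`; the cylinder has the same diameter and height equal to
#' the body length minus the head length, `h - a`. The exposed surface is the
#' lateral cone surface plus the lateral cylinder surface plus the single
#' posterior base disc:
#'
#' \deqn{A_3 = \frac{\pi b}{2}\sqrt{a^2 + b^2/4} + \pi b (h - a) + \frac{\pi b^2}{4}}
#'
#' No disc is counted at the cone/cylinder junction (it is an interior
#' surface) and limbs are deliberately omitted from the model.
#'
#' @param a Head length (mm). Vectorized.
#' @param b Head width (mm).
#' @param h Body length (mm); must satisfy `h >= a`.
#' @return 3D surface area in mm^2.
#' @examples
#' skin_area_3d(3, 8, 10)  # 92*pi: cone slant 5 gives 20*pi + 56*pi + 16*pi
#' @export
skin_area_3d <- function(a, b, h) {
  check_traits(a, b, h)
  pi * b / 2 * sqrt(a^2 + b^2 / 4) + pi * b * (h - a) + pi * b^2 / 4
}

#' Two-dimensional skin silhouette area of a frog body model
#'
#' The planar counterpart of [skin_area_3d()], used to cross-validate
#' area-dependence results: a triangular head silhouette (base `b`, height
#' `a`) plus a rectangular trunk silhouette (`b` by `h - a`):
#'
#' \deqn{A_2 = \frac{ab}{2} + b(h - a)}
#'
#' @inheritParams skin_area_3d
#' @return 2D silhouette area in mm^2.
#' @examples
#' skin_area_2d(3, 8, 10)  # 12 + 56 = 68
#' @export
skin_area_2d <- function(a, b, h) {
  check_traits(a, b, h)
  a * b / 2 + b * (h - a)
}

check_traits <- function(a, b, h) {
  if (any(a < 0) || any(b < 0) || any(h < 0)) {
    stop("morphometric traits must be non-negative")
  }
  if (any(h < a)) {
    stop("body length h must be >= head length a (cylinder height h - a)")
  }
  invisible(NULL)
}

#' Per-sample skin areas from a metadata table
#'
#' @param meta Metadata data.frame from [read_metadata()].
#' @return Data.frame: `sample_id`, `host_species`, `A2_mm2`, `A3_mm2`.
#' @export
skin_areas <- function(meta) {
  data.frame(sample_id = meta$sample_id,
             host_species = meta$host_species,
             A2_mm2 = skin_area_2d(meta$head_length_mm, meta$head_width_mm,
                                   meta$body_length_mm),
             A3_mm2 = skin_area_3d(meta$head_length_mm, meta$head_width_mm,
                                   meta$body_length_mm),
             stringsAsFactors = FALSE)
}

#' Species-mean skin areas
#'
#' Each host species' body surface area is represented by the arithmetic mean
#' of the skin areas of all sampled individuals of that species, for both the
#' 2D and the 3D model.
#'
#' @param areas Per-individual areas from [skin_areas()].
#' @return Data.frame: `host_species`, `n`, `A2_mm2`, `A3_mm2` (means).
#' @export
species_mean_area <- function(areas) {
  if (nrow(areas) == 0L) stop("no individuals to average")
  sp <- split(areas, areas$host_species)
  out <- data.frame(
    host_species = names(sp),
    n = vapply(sp, nrow, integer(1)),
    A2_mm2 = vapply(sp, function(d) mean(d$A2_mm2), numeric(1)),
    A3_mm2 = vapply(sp, function(d) mean(d$A3_mm2), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
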