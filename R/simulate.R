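#' Specification of a synthetic microbial community
#'
#' Describes one synthetic OTU table with a controlled mean-variance
#' relationship. Unit means (per sample for the Type-I target, per OTU for
#' the Type-III target) are drawn log-uniformly from `mean_range`; the
#' default spans two decades so the log-log regression design is
#' well-conditioned. Given a unit mean `M`, the unit variance is set to
#' `exp(target_ln_a) * M^target_b` and abundances are drawn from a
#' distribution matching those two moments.
#'
#' Families: `"power_law_gamma"` (gamma draws matching mean and variance
#' exactly, non-negative continuous abundances), `"poisson"` (ignores
#' `target_b`/`target_ln_a`; variance equals the mean, the random-placement
#' null with b = 1), `"negative_binomial"` (integer counts; requires
#' `V > M` for every unit).
#'
#' @param n_samples Number of samples (>= 3).
#' @param n_otus Number of OTUs (>= 3).
#' @param target_b Target heterogeneity exponent (slope of ln V on ln M).
#' @param target_ln_a Target intercept ln a.
#' @param mean_range Two positive numbers: unit means are log-uniform on this
#'   interval (default `c(1, 100)`).
#' @param family Abundance distribution family (see Details).
#' @param level_target `"type_I"` (per-sample law) or `"type_III"`
#'   (per-OTU law).
#' @param seed Integer RNG seed.
#' @param counts `"real"` (keep continuous gamma draws, default) or
#'   `"integer"` (round).
#' @return A `ple_community_spec` list.
#' @export
ple_community_spec <- function(n_samples, n_otus, target_b = 1,
                               target_ln_a = 0, mean_range = c(1, 100),
                               family = c("power_law_gamma", "poisson",
                                          "negative_binomial"),
                               level_target = c("type_I", "type_III"),
                               seed, counts = c("real", "integer")) {
  family <- match.arg(family)
  level_target <- match.arg(level_target)
  counts <- match.arg(counts)
  if (n_samples < 3L) stop("n_samples must be >= 3")
  if (n_otus < 3L) stop("n_otus must be >= 3")
  if (length(mean_range) != 2L || mean_range[1] <= 0 ||
      mean_range[2] < mean_range[1]) {
    stop("mean_range must be 0 < lo <= hi")
  }
  if (missing(seed)) stop("seed is required")
  structure(list(n_samples = as.integer(n_samples),
                 n_otus = as.integer(n_otus),
                 target_b = target_b, target_ln_a = target_ln_a,
                 mean_range = mean_range, family = family,
                 level_target = level_target, seed = as.integer(seed),
                 counts = counts),
            class = "ple_community_spec")
}

#' Simulate a community with a per-sample (Type-I) mean-variance law
#'
#' For each sample i a mean `M_i` is drawn from the spec's mean law and the
#' sample's across-OTU variance is targeted at
#' `V_i = exp(target_ln_a) * M_i^target_b`; the sample's OTU abundances are
#' then drawn i.i.d. from the spec's family with those two moments (for
#' `family = "poisson"`, all OTUs in sample i are i.i.d. Poisson(`M_i`)).
#' The Type-I fit of the result recovers `target_b` up to sampling error.
#'
#' @param spec A `ple_community_spec` with `level_target = "type_I"`.
#' @return OTU matrix (rows = OTUs, columns = samples).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "ple_community_spec"))
  if (spec$level_target != "type_I") {
    stop("simulate_community expects level_target = 'type_I'; ",
         "use simulate_mixed_population for type_III")
  }
  simulate_by_unit(spec, unit = "sample")
}

#' Simulate a mixed-species population with a per-OTU (Type-III) law
#'
#' For each OTU j a mean `M_j` is drawn from the spec's mean law, its
#' across-sample variance targeted at `V_j = exp(target_ln_a) * M_j^target_b`,
#' and the OTU's abundances across samples drawn i.i.d. with those moments.
#' The Type-III fit of the result recovers `target_b` up to sampling error.
#'
#' @param spec A `ple_community_spec` with `level_target = "type_III"`.
#' @return OTU matrix (rows = OTUs, columns = samples).
#' @export
simulate_mixed_population <- function(spec) {
  stopifnot(inherits(spec, "ple_community_spec"))
  if (spec$level_target != "type_III") {
    stop("simulate_mixed_population expects level_target = 'type_III'; ",
         "use simulate_community for type_I")
  }
  simulate_by_unit(spec, unit = "otu")
}

simulate_by_unit <- function(spec, unit) {
  set.seed(spec$seed)
  n_units <- if (unit == "sample") spec$n_samples else spec$n_otus
  n_draws <- if (unit == "sample") spec$n_otus else spec$n_samples
  M <- exp(stats::runif(n_units, log(spec$mean_range[1]),
                        log(spec$mean_range[2])))
  x <- matrix(0, nrow = n_units, ncol = n_draws)
  for (u in seq_len(n_units)) {
    x[u, ] <- draw_abundances(n_draws, M[u], spec, unit_index = u)
  }
  counts <- if (unit == "sample") t(x) else x
  if (spec$counts == "integer") counts <- round(counts)
  dimnames(counts) <- list(sprintf("OTU_%04d", seq_len(spec$n_otus)),
                           sprintf("S%04d", seq_len(spec$n_samples)))
  counts
}

# n i.i.d. draws with mean M and, for the moment-matched families,
# variance exp(ln_a) * M^b
draw_abundances <- function(n, M, spec, unit_index) {
  if (spec$family == "poisson") return(stats::rpois(n, M))
  V <- exp(spec$target_ln_a) * M^spec$target_b
  if (!is.finite(V) || V <= 0) {
    stop(sprintf("infeasible variance V = %g for unit %d (M = %g)",
                 V, unit_index, M))
  }
  if (spec$family == "power_law_gamma") {
    stats::rgamma(n, shape = M^2 / V, rate = M / V)
  } else {  # negative_binomial: requires overdispersion
    if (V <= M) {
      stop(sprintf("negative binomial needs V > M; unit %d has M = %g, V = %g",
                   unit_index, M, V))
    }
    stats::rnbinom(n, size = M^2 / (V - M), mu = M)
  }
}

#' Specification of one host species in a synthetic study
#'
#' @param name Host species label.
#' @param n_individuals Number of sampled individuals (one sample each).
#' @param trait_mean Named vector `c(a=, b=, h=)`: means of head length, head
#'   width and body length (mm).
#' @param trait_sd Named vector of the corresponding SDs (>= 0).
#' @param community A `ple_community_spec` with `level_target = "type_III"`
#'   giving the species' abundance law (its `n_samples`/`seed` are ignored;
#'   the study drives both).
#' @return A `ple_species_spec` list.
#' @export
ple_species_spec <- function(name, n_individuals,
                             trait_mean = c(a = 15, b = 12, h = 50),
                             trait_sd = c(a = 1.5, b = 1.2, h = 5),
                             community) {
  stopifnot(inherits(community, "ple_community_spec"))
  if (community$level_target != "type_III") {
    stop("study species communities use the per-OTU (type_III) law; ",
         "a per-sample law would make OTUs exchangeable and erase the ",
         "species' composition signature")
  }
  need <- c("a", "b", "h")
  if (!all(need %in% names(trait_mean)) || !all(need %in% names(trait_sd))) {
    stop("trait_mean and trait_sd must name a, b, h")
  }
  if (any(trait_sd < 0)) stop("trait SDs must be >= 0")
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 trait_mean = trait_mean[need], trait_sd = trait_sd[need],
                 community = community),
            class = "ple_species_spec")
}

#' Specification of a multi-species synthetic study
#'
#' Emulates a multi-host field survey: several host species sampled across
#' sites, each with its own morphometric trait distribution and its own OTU
#' mean profile. The OTU pool is split into a block of OTUs shared by all
#' hosts (drawn once from the mean law) plus one private block per species
#' (drawn per species), so community composition shifts between hosts and
#' ANOSIM can separate them; `shared_fraction` controls the split.
#'
#' All species' community specs must agree on `n_otus` (the per-species pool
#' size, shared block + private block).
#'
#' @param species List of `ple_species_spec` objects.
#' @param n_sites Number of sampling sites; individuals are assigned to sites
#'   cyclically within species.
#' @param seed Integer RNG seed for the whole study.
#' @param shared_fraction Fraction of each species' OTU pool shared by all
#'   species (default 0.5).
#' @param phylum_names Phylum labels assigned to OTUs.
#' @param phylum_probs Assignment probabilities (recycled/normalized).
#' @return A `ple_study_spec` list.
#' @export
ple_study_spec <- function(species, n_sites = 10, seed,
                           shared_fraction = 0.5,
                           phylum_names = paste0("Phylum_", LETTERS[1:10]),
                           phylum_probs = 2^(10:1)) {
  if (length(species) < 1L) stop("need >= 1 species")
  ok <- vapply(species, inherits, logical(1), "ple_species_spec")
  if (!all(ok)) stop("species must be a list of ple_species_spec objects")
  if (missing(seed)) stop("seed is required")
  n_otus <- unique(vapply(species, function(s) s$community$n_otus, integer(1)))
  if (length(n_otus) != 1L) stop("all species must share the same n_otus")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicated species names")
  if (length(phylum_probs) != length(phylum_names)) {
    phylum_probs <- rep_len(phylum_probs, length(phylum_names))
  }
  structure(list(species = species, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), shared_fraction = shared_fraction,
                 phylum_names = phylum_names,
                 phylum_probs = phylum_probs / sum(phylum_probs)),
            class = "ple_study_spec")
}

#' Simulate a complete multi-species host-microbiome study
#'
#' Generates the three tables every downstream stage consumes: an OTU
#' abundance matrix over all individuals of all species, a metadata table
#' with host species, site and morphometric traits, and an OTU-to-phylum
#' taxonomy. Within each species, every OTU with a positive profile mean
#' follows the species' per-OTU mean-variance law (family and `target_b`
#' from its community spec); OTUs private to other species stay at zero.
#' Traits are drawn from normals truncated at zero with `h >= a` enforced by
#' resampling (bounded attempts, then error).
#'
#' @param spec A `ple_study_spec`.
#' @return List with `counts` (OTU matrix), `metadata` (data.frame as read by
#'   [read_metadata()]) and `taxonomy` (named character vector).
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "ple_study_spec"))
  set.seed(spec$seed)
  S <- length(spec$species)
  n_otus <- spec$species[[1]]$community$n_otus
  n_shared <- round(spec$shared_fraction * n_otus)
  n_private <- n_otus - n_shared
  n_pool <- n_shared + S * n_private
  otu_ids <- sprintf("OTU_%05d", seq_len(n_pool))
  shared_idx <- seq_len(n_shared)
  private_idx <- lapply(seq_len(S), function(s) {
    if (n_private == 0L) integer(0)
    else n_shared + (s - 1L) * n_private + seq_len(n_private)
  })

  draw_means <- function(cs, k) {
    exp(stats::runif(k, log(cs$mean_range[1]), log(cs$mean_range[2])))
  }
  shared_means <- draw_means(spec$species[[1]]$community, n_shared)

  counts_blocks <- vector("list", S)
  meta_blocks <- vector("list", S)
  for (s in seq_len(S)) {
    sp <- spec$species[[s]]
    cs <- sp$community
    mu <- numeric(n_pool)
    mu[shared_idx] <- shared_means
    mu[private_idx[[s]]] <- draw_means(cs, n_private)
    n_ind <- sp$n_individuals
    x <- matrix(0, nrow = n_pool, ncol = n_ind)
    pos <- which(mu > 0)
    for (j in pos) {
      x[j, ] <- draw_abundances(n_ind, mu[j], cs, unit_index = j)
    }
    if (cs$counts == "integer") x <- round(x)
    sample_ids <- sprintf("%s_%03d", gsub("\\s+", "_", sp$name), seq_len(n_ind))
    colnames(x) <- sample_ids
    counts_blocks[[s]] <- x
    traits <- draw_traits(n_ind, sp$trait_mean, sp$trait_sd)
    meta_blocks[[s]] <- data.frame(
      sample_id = sample_ids,
      host_species = sp$name,
      site_id = sprintf("site_%02d", ((seq_len(n_ind) - 1L) %% spec$n_sites) + 1L),
      head_length_mm = traits$a,
      head_width_mm = traits$b,
      body_length_mm = traits$h,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, counts_blocks)
  rownames(counts) <- otu_ids
  metadata <- do.call(rbind, meta_blocks)
  rownames(metadata) <- NULL
  taxonomy <- stats::setNames(
    sample(spec$phylum_names, n_pool, replace = TRUE, prob = spec$phylum_probs),
    otu_ids)
  list(counts = counts, metadata = metadata, taxonomy = taxonomy)
}

# truncated-at-zero normal traits with h >= a enforced by resampling
draw_traits <- function(n, mean, sd, max_attempts = 1000L) {
  draw1 <- function(m, s) {
    v <- stats::rnorm(n, m, s)
    for (k in seq_len(max_attempts)) {
      bad <- v <= 0
      if (!any(bad)) return(v)
      v[bad] <- stats::rnorm(sum(bad), m, s)
    }
    stop("trait resampling failed: mean/SD place most mass at <= 0")
  }
  a <- draw1(mean[["a"]], sd[["a"]])
  b <- draw1(mean[["b"]], sd[["b"]])
  h <- draw1(mean[["h"]], sd[["h"]])
  for (k in seq_len(max_attempts)) {
    bad <- h < a
    if (!any(bad)) return(list(a = a, b = b, h = h))
    a[bad] <- draw1(mean[["a"]], sd[["a"]])[bad]
    h[bad] <- draw1(mean[["h"]], sd[["h"]])[bad]
  }
  stop("infeasible trait spec: could not satisfy h >= a ",
       "(mean body length too close to or below mean head length)")
}
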