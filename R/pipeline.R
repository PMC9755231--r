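#' Run the full mean-variance scaling analysis
#'
#' Orchestrates the end-to-end analysis: ingest (or simulate) the study,
#' compute skin areas, diversity statistics (per-sample Shannon,
#' Kruskal-Wallis across hosts, Bray-Curtis, ANOSIM), overall and per-species
#' Type-I/Type-III power-law fits, dominant-phylum fits, and the
#' b-versus-area trend for both levels and both area models. All outputs are
#' written as TSV files under `config$out_dir` together with a plain-text
#' provenance log; given the same config and seed the outputs are
#' byte-identical across runs.
#'
#' Config keys (a plain named list):
#' \describe{
#'   \item{`otu_table`, `metadata`, `taxonomy`}{input TSV paths
#'     (`taxonomy` optional), or}
#'   \item{`study_spec`}{a `ple_study_spec` to simulate instead of reading;}
#'   \item{`out_dir`}{output directory (created);}
#'   \item{`seed`}{integer, required (ANOSIM and simulation are stochastic);}
#'   \item{`variance`}{`"sample"` (default) or `"population"`;}
#'   \item{`normalize`}{`"none"` (default) or `"relative"`;}
#'   \item{`n_permutations`}{ANOSIM permutations (default 999);}
#'   \item{`top_k`}{dominant phyla to fit (default 6; 0 skips).}
#' }
#'
#' @param config Named list of options (see Details).
#' @return Invisibly, a list with the in-memory results (`study`, `areas`,
#'   `species_areas`, `shannon`, `kruskal`, `anosim`, `fits`, `phylum_fits`,
#'   `trends`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # -- ingest or simulate ----------------------------------------------------
  if (!is.null(config$study_spec)) {
    sim <- simulate_study(config$study_spec)
    counts <- sim$counts
    meta <- sim$metadata
    taxonomy <- sim$taxonomy
    say("input=simulated n_otus=%d n_samples=%d seed=%d",
        nrow(counts), ncol(counts), config$study_spec$seed)
  } else {
    counts <- read_otu_table(config$otu_table)
    meta <- read_metadata(config$metadata)
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
    say("input=files otu_table=%s metadata=%s", config$otu_table, config$metadata)
  }
  study <- withCallingHandlers(
    join_tables(counts, meta),
    warning = function(w) { say("join: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  say("join: %d samples kept, %d dropped, %d species, %d sites",
      ncol(study$counts), length(study$dropped),
      length(study$species_index), length(study$site_index))

  out <- list(study = study)
  files <- character()
  prov <- c(sprintf("seed=%d", config$seed),
            sprintf("variance=%s normalize=%s n_permutations=%d top_k=%d",
                    config$variance, config$normalize,
                    config$n_permutations, config$top_k))
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # -- skin areas ------------------------------------------------------------
  out$areas <- skin_areas(study$metadata)
  out$species_areas <- species_mean_area(out$areas)
  emit(out$areas, "skin_areas.tsv")
  emit(out$species_areas, "species_mean_areas.tsv")

  # -- diversity -------------------------------------------------------------
  out$shannon <- sample_shannon(study)
  emit(out$shannon, "shannon.tsv")
  if (length(study$species_index) >= 2L) {
    kw <- kruskal_wallis(out$shannon$shannon, study$metadata$host_species)
    out$kruskal <- kw
    emit(data.frame(statistic_H = kw$H, df = kw$df, p_value = kw$p_value,
                    n_groups = kw$n_groups), "kruskal_wallis.tsv")
    d <- bray_curtis(study, relative = config$normalize == "relative")
    an <- anosim(d, study$metadata$host_species,
                 n_permutations = config$n_permutations, seed = config$seed)
    out$anosim <- an
    emit(data.frame(R = an$R, p_value = an$p_value,
                    n_permutations = an$n_permutations, seed = an$seed),
         "anosim.tsv")
    dm <- as.matrix(d)
    emit(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
         "bray_curtis.tsv")
  } else {
    say("diversity: single host species, Kruskal-Wallis/ANOSIM skipped")
  }

  # -- PLE fits --------------------------------------------------------------
  out$fits <- list()
  for (level in c("type_I", "type_III")) {
    for (by in c("all", "host_species")) {
      fits <- grouped_fits(study, level = level, group_by = by,
                           variance = config$variance,
                           normalize = config$normalize)
      sk <- attr(fits, "skipped")
      if (nrow(sk)) {
        for (i in seq_len(nrow(sk))) {
          say("fit %s/%s skipped group '%s': %s", level, by,
              sk$group_label[i], sk$reason[i])
        }
      }
      out$fits[[paste(level, by, sep = ".")]] <- fits
    }
  }
  fit_rows <- do.call(rbind, lapply(out$fits, ple_fit_table))
  emit(fit_rows, "ple_fits.tsv")

  # -- dominant phyla --------------------------------------------------------
  if (!is.null(taxonomy) && config$top_k > 0L) {
    pf <- tryCatch(
      dominant_phyla_fits(study, taxonomy, top_k = config$top_k,
                          variance = config$variance),
      error = function(e) { say("phylum fits skipped: %s", conditionMessage(e))
                            NULL })
    if (!is.null(pf)) {
      out$phylum_fits <- pf
      emit(ple_fit_table(pf), "dominant_phyla_fits.tsv")
      uf <- attr(pf, "unfitted")
      if (nrow(uf)) {
        for (i in seq_len(nrow(uf))) {
          say("phylum fit skipped %s/%s: %s", uf$phylum[i], uf$level[i],
              uf$reason[i])
        }
      }
    }
  }

  # -- b vs area -------------------------------------------------------------
  sp_fits <- out$fits[c("type_I.host_species", "type_III.host_species")]
  trend_rows <- NULL
  out$trends <- list()
  for (fits in sp_fits) {
    for (kind in c("A3", "A2")) {
      tr <- tryCatch(b_vs_area(fits, out$species_areas, area_kind = kind),
                     error = function(e) { say("trend skipped: %s",
                                               conditionMessage(e)); NULL })
      if (is.null(tr)) next
      out$trends[[paste(tr$level, kind, sep = ".")]] <- tr
      trend_rows <- rbind(trend_rows,
                          data.frame(level = tr$level, area_kind = kind,
                                     slope = tr$slope, p_value = tr$p_value,
                                     r_squared = tr$r_squared,
                                     n_species = tr$n_species))
    }
  }
  if (!is.null(trend_rows)) emit(trend_rows, "b_vs_area.tsv")

  # -- provenance ------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.txt")
  writeLines(config_lines(config), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(c(sprintf("config_hash=%s", hash), prov, log_lines,
               sprintf("output=%s", basename(files))),
             file.path(config$out_dir, "provenance.log"))
  out$files <- c(files, cfg_path)
  out$config_hash <- hash
  invisible(out)
}

validate_config <- function(config) {
  problems <- character()
  if (!is.list(config)) stop("config must be a named list")
  defaults <- list(variance = "sample", normalize = "none",
                   n_permutations = 999L, top_k = 6L, taxonomy = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  has_files <- !is.null(config$otu_table) && !is.null(config$metadata)
  has_sim <- !is.null(config$study_spec)
  if (!has_files && !has_sim) {
    problems <- c(problems, "provide otu_table+metadata paths or a study_spec")
  }
  if (has_sim && !inherits(config$study_spec, "ple_study_spec")) {
    problems <- c(problems, "study_spec must be a ple_study_spec")
  }
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir is required")
  if (is.null(config$seed)) {
    problems <- c(problems,
                  "seed is required (ANOSIM permutations / simulation)")
  }
  if (!config$variance %in% c("sample", "population")) {
    problems <- c(problems, "variance must be 'sample' or 'population'")
  }
  if (!config$normalize %in% c("none", "relative")) {
    problems <- c(problems, "normalize must be 'none' or 'relative'")
  }
  if (length(problems)) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  config$seed <- as.integer(config$seed)
  config$n_permutations <- as.integer(config$n_permutations)
  config$top_k <- as.integer(config$top_k)
  config
}

config_lines <- function(config) {
  # out_dir is where results land, not what the run computes: keep it out of
  # the hashed identity so reruns into different directories compare equal
  keys <- setdiff(names(config), c("study_spec", "out_dir"))
  lines <- vapply(keys, function(k) sprintf("%s=%s", k,
                                            paste(config[[k]], collapse = ",")),
                  character(1))
  if (!is.null(config$study_spec)) {
    ss <- config$study_spec
    lines <- c(lines,
               sprintf("study_spec.n_species=%d", length(ss$species)),
               sprintf("study_spec.n_sites=%d", ss$n_sites),
               sprintf("study_spec.seed=%d", ss$seed),
               sprintf("study_spec.shared_fraction=%g", ss$shared_fraction))
  }
  sort(lines)
}
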