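#' Read an OTU abundance table
#'
#' Reads a tab-separated OTU-by-sample abundance table: first column OTU
#' identifiers, remaining columns one per sample, header row carrying the
#' sample identifiers. Cells may be raw counts or normalized abundances;
#' any non-negative number is accepted.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (rows = OTUs, columns = samples) with unique
#'   dimnames.
#' @seealso [write_otu_table()], [read_metadata()], [join_tables()]
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("OTU table has no sample columns: ", path)
  sample_ids <- header[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicated sample id(s) in header: ", paste(dup, collapse = ", "))
  }
  body <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            quote = "", comment.char = "",
                            colClasses = "character",
                            col.names = header, check.names = FALSE)
  otu_ids <- body[[1L]]
  dup <- unique(otu_ids[duplicated(otu_ids)])
  if (length(dup)) {
    stop("duplicated OTU id(s): ", paste(dup, collapse = ", "))
  }
  counts <- matrix(NA_real_, nrow = nrow(body), ncol = length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(body[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value at OTU '%s', sample '%s'",
                   otu_ids[bad[1L]], sample_ids[j]))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("negative abundance at OTU '%s', sample '%s'",
                   otu_ids[neg[1L]], sample_ids[j]))
    }
    counts[, j] <- v
  }
  counts
}

#' Write an OTU abundance table
#'
#' Writes the transpose-free TSV layout read by [read_otu_table()] and a
#' sibling provenance log (`<path>.prov`) recording how the file was made.
#'
#' @param counts Numeric matrix, rows = OTUs, columns = samples, with
#'   dimnames.
#' @param path Output TSV path.
#' @param provenance Character vector of provenance lines (input paths,
#'   options, seed) appended to the sibling log.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path, provenance = character()) {
  counts <- validate_otu_table(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, c(sprintf("writer=write_otu_table n_otus=%d n_samples=%d",
                                   nrow(counts), ncol(counts)), provenance))
  invisible(path)
}

#' Read per-sample host metadata
#'
#' Expects a TSV with header columns `sample_id`, `host_species`, `site_id`,
#' `head_length_mm`, `head_width_mm`, `body_length_mm`. Morphometric traits
#' are the inputs of the skin-area models ([skin_area_2d()],
#' [skin_area_3d()]) and must be positive.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                            comment.char = "", check.names = FALSE,
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "host_species", "site_id",
                "head_length_mm", "head_width_mm", "body_length_mm")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  meta <- meta[required]
  if (nrow(meta) == 0L) return(meta)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "))
  }
  for (tr in c("head_length_mm", "head_width_mm", "body_length_mm")) {
    v <- suppressWarnings(as.numeric(meta[[tr]]))
    if (anyNA(v)) stop("non-numeric value in column ", tr)
    if (any(v <= 0)) {
      stop(sprintf("non-positive trait in column %s (sample '%s')",
                   tr, meta$sample_id[which(v <= 0)[1L]]))
    }
    meta[[tr]] <- v
  }
  meta
}

#' Write per-sample host metadata
#'
#' @param meta Data.frame as returned by [read_metadata()].
#' @inheritParams write_otu_table
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path, provenance = character()) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, c(sprintf("writer=write_metadata n_samples=%d", nrow(meta)),
                           provenance))
  invisible(path)
}

#' Read an OTU-to-phylum taxonomy map
#'
#' Two-column TSV `otu_id<TAB>phylum` with a header. Each OTU may map to at
#' most one phylum.
#'
#' @param path Path to a TSV file.
#' @return Named character vector: names are OTU ids, values phylum names.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tax <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tax) < 2L) stop("taxonomy needs two columns: otu_id, phylum")
  names(tax)[1:2] <- c("otu_id", "phylum")
  dup <- unique(tax$otu_id[duplicated(tax$otu_id)])
  if (length(dup)) {
    stop("OTU(s) mapped more than once in taxonomy: ",
         paste(dup, collapse = ", "))
  }
  stats::setNames(as.character(tax$phylum), tax$otu_id)
}

#' Write an OTU-to-phylum taxonomy map
#'
#' @param taxonomy Named character vector (names = OTU ids, values = phyla).
#' @inheritParams write_otu_table
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path, provenance = character()) {
  df <- data.frame(otu_id = names(taxonomy), phylum = unname(taxonomy),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(path, c(sprintf("writer=write_taxonomy n_otus=%d", length(taxonomy)),
                           provenance))
  invisible(path)
}

#' Join an OTU table with sample metadata into a study object
#'
#' Samples present in both inputs are kept; samples of the table without a
#' metadata row are dropped with a warning (field datasets routinely have
#' orphans). Grouping indices by host species and site are prebuilt.
#'
#' @param counts OTU matrix from [read_otu_table()] or a simulator.
#' @param meta Metadata data.frame from [read_metadata()].
#' @return A `ple_study` object: list with elements `counts`, `metadata`,
#'   `species_index`, `site_index`, `dropped` (sample ids without metadata).
#' @export
join_tables <- function(counts, meta) {
  counts <- validate_otu_table(counts)
  keep <- intersect(colnames(counts), meta$sample_id)
  if (length(keep) == 0L) stop("no overlapping samples between table and metadata")
  dropped <- setdiff(colnames(counts), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d sample(s) without metadata: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  study <- list(counts = counts,
                metadata = meta,
                species_index = split(meta$sample_id, meta$host_species),
                site_index = split(meta$sample_id, meta$site_id),
                dropped = dropped)
  class(study) <- "ple_study"
  study
}

#' @export
print.ple_study <- function(x, ...) {
  cat(sprintf("ple_study: %d OTUs x %d samples, %d host species, %d sites\n",
              nrow(x$counts), ncol(x$counts),
              length(x$species_index), length(x$site_index)))
  if (length(x$dropped)) {
    cat(sprintf("  %d sample(s) dropped at join (no metadata)\n", length(x$dropped)))
  }
  invisible(x)
}

# shared validation: non-negative numeric matrix with unique dimnames
validate_otu_table <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("OTU table must be a numeric matrix (rows = OTUs, columns = samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("OTU table must carry OTU row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated OTU ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (anyNA(counts)) stop("OTU table contains missing values")
  if (any(counts < 0)) stop("OTU table contains negative abundances")
  counts
}

write_provenance <- function(path, lines) {
  writeLines(c(sprintf("file=%s", basename(path)), lines),
             paste0(path, ".prov"))
  invisible(NULL)
}
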