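#' Construct a PSM table
#'
#' A table of peptide-spectrum matches: each row is a peptide identified
#' from one organism's spectra against one target genome, with the match's
#' expectation value (E-value; smaller is more confident). All rows share a
#' single source organism and target genome.
#'
#' @param peptide Amino-acid strings.
#' @param protein_ids Comma-joined locus tags per peptide.
#' @param e_value Positive expectation values.
#' @param source_organism Taxon the spectra came from (length 1).
#' @param target_genome Genome searched (length 1).
#' @return A data frame of class `psm_table` with attributes
#'   `source_organism` and `target_genome`.
#' @export
psm_table <- function(peptide = character(0), protein_ids = character(0),
                      e_value = numeric(0), source_organism, target_genome) {
  peptide <- as.character(peptide)
  if (any(!nzchar(peptide))) stop_input("empty peptide sequence")
  e_value <- as.numeric(e_value)
  if (any(!is.finite(e_value)) || any(e_value <= 0)) {
    stop_input("e_value must be > 0")
  }
  if (length(source_organism) != 1L || length(target_genome) != 1L) {
    stop_input("source_organism and target_genome must be single ids")
  }
  df <- data.frame(peptide = peptide,
                   protein_ids = as.character(protein_ids),
                   e_value = e_value,
                   source_organism = rep(as.character(source_organism),
                                         length(peptide)),
                   target_genome = rep(as.character(target_genome),
                                       length(peptide)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("psm_table", "data.frame"),
            source_organism = as.character(source_organism),
            target_genome = as.character(target_genome))
}

as_psm_table <- function(df) {
  psm_table(df$peptide, df$protein_ids, df$e_value,
            unique(df$source_organism), unique(df$target_genome))
}

#' Read a PSM table from TSV
#'
#' Expects the tab-separated dialect with header
#' `peptide  protein_ids  e_value  source_organism  target_genome`
#' (protein ids comma-joined). Rows with non-positive E-values are rejected.
#'
#' @param path Path to the TSV.
#' @return A [psm_table()].
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "protein_ids", "e_value", "source_organism",
            "target_genome")
  if (!all(need %in% names(df))) {
    stop_input("PSM TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(df$source_organism)) > 1L ||
      length(unique(df$target_genome)) > 1L) {
    stop_input("PSM table mixes source organisms or target genomes")
  }
  as_psm_table(df)
}

#' Write a PSM table as TSV
#' @param table A [psm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table: %d records, spectra from %s searched against %s\n",
              nrow(x), attr(x, "source_organism"), attr(x, "target_genome")))
  if (nrow(x)) {
    cat(sprintf("log10 E-value range: [%.2f, %.2f]\n",
                min(log10(x$e_value)), max(log10(x$e_value))))
  }
  invisible(x)
}

#' PSM filtering configuration
#'
#' The identification filter: fully tryptic peptides of at least
#' `min_length` residues with log10 E-value at or below `max_log_e`
#' (default -8.3, i.e. E-value <= 5.01e-9 — the cut that keeps roughly the
#' top 10 percent most confident matches). Alternatively `top_fraction`
#' recomputes the cut from the data as that quantile of the log E-value
#' distribution.
#'
#' @param min_length Minimum peptide length in residues (default 6).
#' @param max_log_e Inclusive log10 E-value cutoff (default -8.3).
#' @param require_fully_tryptic Verify peptides against a peptide index when
#'   one is supplied to [filter_psms()] (default `TRUE`).
#' @param min_unique_peptides Distinct peptides required to call a protein
#'   observed (default 2).
#' @param top_fraction Optional fraction in `(0, 1)`; when set, the E-value
#'   cut is the corresponding quantile of the table's log10 E-values rather
#'   than the fixed `max_log_e`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_length = 6L, max_log_e = -8.3,
                          require_fully_tryptic = TRUE,
                          min_unique_peptides = 2L, top_fraction = NULL) {
  if (min_unique_peptides < 1) stop_input("min_unique_peptides must be >= 1")
  if (!is.null(top_fraction) &&
      (top_fraction <= 0 || top_fraction >= 1)) {
    stop_input("top_fraction must be in (0, 1)")
  }
  structure(list(min_length = as.integer(min_length), max_log_e = max_log_e,
                 require_fully_tryptic = isTRUE(require_fully_tryptic),
                 min_unique_peptides = as.integer(min_unique_peptides),
                 top_fraction = top_fraction),
            class = "filter_config")
}

#' Filter a PSM table
#'
#' Applies the identification filter: peptide length at least
#' `config$min_length`, log10 E-value at or below the cutoff (inclusive at
#' the boundary), and — when a peptide index for the target genome is
#' supplied and `require_fully_tryptic` is set — presence of the peptide in
#' that index. Records sharing a peptide are collapsed to the best (lowest)
#' E-value. The filter is idempotent.
#'
#' @param table A [psm_table()].
#' @param config A [filter_config()].
#' @param index Optional [build_peptide_index()] result for the table's
#'   target genome; a genome mismatch is an error.
#' @return The filtered [psm_table()]; when `index` is given, the digestion
#'   parameters are recorded in attribute `digest_params`.
#' @export
filter_psms <- function(table, config = filter_config(), index = NULL) {
  stopifnot(inherits(table, "psm_table"))
  if (!is.null(index) &&
      !identical(index$organism_id, attr(table, "target_genome"))) {
    stop_input("peptide index is for ", index$organism_id,
               " but table targets ", attr(table, "target_genome"))
  }
  loge <- log10(table$e_value)
  cut <- if (!is.null(config$top_fraction) && nrow(table) > 0L) {
    stats::quantile(loge, config$top_fraction, type = 7, names = FALSE)
  } else {
    config$max_log_e
  }
  # inclusive boundary; small epsilon guards log10 round-trip noise only
  keep <- nchar(table$peptide) >= config$min_length & loge <= cut + 1e-9
  if (!is.null(index) && config$require_fully_tryptic) {
    key <- if (index$params$collapse_IL) collapse_il(table$peptide) else
      table$peptide
    keep <- keep & key %in% names(index$entries)
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) > 1L && anyDuplicated(out$peptide)) {
    out <- out[order(out$e_value), , drop = FALSE]
    out <- out[!duplicated(out$peptide), , drop = FALSE]
    out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  }
  rownames(out) <- NULL
  res <- as_psm_table(if (nrow(out)) out else
    data.frame(peptide = character(0), protein_ids = character(0),
               e_value = numeric(0),
               source_organism = attr(table, "source_organism"),
               target_genome = attr(table, "target_genome"),
               stringsAsFactors = FALSE)[0, ])
  attr(res, "source_organism") <- attr(table, "source_organism")
  attr(res, "target_genome") <- attr(table, "target_genome")
  if (!is.null(index)) attr(res, "digest_params") <- index$params
  res
}

#' Percentile interval boundaries of a log E-value distribution
#'
#' Divides a log10 E-value distribution into five confidence intervals A-E
#' by its 10th, 25th, 50th, 75th and 90th percentiles (A: most confident,
#' all values at or below the 10th percentile; E: all values above the 90th).
#' Percentiles use linear interpolation between closest ranks.
#'
#' @param log_e_values Nonempty numeric vector of log10 E-values.
#' @return An object of class `interval_boundaries`: named numeric vector of
#'   the four cut points `p10`, `p25`, `p50`, `p75`, `p90`.
#' @export
evalue_percentile_intervals <- function(log_e_values) {
  x <- as.numeric(log_e_values)
  if (length(x) == 0L || any(!is.finite(x))) {
    stop_input("log_e_values must be nonempty and finite")
  }
  b <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                       names = FALSE)
  structure(stats::setNames(b, c("p10", "p25", "p50", "p75", "p90")),
            class = "interval_boundaries")
}

#' @export
print.interval_boundaries <- function(x, ...) {
  b <- unclass(x)
  cat("E-value confidence intervals (log10 units):\n")
  cat(sprintf("  A: <= %.3g\n", b[1]))
  lab <- c("B", "C", "D")
  for (i in 1:3) cat(sprintf("  %s: (%.3g, %.3g]\n", lab[i], b[i], b[i + 1]))
  cat(sprintf("  E: > %.3g\n", b[4]))
  invisible(x)
}

#' Assign log E-values to confidence intervals
#'
#' Membership follows the half-open pattern: interval A holds values at or
#' below the 10th-percentile cut, B values above it and at or below the
#' 25th-percentile cut, C and D likewise up to the 75th-percentile cut, and
#' E everything above that. The assignment partitions the input.
#'
#' @param log_e_values Numeric vector.
#' @param boundaries An [evalue_percentile_intervals()] result.
#' @return Factor with levels `A`-`E`.
#' @export
assign_interval <- function(log_e_values, boundaries) {
  b <- unclass(boundaries)
  cut(log_e_values, breaks = unique(c(-Inf, b[1:4], Inf)),
      labels = if (length(unique(b[1:4])) == 4L)
        c("A", "B", "C", "D", "E") else NULL,
      right = TRUE)
}

#' Infer observed proteins from a filtered PSM table
#'
#' A protein counts as positively observed when supported by at least
#' `min_unique_peptides` distinct peptide sequences. A peptide mapping to
#' several proteins supports each of them (no parsimony grouping: the unit
#' of reporting is the locus).
#'
#' @param table A filtered [psm_table()].
#' @param min_unique_peptides Distinct-peptide threshold (default 2).
#' @return Named list: protein id -> character vector of supporting
#'   peptides; only proteins meeting the threshold are returned.
#' @export
infer_proteins <- function(table, min_unique_peptides = 2L) {
  stopifnot(inherits(table, "psm_table"))
  if (nrow(table) == 0L) return(structure(list(), names = character(0)))
  ids <- split_ids(table$protein_ids)
  prot <- unlist(ids, use.names = FALSE)
  pep <- rep(table$peptide, lengths(ids))
  support <- lapply(split(pep, prot), unique)
  support[lengths(support) >= min_unique_peptides]
}
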