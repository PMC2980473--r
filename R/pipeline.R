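#' Run the proof-of-concept panel analysis
#'
#' Orchestrates the full trans-organism evaluation for a panel of sequenced
#' organisms: builds a tryptic peptide index per organism, filters each
#' organism's self-search PSM table, runs the trans-organism search of every
#' query against every neighbor, converts counts to normalized ratios,
#' computes the 16S distance matrix, fits the decay and sigmoid models to
#' the pooled points, selects the better model, and derives the 95 percent
#' prediction band. With `out_dir` set, all intermediates are written
#' (points and distances as TSV, band as TSV, fit and summary as JSON), so
#' a run is fully auditable; record counts at each stage are logged.
#'
#' @param proteomes Named list of [proteome()] objects (panel organisms).
#' @param markers Named character vector of 16S sequences (same names).
#' @param psm_tables Named list of self-search [psm_table()]s (same names).
#' @param digest [digest_params()].
#' @param filter [filter_config()].
#' @param align [alignment_params()].
#' @param level `"peptide"` or `"protein"` ratios.
#' @param alpha Model-selection significance level.
#' @param out_dir Optional output directory.
#' @param verbose Log per-stage record counts (default `FALSE`).
#' @return An object of class `panel_run`: list with `points`, `distances`,
#'   `indices`, `filtered` (PSM tables), `fits`, `selection`, `fit` (the
#'   chosen model or `NULL`), `band`, and `regression_error` (message when
#'   the panel is too small to fit).
#' @export
run_panel <- function(proteomes, markers, psm_tables,
                      digest = digest_params(), filter = filter_config(),
                      align = alignment_params(),
                      level = c("peptide", "protein"), alpha = 0.05,
                      out_dir = NULL, verbose = FALSE) {
  level <- match.arg(level)
  orgs <- names(proteomes)
  if (is.null(orgs) || !setequal(orgs, names(psm_tables)) ||
      !all(orgs %in% names(markers))) {
    stop_input("proteomes, markers and psm_tables must share organism names")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage ", name, ": ", conditionMessage(e)),
                          class = c("transprot_stage_error", "error")))
    })
  }
  indices <- stage("digestion", {
    lapply(proteomes, build_peptide_index, params = digest)
  })
  for (o in orgs) say("index %s: %d peptides", o, length(indices[[o]]$entries))
  filtered <- stage("psm_filter", {
    stats::setNames(lapply(orgs, function(o) {
      f <- filter_psms(psm_tables[[o]], filter, indices[[o]])
      say("filter %s: %d -> %d records", o, nrow(psm_tables[[o]]), nrow(f))
      f
    }), orgs)
  })
  distances <- if (length(orgs) >= 2L) {
    stage("distances", distance_matrix(markers[orgs], align))
  } else {
    matrix(0, 1, 1, dimnames = list(orgs, orgs))
  }
  points <- stage("conservation", {
    pts <- do.call(rbind, lapply(orgs, function(q) {
      conservation_profile(q, orgs, filtered[[q]], indices, distances,
                           level = level,
                           min_unique_peptides = filter$min_unique_peptides)
    }))
    pts <- pts[order(pts$distance), , drop = FALSE]
    rownames(pts) <- NULL
    class(pts) <- c("conservation_profile", "data.frame")
    pts
  })
  say("conservation: %d points", nrow(points))
  fits <- list()
  regression_error <- NULL
  for (m in c("decay", "sigmoid")) {
    f <- tryCatch(
      switch(m, decay = fit_decay(points), sigmoid = fit_sigmoid(points)),
      error = function(e) conditionMessage(e))
    if (inherits(f, "conservation_fit")) fits[[m]] <- f
    else regression_error <- c(regression_error, f)
  }
  selection <- if (length(fits)) select_model(fits, alpha) else NULL
  fit <- selection$best
  band <- if (!is.null(fit) && !fit$degenerate) prediction_band(fit) else NULL
  res <- structure(list(points = points, distances = distances,
                        indices = indices, filtered = filtered, fits = fits,
                        selection = selection, fit = fit, band = band,
                        regression_error = regression_error,
                        level = level),
                   class = "panel_run")
  if (!is.null(out_dir)) write_panel_run(res, out_dir)
  res
}

write_panel_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_conservation_points(res$points,
                            file.path(out_dir, "conservation_points.tsv"))
  write_distance_matrix(res$distances,
                        file.path(out_dir, "distance_matrix.tsv"))
  if (!is.null(res$band)) {
    utils::write.table(as.data.frame(res$band),
                       file.path(out_dir, "prediction_band.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$fit)) {
    write_fit_json(res$fit, file.path(out_dir, "fit.json"), res$selection)
  }
  summary <- list(
    level = res$level,
    organisms = rownames(res$distances),
    n_points = nrow(res$points),
    model = if (!is.null(res$fit)) res$fit$model else NULL,
    r2 = if (!is.null(res$fit)) res$fit$r2 else NULL,
    regression_error = res$regression_error)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.panel_run <- function(x, ...) {
  cat(sprintf("Panel run (%s level): %d organisms, %d conservation points\n",
              x$level, nrow(x$distances), nrow(x$points)))
  if (!is.null(x$fit)) {
    cat("Chosen model:\n")
    print(x$fit)
  } else {
    cat("Regression not performed:",
        paste(x$regression_error, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Characterize an unsequenced isolate against a sequenced panel
#'
#' Given an isolate's filtered PSM identifications (obtained by searching
#' its spectra against neighbor genomes is emulated here by exact peptide
#' matching) and its partial 16S sequence, reports per-neighbor conserved
#' peptide and protein counts, a normalized ratio, and whether each point
#' falls within the fitted 95 percent prediction band. Because an isolate
#' has no own-genome search, ratios are normalized to the maximum
#' per-neighbor peptide count for that isolate. The closest relative is the
#' neighbor with the most conserved peptides; coverage gaps are computed
#' along that genome's gene order.
#'
#' @param isolate_psms The isolate's [psm_table()] (peptides from its
#'   spectra); it is re-filtered defensively with `filter`.
#' @param isolate_marker The isolate's partial 16S sequence.
#' @param panel Either a [run_panel()] result or a list with elements
#'   `proteomes`, `indices`, `markers`.
#' @param proteomes,markers Required when `panel` is a `panel_run` (which
#'   stores only indices): named list/vector as in [run_panel()]. Ignored
#'   otherwise if `panel` carries them.
#' @param fit Optional `conservation_fit` used for the within-band flag.
#' @param filter [filter_config()].
#' @param align [alignment_params()].
#' @param min_genes Coverage-gap threshold (default 5).
#' @param level Prediction-band level (default 0.95).
#' @return An object of class `isolate_report`: list with `isolate`, `rows`
#'   (one per neighbor, sorted by distance: `neighbor`, `distance`,
#'   `conserved_peptides`, `conserved_proteins`, `ratio`, `within_band`),
#'   `closest_relative`, `furthest_relative`, `gaps`, `categories`.
#' @export
characterize_isolate <- function(isolate_psms, isolate_marker, panel,
                                 proteomes = NULL, markers = NULL,
                                 fit = NULL, filter = filter_config(),
                                 align = alignment_params(), min_genes = 5L,
                                 level = 0.95) {
  stopifnot(inherits(isolate_psms, "psm_table"))
  if (nrow(isolate_psms) == 0L) stop_input("empty isolate PSM table")
  if (inherits(panel, "panel_run")) {
    indices <- panel$indices
    fit <- fit %||% panel$fit
  } else {
    indices <- panel$indices
    proteomes <- proteomes %||% panel$proteomes
    markers <- markers %||% panel$markers
  }
  if (is.null(proteomes) || is.null(markers)) {
    stop_input("panel proteomes and markers are required")
  }
  iso <- attr(isolate_psms, "source_organism")
  flt <- filter_psms(isolate_psms, filter)
  if (nrow(flt) == 0L) stop_input("no isolate PSMs survive the filter")
  orgs <- names(indices)
  dist_iso <- vapply(orgs, function(o) {
    pairwise_distance_16s(isolate_marker, markers[[o]], align)
  }, numeric(1))
  searches <- lapply(orgs, function(o) trans_search(flt, indices[[o]]))
  names(searches) <- orgs
  n_pep <- vapply(searches, function(s) length(unique(s$peptide)), integer(1))
  n_prot <- vapply(searches, function(s) {
    length(infer_proteins(s, filter$min_unique_peptides))
  }, integer(1))
  if (max(n_pep) == 0L) stop_input("no isolate peptide matched any panel genome")
  # isolate rule: no own-genome search exists, so normalize to the maximum
  # per-neighbor peptide count
  ratio <- normalized_ratio(n_pep, max(n_pep))
  within <- rep(NA, length(orgs))
  if (!is.null(fit) && !fit$degenerate) {
    pi <- prediction_interval(fit, dist_iso, level)
    within <- ratio >= pi[, "lwr"] & ratio <= pi[, "upr"]
  }
  rows <- data.frame(neighbor = orgs, distance = dist_iso,
                     conserved_peptides = n_pep,
                     conserved_proteins = n_prot, ratio = ratio,
                     within_band = within, stringsAsFactors = FALSE)
  rows <- rows[order(rows$distance), , drop = FALSE]
  rownames(rows) <- NULL
  closest <- rows$neighbor[which.max(rows$conserved_peptides)]
  informative <- rows$neighbor[rows$conserved_peptides > 0]
  furthest <- informative[which.max(rows$distance[rows$neighbor %in%
                                                    informative])]
  gaps <- NULL
  categories <- NULL
  ref <- proteomes[[closest]]
  if (!any(is.na(ref$records$start))) {
    obs <- names(infer_proteins(searches[[closest]],
                                filter$min_unique_peptides))
    ord <- ref$records[order(ref$records$start), , drop = FALSE]
    gaps <- detect_coverage_gaps(ord, stats::setNames(list(obs), iso),
                                 min_genes = min_genes, scope = "any",
                                 genome = closest)
  }
  if (!all(is.na(ref$records$category))) {
    obs <- names(infer_proteins(searches[[closest]],
                                filter$min_unique_peptides))
    cats <- ref$records$category[ref$records$id %in% obs]
    if (length(cats)) categories <- table(cats) / length(cats)
  }
  structure(list(isolate = iso, rows = rows, closest_relative = closest,
                 furthest_relative = furthest, gaps = gaps,
                 categories = categories, level = level),
            class = "isolate_report")
}

#' @export
print.isolate_report <- function(x, ...) {
  cat(sprintf("Isolate %s characterized against %d neighbors\n",
              x$isolate, nrow(x$rows)))
  print(x$rows, digits = 4)
  cat(sprintf("Closest relative: %s; furthest informative relative: %s\n",
              x$closest_relative, x$furthest_relative))
  if (!is.null(x$gaps) && nrow(x$gaps)) {
    cat(sprintf("%d coverage gap(s) along %s\n", nrow(x$gaps),
                x$closest_relative))
  }
  invisible(x)
}
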