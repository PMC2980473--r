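#' Normalized observation ratio
#'
#' The count of peptides (or proteins) identified against a neighbor genome
#' divided by the count identified against the organism's own genome. The
#' reporting layer rounds to two decimals; for example 3067 neighbor
#' identifications over 4594 self identifications gives 0.67.
#'
#' @param n_neighbor Count against the neighbor genome (>= 0).
#' @param n_self Count against the organism's own genome (> 0).
#' @return `n_neighbor / n_self`.
#' @export
normalized_ratio <- function(n_neighbor, n_self) {
  if (any(n_self <= 0)) stop_input("undefined ratio: n_self must be > 0")
  if (any(n_neighbor < 0)) stop_input("n_neighbor must be >= 0")
  n_neighbor / n_self
}

#' Trans-organism search by exact peptide membership
#'
#' The desk-scale surrogate for re-searching one organism's spectra against
#' a neighbor genome: a peptide identified against the organism's own
#' genome is retained if and only if its exact sequence occurs in the
#' neighbor's tryptic peptide index (after any I/L collapse configured at
#' indexing). A peptide with even one substituted residue is unmatched,
#' which is the mechanism by which sequence divergence erodes
#' identifiability. Peptides containing nonstandard residues (B, Z, X, U)
#' never match. Protein ids are rewritten to the neighbor's loci and the
#' target genome becomes the neighbor.
#'
#' @param table A filtered [psm_table()] from the organism's self search.
#' @param neighbor_index [build_peptide_index()] result for the neighbor.
#' @return The restricted [psm_table()] targeting the neighbor genome.
#' @export
trans_search <- function(table, neighbor_index) {
  stopifnot(inherits(table, "psm_table"),
            inherits(neighbor_index, "peptide_index"))
  qp <- attr(table, "digest_params")
  if (!is.null(qp) && !same_digest_params(qp, neighbor_index$params)) {
    stop_input("digestion parameters of query filter and neighbor index differ")
  }
  key <- if (neighbor_index$params$collapse_IL) collapse_il(table$peptide)
         else table$peptide
  keep <- key %in% names(neighbor_index$entries) & !has_nonstandard(key)
  out <- table[keep, , drop = FALSE]
  res <- psm_table(out$peptide,
                   join_ids(neighbor_index$entries[key[keep]]),
                   out$e_value,
                   source_organism = attr(table, "source_organism"),
                   target_genome = neighbor_index$organism_id)
  attr(res, "digest_params") <- neighbor_index$params
  res
}

#' Conservation profile of a query organism across a neighbor panel
#'
#' For each neighbor, counts the query's filtered peptide (or inferred
#' protein) identifications that survive the trans-organism search against
#' that neighbor's genome, and normalizes by the self-search count. One
#' point per neighbor, sorted by 16S distance; these points are the data
#' for [fit_decay()] / [fit_sigmoid()].
#'
#' @param query Query organism id.
#' @param neighbors Character vector of neighbor organism ids (may include
#'   the query itself, giving the (0, 1) point).
#' @param psm_table The query's *filtered* self-search [psm_table()].
#' @param indices Named list of `peptide_index` objects covering query and
#'   neighbors.
#' @param distances Distance matrix from [distance_matrix()] containing all
#'   organisms involved.
#' @param level `"peptide"` or `"protein"`; protein level applies
#'   [infer_proteins()] after the trans search.
#' @param min_unique_peptides Protein-inference threshold (protein level).
#' @return Data frame of class `conservation_profile` with columns `query`,
#'   `neighbor`, `distance`, `level`, `n_self`, `n_neighbor`, `ratio`.
#' @export
conservation_profile <- function(query, neighbors, psm_table, indices,
                                 distances, level = c("peptide", "protein"),
                                 min_unique_peptides = 2L) {
  level <- match.arg(level)
  stopifnot(inherits(psm_table, "psm_table"))
  if (!query %in% names(indices)) stop_input("missing self index for ", query)
  if (!identical(attr(psm_table, "target_genome"), query)) {
    stop_input("psm_table must be the query's self search")
  }
  miss <- setdiff(c(query, neighbors), rownames(distances))
  if (length(miss)) stop_input("absent from distance matrix: ",
                               paste(miss, collapse = ", "))
  count_of <- function(tab) {
    if (level == "peptide") length(unique(tab$peptide))
    else length(infer_proteins(tab, min_unique_peptides))
  }
  n_self <- count_of(psm_table)
  if (n_self == 0L) stop_input("self search yielded no identifications")
  rows <- lapply(neighbors, function(nb) {
    if (!nb %in% names(indices)) stop_input("missing index for ", nb)
    tab <- trans_search(psm_table, indices[[nb]])
    data.frame(query = query, neighbor = nb,
               distance = distances[query, nb], level = level,
               n_self = n_self, n_neighbor = count_of(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- normalized_ratio(out$n_neighbor, out$n_self)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Write conservation points as TSV
#' @param points A `conservation_profile` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_points <- function(points, path) {
  utils::write.table(as.data.frame(points), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Functional-category conservation of observed orthologs
#'
#' Two normalizations are supported. Mode `"methods"`: for each category
#' (and overall), the number of orthologs observed via the neighbor genome
#' divided by the number observed via the organism's own genome — how much
#' of each functional category survives the trans search. Mode `"figure2"`:
#' the composition view — observed proteins in each category divided by the
#' total observed in the set, for self and neighbor separately.
#'
#' @param observed_self Character vector of query loci observed in the self
#'   search.
#' @param observed_via_neighbor Character vector of loci observed via the
#'   neighbor genome; neighbor loci are translated through the ortholog map.
#' @param ortholog_map Data frame with columns `query_locus`,
#'   `neighbor_locus`, `category` (one neighbor locus at most per query
#'   locus). Observed loci absent from the map are skipped and counted in
#'   attribute `n_unmapped`.
#' @param mode `"methods"` or `"figure2"`.
#' @return Mode `"methods"`: named numeric of per-category fractions plus
#'   `overall`. Mode `"figure2"`: matrix with rows `self`/`neighbor` and one
#'   column per category.
#' @export
category_conservation <- function(observed_self, observed_via_neighbor,
                                  ortholog_map,
                                  mode = c("methods", "figure2")) {
  mode <- match.arg(mode)
  need <- c("query_locus", "neighbor_locus", "category")
  if (!all(need %in% names(ortholog_map))) {
    stop_input("ortholog_map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ortholog_map$query_locus)) {
    stop_input("ortholog_map maps a query locus to several neighbor loci")
  }
  if (length(observed_self) == 0L) stop_input("empty self-observed set")
  # translate neighbor loci back to query loci; accept query loci as-is
  nb_as_query <- unique(c(
    observed_via_neighbor[observed_via_neighbor %in% ortholog_map$query_locus],
    ortholog_map$query_locus[match(
      observed_via_neighbor[observed_via_neighbor %in%
                              ortholog_map$neighbor_locus],
      ortholog_map$neighbor_locus)]))
  self_mapped <- intersect(unique(observed_self), ortholog_map$query_locus)
  n_unmapped <- length(unique(observed_self)) - length(self_mapped) +
    sum(!(observed_via_neighbor %in% ortholog_map$query_locus |
            observed_via_neighbor %in% ortholog_map$neighbor_locus))
  cat_of <- function(loci) {
    ortholog_map$category[match(loci, ortholog_map$query_locus)]
  }
  cats <- sort(unique(ortholog_map$category))
  self_n <- table(factor(cat_of(self_mapped), levels = cats))
  nb_n <- table(factor(cat_of(nb_as_query), levels = cats))
  if (mode == "methods") {
    frac <- ifelse(self_n > 0, as.numeric(nb_n) / as.numeric(self_n), NA_real_)
    out <- c(stats::setNames(frac, cats),
             overall = length(nb_as_query) / length(self_mapped))
  } else {
    out <- rbind(self = as.numeric(self_n) / max(length(self_mapped), 1L),
                 neighbor = as.numeric(nb_n) / max(length(nb_as_query), 1L))
    colnames(out) <- cats
  }
  attr(out, "n_unmapped") <- n_unmapped
  if (n_unmapped > 0L) {
    message(n_unmapped, " observed loci absent from the ortholog map were skipped")
  }
  out
}

#' Detect genomic coverage gaps
#'
#' Scans a genomically ordered gene table for maximal runs of consecutive
#' genes with no observed protein, reporting runs of at least `min_genes`
#' genes. With `scope = "all"` a gene counts as unobserved only when no
#' isolate observed it (gaps common to the whole panel); with
#' `scope = "any"` runs are computed per isolate.
#'
#' @param gene_table Data frame with columns `id`, `start`, `end`, sorted by
#'   `start`, coordinates present (a [proteome()]'s `records` works).
#' @param observed Named list: isolate id -> character vector of observed
#'   protein ids (loci of `gene_table`).
#' @param min_genes Minimum run length to report (default 5).
#' @param scope `"all"` or `"any"`.
#' @param genome Reference genome id recorded in the output.
#' @return Data frame of class `coverage_gaps`: `genome`, `start_gene`,
#'   `end_gene` (gene indices), `start_bp`, `end_bp`, `n_genes`,
#'   `absent_in` (comma-joined isolate ids).
#' @export
detect_coverage_gaps <- function(gene_table, observed, min_genes = 5L,
                                 scope = c("all", "any"),
                                 genome = "reference") {
  scope <- match.arg(scope)
  if (inherits(gene_table, "proteome")) {
    genome <- gene_table$organism_id
    gene_table <- gene_table$records
  }
  if (any(is.na(gene_table$start)) || any(is.na(gene_table$end))) {
    stop_input("gene_table lacks coordinates")
  }
  if (is.unsorted(gene_table$start)) {
    stop_input("gene_table must be sorted by start coordinate")
  }
  if (length(observed) == 0L || is.null(names(observed))) {
    stop_input("observed must be a named list of isolate protein sets")
  }
  run_gaps <- function(unobs, absent_in) {
    r <- rle(unobs)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_genes
    if (!any(keep)) return(NULL)
    data.frame(genome = genome, start_gene = starts[keep],
               end_gene = ends[keep],
               start_bp = gene_table$start[starts[keep]],
               end_bp = gene_table$end[ends[keep]],
               n_genes = r$lengths[keep],
               absent_in = absent_in, stringsAsFactors = FALSE)
  }
  if (scope == "all") {
    seen <- unique(unlist(observed, use.names = FALSE))
    gaps <- run_gaps(!(gene_table$id %in% seen),
                     paste(names(observed), collapse = ","))
  } else {
    gaps <- do.call(rbind, lapply(names(observed), function(iso) {
      run_gaps(!(gene_table$id %in% observed[[iso]]), iso)
    }))
  }
  if (is.null(gaps)) {
    gaps <- data.frame(genome = character(0), start_gene = integer(0),
                       end_gene = integer(0), start_bp = integer(0),
                       end_bp = integer(0), n_genes = integer(0),
                       absent_in = character(0), stringsAsFactors = FALSE)
  }
  rownames(gaps) <- NULL
  class(gaps) <- c("coverage_gaps", "data.frame")
  gaps
}

#' Write coverage gaps as BED
#'
#' Emits 0-based half-open intervals on the reference genome for
#' genome-browser use; the name field lists the isolates lacking the
#' region.
#'
#' @param gaps A [detect_coverage_gaps()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaps_bed <- function(gaps, path) {
  bed <- data.frame(chrom = gaps$genome, start = gaps$start_bp - 1L,
                    end = gaps$end_bp,
                    name = paste0("gap_", seq_len(nrow(gaps)), "_absent_in_",
                                  gsub(",", "+", gaps$absent_in)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
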