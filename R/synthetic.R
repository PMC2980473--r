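#' Synthetic clade configuration
#'
#' Parameters for simulating a star-shaped clade of bacterial proteomes with
#' coupled 16S marker sequences. Each taxon diverges from a common ancestor
#' by a target 16S p-distance `d`; its proteins accumulate amino-acid
#' substitutions at per-site probability `kappa * d`, and its 16S marker at
#' per-site probability `d`. The simulator exists so the whole pipeline —
#' digestion, filtering, trans-organism search, regression — can be run and
#' validated without raw mass-spectrometry data.
#'
#' @param n_proteins Number of protein-coding genes per taxon.
#' @param protein_length_mean Mean protein length in residues; lengths are
#'   drawn geometric with this mean and a 50-residue minimum.
#' @param target_16s_distances Numeric vector of per-taxon 16S distances in
#'   `[0, 1)`, one per taxon.
#' @param kappa Divergence coupling: per-site amino-acid substitution
#'   probability is `kappa * d`. Default 5, which reproduces a steep drop in
#'   peptide conservation over 16S distances 0-0.05.
#' @param marker_length 16S marker length in bases (default 850, a partial
#'   sequence representing the 5' end of the gene).
#' @param deleted_region Optional `list(taxon=, from=, to=)`: gene indices
#'   (inclusive) deleted from that taxon, emulating a genomic island absent
#'   from an isolate.
#' @param n_categories Number of functional-category labels assigned to
#'   genes (ancestral genes keep their category in every taxon).
#' @param seed Integer seed; the simulation is a pure function of the
#'   configuration including this seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 60L, protein_length_mean = 300,
                             target_16s_distances = c(0, 0.01, 0.02, 0.05, 0.1),
                             kappa = 5, marker_length = 850L,
                             deleted_region = NULL, n_categories = 4L,
                             seed = 1L) {
  d <- as.numeric(target_16s_distances)
  if (any(d < 0 | d >= 1)) stop_input("distances must lie in [0, 1)")
  if (kappa < 0) stop_input("kappa must be >= 0")
  if (length(d) && kappa * max(d) >= 1) {
    stop_input("kappa * max(distance) must be < 1")
  }
  if (marker_length <= 0) stop_input("marker_length must be > 0")
  if (!is.null(deleted_region)) {
    stopifnot(all(c("taxon", "from", "to") %in% names(deleted_region)))
    if (deleted_region$from > deleted_region$to ||
        deleted_region$from < 1 || deleted_region$to > n_proteins) {
      stop_input("deleted_region indices out of range")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_mean = protein_length_mean,
                 target_16s_distances = d, kappa = kappa,
                 marker_length = as.integer(marker_length),
                 deleted_region = deleted_region,
                 n_categories = as.integer(n_categories),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# replace each character with probability p by a uniformly chosen *different*
# symbol from `alphabet`; consumes the current RNG stream
mutate_chars <- function(chars, p, alphabet) {
  n <- length(chars)
  hit <- stats::runif(n) < p
  nh <- sum(hit)
  if (nh > 0L) {
    k <- length(alphabet)
    cur <- match(chars[hit], alphabet)
    r <- sample.int(k - 1L, nh, replace = TRUE)
    chars[hit] <- alphabet[ifelse(r < cur, r, r + 1L)]
  }
  chars
}

#' Evolve a sequence by i.i.d. per-site substitution
#'
#' Each site is independently replaced, with the given probability, by a
#' symbol drawn uniformly from the alphabet excluding the current one. No
#' indels are introduced, so divergence equals expected Hamming distance.
#'
#' @param sequence Residue or base string over `alphabet`.
#' @param substitution_probability Per-site substitution probability in
#'   `[0, 1]`.
#' @param alphabet `"protein"`, `"dna"`, or a character vector of symbols.
#' @param seed Integer seed; identical arguments give identical output.
#' @return The evolved string (same length).
#' @export
evolve_sequence <- function(sequence, substitution_probability,
                            alphabet = c("protein", "dna"), seed = 1L) {
  if (is.character(alphabet) && length(alphabet) == 1L) {
    alphabet <- switch(match.arg(alphabet), protein = AA_STANDARD,
                       dna = DNA_BASES)
  }
  if (length(sequence) != 1L || !nzchar(sequence)) stop_input("empty sequence")
  p <- substitution_probability
  if (p < 0 || p > 1) stop_input("substitution_probability must be in [0, 1]")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% alphabet)) stop_input("symbol outside alphabet")
  with_seed(seed, paste(mutate_chars(chars, p, alphabet), collapse = ""))
}

rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulate a clade of diverged proteomes with 16S markers
#'
#' Draws an ancestral proteome with uniform residue frequencies and an
#' ancestral 16S marker, then derives each taxon by independent per-site
#' substitution: proteins at probability `kappa * d`, the marker at
#' probability `d`. Gene ids, coordinates and categories are shared across
#' taxa except within an optional deleted region. The true pairwise distance
#' matrix holds the expected marker p-distance between taxa under the star
#' model: `d_i + d_j - (4/3) d_i d_j` for a 4-letter alphabet.
#'
#' @param config A [synthetic_config()] object.
#' @return An object of class `synthetic_clade` with fields `ancestor`,
#'   `taxa` (named list of [proteome()]s `T1`, `T2`, ...), `markers` (named
#'   character vector of 16S sequences), `true_distance_matrix`, `config`.
#' @export
simulate_clade <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- config$target_16s_distances
  nt <- length(d)
  with_seed(config$seed, {
    np <- config$n_proteins
    # geometric lengths, mean protein_length_mean, floor 50
    pgeo <- 1 / max(config$protein_length_mean - 49, 1)
    lens <- 50L + stats::rgeom(np, pgeo)
    anc_seq <- vapply(lens, rand_string, character(1), alphabet = AA_STANDARD)
    gene_len <- 3L * lens + 3L
    starts <- cumsum(c(1L, utils::head(gene_len + 100L, -1L)))
    ids <- sprintf("g%04d", seq_len(np))
    cats <- sample(paste0("cat", seq_len(config$n_categories)), np,
                   replace = TRUE)
    ancestor <- proteome("ancestor", ids, anc_seq, start = starts,
                         end = starts + gene_len - 1L, strand = "+",
                         category = cats)
    anc_marker <- rand_string(config$marker_length, DNA_BASES)
    taxa <- vector("list", nt)
    markers <- character(nt)
    names(taxa) <- names(markers) <- paste0("T", seq_len(nt))
    for (i in seq_len(nt)) {
      p_aa <- config$kappa * d[i]
      seqs <- vapply(anc_seq, function(s) {
        paste(mutate_chars(strsplit(s, "", fixed = TRUE)[[1]], p_aa,
                           AA_STANDARD), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      keep <- rep(TRUE, np)
      dr <- config$deleted_region
      if (!is.null(dr) && identical(dr$taxon, names(taxa)[i])) {
        keep[dr$from:dr$to] <- FALSE
      }
      taxa[[i]] <- proteome(names(taxa)[i], ids[keep], seqs[keep],
                            start = starts[keep],
                            end = (starts + gene_len - 1L)[keep],
                            strand = "+", category = cats[keep])
      markers[i] <- paste(
        mutate_chars(strsplit(anc_marker, "", fixed = TRUE)[[1]], d[i],
                     DNA_BASES), collapse = "")
    }
    truth <- outer(d, d, function(a, b) a + b - (4 / 3) * a * b)
    diag(truth) <- 0
    dimnames(truth) <- list(names(taxa), names(taxa))
    structure(list(ancestor = ancestor, taxa = taxa, markers = markers,
                   true_distance_matrix = truth, config = config),
              class = "synthetic_clade")
  })
}

#' @export
print.synthetic_clade <- function(x, ...) {
  cat(sprintf("Synthetic clade: %d taxa, %d ancestral proteins, kappa = %g\n",
              length(x$taxa), nrow(x$ancestor$records), x$config$kappa))
  cat("Target 16S distances:",
      paste(signif(x$config$target_16s_distances, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Detection model configuration
#'
#' Surrogate for LC-MS/MS sampling of a proteome: each distinct tryptic
#' peptide is detected independently with a fixed probability, and each
#' detected peptide receives a log10 E-value drawn from a normal
#' distribution. Defaults (mean -10, sd 1) place most simulated matches
#' below the -8.3 confidence cutoff, emulating a high-confidence PSM set.
#'
#' @param detect_probability Per-peptide detection probability in `[0, 1]`.
#' @param log_e_mean,log_e_sd Mean and standard deviation of the simulated
#'   log10 E-values (`log_e_sd > 0`).
#' @param seed Integer seed.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(detect_probability = 0.9, log_e_mean = -10,
                             log_e_sd = 1, seed = 1L) {
  if (detect_probability < 0 || detect_probability > 1) {
    stop_input("detect_probability must be in [0, 1]")
  }
  if (log_e_sd <= 0) stop_input("log_e_sd must be > 0")
  structure(list(detect_probability = detect_probability,
                 log_e_mean = log_e_mean, log_e_sd = log_e_sd,
                 seed = as.integer(seed)),
            class = "detection_config")
}

#' Simulate a PSM table for a proteome
#'
#' Digests the proteome, samples each distinct fully tryptic peptide
#' independently with the configured detection probability, and assigns each
#' detected peptide an E-value of `10^x` with `x ~ Normal(log_e_mean,
#' log_e_sd)`. Source organism and target genome are both the proteome's
#' organism (a self search).
#'
#' @param proteome A [proteome()] object.
#' @param index_params [digest_params()] used for the digest.
#' @param det A [detection_config()] object.
#' @return A [psm_table()].
#' @export
simulate_observation <- function(proteome, index_params = digest_params(),
                                 det = detection_config()) {
  idx <- build_peptide_index(proteome, index_params)
  peps <- names(idx$entries)
  with_seed(det$seed, {
    keep <- stats::runif(length(peps)) < det$detect_probability
    peps <- peps[keep]
    loge <- stats::rnorm(length(peps), det$log_e_mean, det$log_e_sd)
    psm_table(peptide = peps,
              protein_ids = join_ids(idx$entries[keep]),
              e_value = 10^loge,
              source_organism = proteome$organism_id,
              target_genome = proteome$organism_id)
  })
}

#' Write a synthetic clade to disk
#'
#' Emits one protein FASTA per taxon (headers `>locus|taxon`), a 16S marker
#' FASTA, a per-gene coordinates TSV, and a truth TSV of target distances.
#'
#' @param clade A `synthetic_clade`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(clade$taxa)) {
    write_proteome(clade$taxa[[tx]], file.path(dir, paste0(tx, ".faa")))
  }
  dna <- Biostrings::DNAStringSet(clade$markers)
  names(dna) <- names(clade$markers)
  Biostrings::writeXStringSet(dna, file.path(dir, "markers_16s.fasta"))
  rec <- clade$ancestor$records
  utils::write.table(rec[, c("id", "start", "end", "strand", "category")],
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(taxon = names(clade$taxa),
                      target_distance = clade$config$target_16s_distances)
  utils::write.table(truth, file.path(dir, "truth_distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
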