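#' Digestion parameters
#'
#' Settings for in-silico tryptic digestion. Trypsin cleaves C-terminal to
#' lysine (K) and arginine (R); by convention cleavage is suppressed when the
#' next residue is proline. A peptide is *fully tryptic* when both of its
#' termini are cleavage sites or protein termini; internal K/R sites left
#' uncleaved are *missed cleavages*.
#'
#' @param min_length Minimum peptide length in residues (default 6, the usual
#'   floor for confident spectrum matching).
#' @param max_missed_cleavages Maximum number of internal missed cleavage
#'   sites per peptide (default 2, the common database-search default).
#' @param proline_block Suppress cleavage at K/R followed by P (default
#'   `TRUE`, the dominant trypsin convention).
#' @param collapse_IL Treat isoleucine and leucine as equivalent when keying
#'   the peptide index (they are isobaric and indistinguishable on an ion
#'   trap). Default `FALSE`: exact-database semantics.
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(min_length = 6L, max_missed_cleavages = 2L,
                          proline_block = TRUE, collapse_IL = FALSE) {
  if (min_length < 1) stop_input("min_length must be >= 1")
  if (max_missed_cleavages < 0) stop_input("max_missed_cleavages must be >= 0")
  structure(list(min_length = as.integer(min_length),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 proline_block = isTRUE(proline_block),
                 collapse_IL = isTRUE(collapse_IL)),
            class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat(sprintf(
    "Tryptic digestion: length >= %d, <= %d missed cleavages, KP block %s, I/L %s\n",
    x$min_length, x$max_missed_cleavages,
    if (x$proline_block) "on" else "off",
    if (x$collapse_IL) "collapsed" else "distinct"))
  invisible(x)
}

same_digest_params <- function(a, b) {
  identical(unclass(a), unclass(b))
}

#' Construct a proteome
#'
#' A proteome is an organism identifier plus a table of protein records.
#' Genomic coordinates, strand and functional category are optional and only
#' needed for coverage-gap detection and category summaries.
#'
#' @param organism_id Taxon identifier.
#' @param id Character vector of locus tags (unique).
#' @param sequence Amino-acid sequences (20-letter alphabet; X tolerated).
#' @param start,end Optional genomic coordinates in bases (`end >= start`).
#' @param strand Optional strand, `"+"` or `"-"`.
#' @param category Optional functional-category labels.
#' @return An object of class `proteome` wrapping a record data frame.
#' @export
proteome <- function(organism_id, id, sequence, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     category = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) stop_input("id and sequence lengths differ")
  if (anyDuplicated(id)) stop_input("duplicate protein ids in proteome")
  if (any(!nzchar(sequence))) stop_input("empty protein sequence")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU]", sequence)
  if (any(bad)) stop_input("invalid residues in protein(s): ",
                           paste(utils::head(id[bad], 3), collapse = ", "))
  records <- data.frame(id = id, sequence = sequence,
                        start = as.integer(start), end = as.integer(end),
                        strand = as.character(strand),
                        category = as.character(category),
                        stringsAsFactors = FALSE)
  ok <- !is.na(records$start) & !is.na(records$end)
  if (any(ok & records$end < records$start)) stop_input("end < start for some records")
  structure(list(organism_id = as.character(organism_id), records = records),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("Proteome of %s: %d proteins, %d residues total\n",
              x$organism_id, nrow(x$records), sum(nchar(x$records$sequence))))
  invisible(x)
}

# cleavage boundaries (0-based positions after which the chain is cut),
# including 0 and nchar(seq)
tryptic_boundaries <- function(sequence, proline_block = TRUE) {
  n <- nchar(sequence)
  pat <- if (proline_block) "[KR](?!P)" else "[KR]"
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  sites <- if (m[1] == -1L) integer(0) else as.integer(m)
  unique(c(0L, sites[sites < n], n))
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates all fully tryptic peptides of a sequence: both termini are
#' tryptic cleavage points (after K/R, optionally blocked before P) or the
#' protein's ends, with at most `max_missed_cleavages` internal sites and
#' length at least `min_length`. Peptides are listed in rounds of increasing
#' missed-cleavage count, left to right; duplicates are retained.
#'
#' @param sequence Amino-acid string.
#' @param params A [digest_params()] object.
#' @return Character vector of peptide sequences.
#' @examples
#' digest_protein("MKTAYIAKQR", digest_params(min_length = 6,
#'                                            max_missed_cleavages = 1))
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) stop_input("empty sequence")
  b <- tryptic_boundaries(sequence, params$proline_block)
  nb <- length(b)
  out <- character(0)
  for (m in 0:params$max_missed_cleavages) {
    i <- seq_len(nb - 1L - m)
    if (length(i) == 0L) break
    starts <- b[i] + 1L
    ends <- b[i + 1L + m]
    keep <- (ends - starts + 1L) >= params$min_length
    if (any(keep)) out <- c(out, substring(sequence, starts[keep], ends[keep]))
  }
  out
}

collapse_il <- function(peptides) chartr("I", "L", peptides)

#' Build a peptide-to-protein index for a proteome
#'
#' Digests every protein and maps each distinct peptide to the set of
#' proteins that yield it. The index is the desk-scale surrogate for the
#' searchable tryptic peptide space of a genome. When
#' `params$collapse_IL` is set, index keys use L for both I and L.
#'
#' @param proteome A [proteome()] object.
#' @param params A [digest_params()] object.
#' @return An object of class `peptide_index` with fields `organism_id`,
#'   `params` and `entries` (named list: peptide -> character vector of
#'   protein ids).
#' @export
build_peptide_index <- function(proteome, params = digest_params()) {
  stopifnot(inherits(proteome, "proteome"))
  if (nrow(proteome$records) == 0L) stop_input("empty proteome")
  if (anyDuplicated(proteome$records$id)) stop_input("duplicate protein ids")
  peps <- lapply(proteome$records$sequence, digest_protein, params = params)
  prot <- rep(proteome$records$id, lengths(peps))
  pep <- unlist(peps, use.names = FALSE)
  if (params$collapse_IL) pep <- collapse_il(pep)
  if (length(pep) == 0L) {
    entries <- structure(list(), names = character(0))
  } else {
    entries <- lapply(split(prot, pep), unique)
  }
  structure(list(organism_id = proteome$organism_id, params = params,
                 entries = entries),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("Peptide index of %s: %d distinct peptides\n",
              x$organism_id, length(x$entries)))
  print(x$params)
  invisible(x)
}

# peptides containing nonstandard residues are indexed but never matched
# across organisms
has_nonstandard <- function(peptides) grepl("[BZXU]", peptides)

#' Read a protein FASTA as a proteome
#'
#' Header convention: the record id is the first `|`- or space-delimited
#' token. An optional sidecar TSV (`id`, `start`, `end`, `strand`,
#' `category`, with header) supplies genomic coordinates and functional
#' categories.
#'
#' @param path Path to a protein FASTA file.
#' @param organism_id Taxon id; defaults to the file name without extension.
#' @param sidecar Optional path to the coordinates TSV.
#' @return A [proteome()] object.
#' @export
read_proteome <- function(path, organism_id = NULL, sidecar = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "[ |]"), `[`, character(1), 1L)
  org <- organism_id %||% sub("\\.[^.]*$", "", basename(path))
  p <- proteome(org, ids, as.character(aa))
  if (!is.null(sidecar)) {
    tab <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    m <- match(p$records$id, tab$id)
    for (col in intersect(c("start", "end", "strand", "category"), names(tab))) {
      p$records[[col]] <- tab[[col]][m]
    }
  }
  p
}

#' Write a proteome as FASTA
#'
#' Headers follow the `>locus|taxon` convention.
#'
#' @param proteome A [proteome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$records$sequence)
  names(aa) <- paste0(proteome$records$id, "|", proteome$organism_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write a peptide index as TSV
#'
#' Two columns: `peptide` and comma-joined `protein_ids`.
#'
#' @param index A `peptide_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_index <- function(index, path) {
  df <- data.frame(peptide = names(index$entries),
                   protein_ids = join_ids(index$entries),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
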