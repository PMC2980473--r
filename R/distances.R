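#' Alignment parameters for 16S distance calculation
#'
#' Scoring for pairwise global (Needleman-Wunsch) alignment with affine
#' gaps. A gap of length L costs `gap_open + gap_extend * L`. Defaults
#' (match 2, mismatch -1, open 10, extend 0.5) are conventional DNA
#' alignment weights.
#'
#' @param match,mismatch Substitution scores (dimensionless).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1, gap_open = 10,
                             gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop_input("gap penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_params")
}

check_dna <- function(x, what) {
  if (length(x) != 1L || !nzchar(x)) stop_input("empty sequence: ", what)
  x <- toupper(x)
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  if (!all(chars %in% DNA_IUPAC)) {
    stop_input("non-IUPAC symbol in ", what, ": ",
               paste(setdiff(chars, DNA_IUPAC), collapse = ""))
  }
  x
}

align_pair <- function(a, b, params) {
  syms <- union(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  # identity matrix: ambiguity codes match only themselves
  mat <- matrix(params$mismatch, length(syms), length(syms),
                dimnames = list(syms, syms))
  diag(mat) <- params$match
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = params$gap_open,
                                gapExtension = params$gap_extend)
}

#' Pairwise evolutionary distance from two 16S sequences
#'
#' Globally aligns the two sequences with affine gap penalties and returns
#' the uncorrected p-distance: the fraction of mismatched columns among
#' columns where neither sequence has a gap. IUPAC ambiguity codes are
#' tolerated and count as mismatches unless identical. With
#' `correction = "kimura"` the Kimura two-parameter correction is applied
#' using the transition/transversion split observed in the alignment.
#'
#' @param seq_a,seq_b Nonempty DNA strings.
#' @param params An [alignment_params()] object.
#' @param correction `"none"` (default, observed divergence) or `"kimura"`.
#' @return Distance in `[0, 1]` (Kimura-corrected values may exceed 1 at
#'   extreme divergence).
#' @examples
#' pairwise_distance_16s("ACGTACGT", "ACGAACGT")  # 1 mismatch / 8 -> 0.125
#' @export
pairwise_distance_16s <- function(seq_a, seq_b, params = alignment_params(),
                                  correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  a <- check_dna(seq_a, "seq_a")
  b <- check_dna(seq_b, "seq_b")
  pa <- align_pair(a, b, params)
  ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gapless <- ca != "-" & cb != "-"
  if (!any(gapless)) stop_input("alignment has no gap-free columns")
  diff <- gapless & ca != cb
  p <- sum(diff) / sum(gapless)
  if (correction == "none") return(p)
  # Kimura 2-parameter from observed transition (P) / transversion (Q) split
  pur <- c("A", "G")
  transition <- diff & ((ca %in% pur) == (cb %in% pur))
  P <- sum(transition) / sum(gapless)
  Q <- p - P
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) stop_input("divergence too high for Kimura correction")
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Pairwise 16S distance matrix for a set of taxa
#'
#' Computes [pairwise_distance_16s()] for every unordered pair of markers.
#'
#' @param markers Named character vector or list, taxon id -> 16S sequence;
#'   at least two taxa with unique ids.
#' @param params An [alignment_params()] object.
#' @param correction Passed to [pairwise_distance_16s()].
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames.
#' @export
distance_matrix <- function(markers, params = alignment_params(),
                            correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  markers <- unlist(markers)
  if (length(markers) < 2L) stop_input("need at least two taxa")
  if (is.null(names(markers)) || anyDuplicated(names(markers))) {
    stop_input("markers must have unique taxon ids as names")
  }
  n <- length(markers)
  m <- matrix(0, n, n, dimnames = list(names(markers), names(markers)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwise_distance_16s(markers[[i]], markers[[j]], params,
                                 correction)
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Read 16S marker sequences from FASTA
#'
#' Record ids (first header token) become taxon ids.
#'
#' @param path FASTA path.
#' @return Named character vector of DNA sequences.
#' @export
read_markers <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(dna), "[ |]"), `[`, character(1), 1L)
  stats::setNames(as.character(dna), ids)
}

#' Write a distance matrix as TSV or PHYLIP square format
#'
#' @param m Square distance matrix with taxon dimnames.
#' @param path Output path.
#' @param format `"tsv"` (taxon header row and column) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("taxon", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 6,
                                                trim = TRUE)),
                       collapse = "\t"), con)
    }
  } else {
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                         sprintf("%.6f", m[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}
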