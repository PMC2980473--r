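# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

# O(L^2) enumeration of all fully tryptic substrings of a protein
oracle_digest <- function(seq, min_length = 6, max_missed = 2,
                          proline_block = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  is_site <- function(pos) {
    # cleavage after position pos
    if (pos < 1 || pos >= n) return(FALSE)
    ch[pos] %in% c("K", "R") && !(proline_block && ch[pos + 1] == "P")
  }
  out <- character(0)
  for (i in seq_len(n)) {
    start_ok <- i == 1 || is_site(i - 1)
    if (!start_ok) next
    for (j in i:n) {
      end_ok <- j == n || is_site(j)
      if (!end_ok) next
      if (j - i + 1 < min_length) next
      internal <- if (j > i) sum(vapply((i:(j - 1)), is_site, logical(1)))
                  else 0
      if (internal > max_missed) next
      out <- c(out, paste(ch[i:j], collapse = ""))
    }
  }
  out
}

# brute-force peptide -> protein map over a proteome
oracle_index <- function(prot, min_length = 6, max_missed = 2,
                         proline_block = TRUE, collapse_IL = FALSE) {
  pairs <- list()
  for (r in seq_len(nrow(prot$records))) {
    peps <- unique(oracle_digest(prot$records$sequence[r], min_length,
                                 max_missed, proline_block))
    if (collapse_IL) peps <- unique(chartr("I", "L", peps))
    for (p in peps) pairs[[p]] <- c(pairs[[p]], prot$records$id[r])
  }
  lapply(pairs, unique)
}

# percentile by linear interpolation between closest ranks, written
# independently of stats::quantile
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive global affine-gap alignment score by enumerating every
# monotone alignment path (feasible for sequences of length <= 8)
oracle_align_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = 10, gap_extend = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, "M", sc + s)
    }
    if (i <= length(a)) {
      pen <- gap_extend + if (prev == "D") 0 else gap_open
      rec(i + 1, j, "D", sc - pen)
    }
    if (j <= length(b)) {
      pen <- gap_extend + if (prev == "I") 0 else gap_open
      rec(i, j + 1, "I", sc - pen)
    }
  }
  rec(1, 1, "start", 0)
  best
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

random_proteome <- function(n, org = "org", len_range = c(30, 120)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  proteome(org, sprintf("p%03d", seq_len(n)),
           vapply(lens, random_protein, character(1)))
}

random_psm_table <- function(n, source = "S", target = "S") {
  lens <- sample(4:15, n, replace = TRUE)
  psm_table(peptide = vapply(lens, function(l)
              paste(sample(AA20, l, replace = TRUE), collapse = ""),
              character(1)),
            protein_ids = sprintf("p%03d", sample(50, n, replace = TRUE)),
            e_value = 10^runif(n, -14, -1),
            source_organism = source, target_genome = target)
}

hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

with_seed_helper <- function(seed, code) {
  set.seed(seed)
  force(code)
}
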