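# Internal helpers shared across modules.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_BASES <- c("A", "C", "G", "T")
# IUPAC codes tolerated in 16S input; treated as mismatches unless identical
DNA_IUPAC <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state,
# so every stochastic operation is a pure function of its arguments.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("transprot_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split comma-joined protein id fields into a list of character vectors
split_ids <- function(x) strsplit(as.character(x), ",", fixed = TRUE)

join_ids <- function(x) vapply(x, paste, character(1), collapse = ",")
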