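# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases over A, C, G, T. Used for single-copy background,
#' decoy reference entries and organelle stand-ins.
#'
#' @param n Sequence length in bases.
#' @param seed Optional integer seed; when given the result is deterministic
#'   and the caller's RNG state is left untouched.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, seed = NULL) {
  stopifnot(is.numeric(n), n >= 0)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

#' Reverse complement of plain character sequences
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at the given per-base rate (substitutions only, no indels,
# so that every mutated copy keeps its template length).
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  if (!length(hits)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  ch[hits] <- vapply(ch[hits],
                     function(b) sample(bases[bases != b], 1L),
                     character(1))
  paste(ch, collapse = "")
}

# Canonical (strand-symmetric) k-mers of one sequence; k-mers containing
# non-ACGT characters are dropped.
canonical_kmers <- function(seq, k = 13L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), k:n)
  keep <- !grepl("[^ACGT]", km)
  km <- unique(km[keep])
  if (!length(km)) return(character(0))
  unique(pmin(km, revcomp_chr(km)))
}

# C-locale, deterministic character sort (radix is locale-independent).
sort_c <- function(x) sort(x, method = "radix")

# Minimum aligned span implied by a fractional overlap threshold; the tiny
# epsilon keeps exact boundary cases (e.g. 55 columns at 55% of 100) from
# failing to floating-point representation.
span_needed <- function(frac, len) frac * len - 1e-9

# Pair stem of a read id: drop the /1 or /2 mate suffix.
pair_stem <- function(ids) sub("/[12]$", "", ids)

# Phred string -> integer vector (Phred+33 encoding).
phred_to_int <- function(q) utf8ToInt(q) - 33L

`%||%` <- function(a, b) if (is.null(a)) b else a
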