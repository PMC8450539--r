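#' Extract LTR-3'/5'-UTR junction tags
#'
#' From an LTR element with an annotated boundary between the end of the
#' 5' LTR and the start of the internal region, extracts the 30-nt tag
#' ending the LTR (`ltr3_tag`), the 30-nt tag opening the internal region
#' (`utr5_tag`), and their 60-nt concatenation (`combined_tag`). The
#' combined tag spans the junction found in full-length elements but absent
#' from solo-LTRs, which is what makes the tag cascade informative.
#'
#' @param x A [repeat_template()] with LTR structure, or a list with
#'   elements `sequence` and `boundary` (last base of the LTR, 1-based).
#' @return List with class `junction_tags`: `family`, `ltr3_tag`,
#'   `utr5_tag`, `combined_tag`.
#' @export
extract_tags <- function(x) {
  if (inherits(x, "repeat_template")) {
    if (!is_ltr_template(x)) stop("template has no LTR/internal structure")
    ltr <- ltr_segment(x)
    internal <- internal_segment(x)
    family <- x$name
  } else {
    stopifnot(is.list(x), !is.null(x$sequence), !is.null(x$boundary))
    ltr <- substr(x$sequence, 1L, x$boundary)
    internal <- substr(x$sequence, x$boundary + 1L, nchar(x$sequence))
    family <- x$family %||% "element"
  }
  if (nchar(ltr) < 30L) stop("LTR segment shorter than the 30 nt tag")
  if (nchar(internal) < 30L) stop("internal segment shorter than the 30 nt tag")
  ltr3 <- substr(ltr, nchar(ltr) - 29L, nchar(ltr))
  utr5 <- substr(internal, 1L, 30L)
  structure(list(family = family, ltr3_tag = ltr3, utr5_tag = utr5,
                 combined_tag = paste0(ltr3, utr5)),
            class = "junction_tags")
}

# Reads (DNAStringSet) fully containing `pattern` on either strand with at
# most `max_mismatch` substitutions.
tag_matches <- function(dna, pattern, max_mismatch) {
  fw <- Biostrings::vcountPattern(pattern, dna, max.mismatch = max_mismatch,
                                  fixed = TRUE) > 0L
  rv <- Biostrings::vcountPattern(revcomp_chr(pattern), dna,
                                  max.mismatch = max_mismatch,
                                  fixed = TRUE) > 0L
  fw | rv
}

#' Count solo-LTR evidence reads and compute Rsf
#'
#' Tag-matching cascade over quality-filtered reads: reads fully containing
#' the 30-nt LTR-3' tag (either strand, at most `max_mismatch`
#' substitutions) form the candidate set `Lx`; candidates that continue
#' across the junction — i.e. also contain the combined-tag prefix made of
#' the LTR-3' tag plus the first `min_junction_overhang` bases of the
#' 5'-UTR tag — form `LU`. The solo-LTR ratio is
#' `Rsf = (Lx - LU) / LU`; genomes dominated by solo-LTRs give large Rsf.
#' With `LU = 0` the ratio is flagged undefined (`NA`) rather than
#' dividing by zero.
#'
#' @param reads A [read_set()].
#' @param tags A [extract_tags()] result.
#' @param max_mismatch Substitutions tolerated per tag match (default 2,
#'   i.e. about 93% identity over the 30-nt tag).
#' @param min_junction_overhang Bases a junction read must continue past
#'   the LTR end into the 5'-UTR (default 10).
#' @param species Optional species label carried into the result.
#' @return List with class `rsf_result`: `family`, `species`, `lx`, `lu`,
#'   `rsf`, `undefined`.
#' @export
rsf_count <- function(reads, tags, max_mismatch = 2L,
                      min_junction_overhang = 10L, species = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(tags, "junction_tags"))
  if (min_junction_overhang < 1L || min_junction_overhang > 30L) {
    stop("min_junction_overhang must be in 1..30")
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  lx_hit <- tag_matches(dna, tags$ltr3_tag, max_mismatch)
  junction <- substr(tags$combined_tag, 1L, 30L + min_junction_overhang)
  lu_hit <- lx_hit & tag_matches(dna, junction, max_mismatch)
  lx <- sum(lx_hit)
  lu <- sum(lu_hit)
  structure(list(family = tags$family,
                 species = species %||% reads$species_tag,
                 lx = lx, lu = lu,
                 rsf = if (lu > 0L) (lx - lu) / lu else NA_real_,
                 undefined = lu == 0L),
            class = "rsf_result")
}

#' @export
print.rsf_result <- function(x, ...) {
  cat(sprintf("<rsf_result> %s / %s: Lx = %d, LU = %d, Rsf = %s\n",
              x$family, x$species, x$lx, x$lu,
              if (x$undefined) "undefined" else format(round(x$rsf, 3))))
  invisible(x)
}

#' Analytic Rsf expectation for a truth genome
#'
#' Expected Rsf from exact base counting: with `full` full-length copies
#' (two LTR ends each, one of them at the junction) and `solo` solo-LTR
#' copies (one LTR end each), a read of length `L` fully contains a 30-nt
#' LTR-3' tag at `L - 30 + 1` start positions per tag occurrence, and spans
#' the junction by at least `overhang` bases at `L - 30 - overhang + 1`
#' positions per full-length copy. Sampling uniformly,
#' `E[Lx] / E[LU] = (2*full + solo) * (L - 29) / (full * (L - 29 - overhang))`
#' and the expected Rsf follows from `(Lx - LU) / LU`.
#'
#' @param full Full-length copy count.
#' @param solo Solo-LTR copy count.
#' @param read_length Read length in bases.
#' @param tag_length Tag length (30).
#' @param overhang Junction overhang used by [rsf_count()].
#' @return Expected Rsf (numeric; `Inf` when `full` is 0).
#' @export
rsf_expected <- function(full, solo, read_length = 100L, tag_length = 30L,
                         overhang = 10L) {
  lx_positions <- (2 * full + solo) * (read_length - tag_length + 1L)
  lu_positions <- full * (read_length - tag_length - overhang + 1L)
  if (lu_positions == 0) return(Inf)
  (lx_positions - lu_positions) / lu_positions
}
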