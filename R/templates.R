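#' Define a repeat family template
#'
#' A template is the named sequence model of one repeat family: its lineage
#' label and its ordered structural segments. LTR retrotransposon templates
#' have the segment order LTR, internal, LTR with both LTR strings identical
#' before per-copy mutation; tandem satellites have a single `monomer`
#' segment; other repeats (DNA transposons, LINEs, rDNA) use a single `body`
#' segment.
#'
#' @param name Family identifier (e.g. `"Angela"`, `"HeloSAT"`).
#' @param lineage Lineage label, e.g. `"Ty1/copia-Angela"`, `"Ty3/gypsy-Retand"`,
#'   `"EnSpm/CACTA"`, `"satellite"`, `"rDNA"`.
#' @param ltr,internal LTR and internal sequences (LTR elements only). The
#'   5' and 3' LTR copies are taken identical before mutation.
#' @param monomer Monomer sequence (satellites only).
#' @param body Body sequence (all other repeat types).
#' @return An object of class `repeat_template`.
#' @examples
#' tpl <- repeat_template("toy", "Ty1/copia-Angela",
#'                        ltr = random_dna(60, seed = 1),
#'                        internal = random_dna(160, seed = 2))
#' template_length(tpl)
#' @export
repeat_template <- function(name, lineage, ltr = NULL, internal = NULL,
                            monomer = NULL, body = NULL) {
  stopifnot(is.character(name), nzchar(name), is.character(lineage))
  has <- c(ltr = !is.null(ltr), monomer = !is.null(monomer),
           body = !is.null(body))
  if (has[["ltr"]]) {
    if (is.null(internal)) stop("LTR templates need an `internal` segment")
    segments <- list(list(role = "LTR", seq = ltr),
                     list(role = "internal", seq = internal),
                     list(role = "LTR", seq = ltr))
    kind <- "LTR"
  } else if (has[["monomer"]]) {
    segments <- list(list(role = "monomer", seq = monomer))
    kind <- "satellite"
  } else if (has[["body"]]) {
    segments <- list(list(role = "body", seq = body))
    kind <- "other"
  } else {
    stop("provide `ltr` + `internal`, `monomer`, or `body`")
  }
  for (s in segments) {
    if (!nzchar(s$seq) || grepl("[^ACGT]", s$seq)) {
      stop("template segments must be non-empty strings over {A,C,G,T}")
    }
  }
  structure(list(name = name, lineage = lineage, kind = kind,
                 segments = segments,
                 monomer_length = if (kind == "satellite") nchar(monomer)),
            class = "repeat_template")
}

#' @export
print.repeat_template <- function(x, ...) {
  segs <- vapply(x$segments, function(s) sprintf("%s(%d)", s$role,
                                                 nchar(s$seq)), "")
  cat(sprintf("<repeat_template> %s [%s] %s\n", x$name, x$lineage,
              paste(segs, collapse = "+")))
  invisible(x)
}

#' Total length of one template copy
#'
#' For satellites this is the monomer length; a placed copy is an array of
#' `monomers_per_copy` monomers (see [genome_spec()]).
#' @param template A [repeat_template()].
#' @return Integer number of bases.
#' @export
template_length <- function(template) {
  stopifnot(inherits(template, "repeat_template"))
  sum(vapply(template$segments, function(s) nchar(s$seq), integer(1)))
}

is_ltr_template <- function(template) template$kind == "LTR"

ltr_segment <- function(template) {
  stopifnot(is_ltr_template(template))
  template$segments[[1]]$seq
}

internal_segment <- function(template) {
  stopifnot(is_ltr_template(template))
  template$segments[[2]]$seq
}

#' Built-in set of miniature repeat templates
#'
#' A deterministic set of desk-scale repeat family templates covering the
#' main lineages profiled in the package: Ty1/copia (Angela, Ale), Ty3/gypsy
#' (Retand, Tekay), a CACTA DNA transposon, a LINE, rDNA, and a 26-bp tandem
#' satellite. Element lengths are scaled down (hundreds of bases rather than
#' kilobases) to match the miniature genomes the simulator builds, so that
#' low-coverage read sampling still tiles each family.
#'
#' @param seed Integer seed controlling the template sequences.
#' @return Named list of [repeat_template()] objects.
#' @export
default_templates <- function(seed = 1201L) {
  with_seed(seed, {
    rd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
    list(
      angela  = repeat_template("Angela", "Ty1/copia-Angela",
                                ltr = rd(60), internal = rd(160)),
      ale     = repeat_template("Ale", "Ty1/copia-Ale",
                                ltr = rd(50), internal = rd(120)),
      retand  = repeat_template("Retand", "Ty3/gypsy-Retand",
                                ltr = rd(60), internal = rd(140)),
      tekay   = repeat_template("Tekay", "Ty3/gypsy-Tekay",
                                ltr = rd(50), internal = rd(130)),
      cacta   = repeat_template("CACTA", "EnSpm/CACTA", body = rd(200)),
      line    = repeat_template("LINE", "LINE", body = rd(180)),
      rdna    = repeat_template("rDNA", "rDNA", body = rd(300)),
      helosat = repeat_template("HeloSAT", "satellite", monomer = rd(26))
    )
  })
}
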