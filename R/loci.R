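#' Locus schema
#'
#' A biallelic locus is described by its name, the ordered triple of genotype
#' labels (major homozygote, heterozygote, minor homozygote) and the pair of
#' allele symbols (major, minor) implied by that ordering.
#'
#' @param name Locus identifier.
#' @param labels Character vector of exactly 3 pairwise-distinct genotype
#'   labels in (major-homozygote, heterozygote, minor-homozygote) order.
#' @param alleles Character vector of 2 allele symbols, (major, minor).
#' @return An object of class `locus_schema`.
#' @export
locus_schema <- function(name, labels, alleles) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(labels) != 3L || anyDuplicated(labels))
    stop("locus '", name, "': need exactly 3 pairwise-distinct genotype labels")
  stopifnot(length(alleles) == 2L)
  structure(list(name = name, labels = as.character(labels),
                 alleles = as.character(alleles)),
            class = "locus_schema")
}

#' @export
print.locus_schema <- function(x, ...) {
  cat("<locus_schema> ", x$name, ": ", paste(x$labels, collapse = " / "),
      "  (alleles ", x$alleles[1], "/", x$alleles[2], ")\n", sep = "")
  invisible(x)
}

#' The seven canonical folate-pathway loci
#'
#' Pre-registered schemas for the loci used throughout: MTHFR 677C>T,
#' MTHFR 1298A>C, MTRR 66A>G, MTR 2756A>G, RFC1 80G>A, the TYMS 28bp tandem
#' repeat (2R/3R alleles) and the TYMS 1494 6bp deletion (+ = insertion,
#' - = deletion). Genotype labels follow the usual epidemiological reporting
#' convention, ordered (major homozygote, heterozygote, minor homozygote).
#'
#' @return Named list of [locus_schema()] objects.
#' @export
canonical_loci <- function() {
  list(
    MTHFR677  = locus_schema("MTHFR677",  c("CC", "CT", "TT"),           c("C",  "T")),
    MTHFR1298 = locus_schema("MTHFR1298", c("AA", "AC", "CC"),           c("A",  "C")),
    MTRR66    = locus_schema("MTRR66",    c("AA", "AG", "GG"),           c("A",  "G")),
    MTR2756   = locus_schema("MTR2756",   c("AA", "AG", "GG"),           c("A",  "G")),
    RFC1_80   = locus_schema("RFC1_80",   c("GG", "GA", "AA"),           c("G",  "A")),
    TYMS_28bp = locus_schema("TYMS_28bp", c("2R/2R", "2R/3R", "3R/3R"),  c("2R", "3R")),
    TYMS_6bp  = locus_schema("TYMS_6bp",  c("+/+", "+/-", "-/-"),        c("+",  "-"))
  )
}

#' One-hot encode a genotype call
#'
#' Each genotype call expands into three binary indicators, one per genotype
#' class, with exactly one 1 at the position of the call in the schema's
#' (major-homozygote, heterozygote, minor-homozygote) ordering.
#'
#' @param call Genotype label.
#' @param schema A [locus_schema()].
#' @return Integer vector of length 3 with exactly one 1.
#' @export
#' @examples
#' loci <- canonical_loci()
#' encode_genotype("AA", loci$MTRR66)  # (1, 0, 0)
#' encode_genotype("GG", loci$MTRR66)  # (0, 0, 1)
encode_genotype <- function(call, schema) {
  idx <- match(call, schema$labels)
  if (is.na(idx))
    stop("locus '", schema$name, "': unknown genotype label '", call, "'")
  out <- integer(3L)
  out[idx] <- 1L
  out
}
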