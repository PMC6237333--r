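#' Genetic code tables for mitochondrial codon analysis
#'
#' Wraps an NCBI translation table (default: table 2, vertebrate
#' mitochondrial) into the form the codon-usage and selection machinery
#' uses: a codon to amino-acid map over DNA codons, the stop-codon set,
#' the initiation-codon set, and the synonymous families that define RSCU.
#' Under table 2, ATA codes Met, TGA codes Trp, and AGA/AGG are stops, so
#' there are 60 sense codons.
#'
#' @param table_id NCBI genetic-code table id (integer or string); 2 is the
#'   vertebrate mitochondrial code.
#' @return An object of class `genetic_code`: list with `table_id`, `map`
#'   (named character, codon -> single-letter amino acid, `*` for stop),
#'   `start_codons`, `stop_codons`, `sense_codons`, and `families`
#'   (amino acid -> character vector of synonymous codons).
#' @examples
#' code <- genetic_code(2)
#' code$map[["TGA"]]  # "W"
#' @export
genetic_code <- function(table_id = 2L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  starts <- unique(c("ATG", attr(map, "alt_init_codons")))
  if (as.integer(table_id) == 2L) starts <- unique(c(starts, "ATA"))
  fam <- split(sense, map[sense])
  structure(
    list(table_id = as.integer(table_id),
         map = map,
         start_codons = starts,
         stop_codons = stops,
         sense_codons = sense,
         families = fam),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code table %d: %d sense codons, stops: %s\n",
              x$table_id, length(x$sense_codons),
              paste(x$stop_codons, collapse = " ")))
  invisible(x)
}

is_stop_codon <- function(codon, code) codon %in% code$stop_codons

aa_of <- function(codon, code) unname(code$map[codon])
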