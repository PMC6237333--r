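split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Split a CDS into codons and classify its start/stop codons
#'
#' Codons are consecutive non-overlapping 3-mers. A trailing 1-2 nt
#' remainder is an incomplete termination codon (completed to TAA by
#' polyadenylation in mitochondrial transcripts); a final complete codon
#' that belongs to the genetic code's stop set is a complete stop. The
#' terminal stop (complete or incomplete) is not included in the returned
#' codon list, so `3 * length(codons) + nchar(stop) = nchar(cds)`.
#'
#' @param cds_seq In-frame CDS string, length >= 4.
#' @param code A [genetic_code()].
#' @return List with `codons` (character vector) and `classification`
#'   (list: `start_codon`, `start_canonical` (ATG), `stop_codon` (possibly
#'   NA), `stop_complete`).
#' @export
extract_codons <- function(cds_seq, code = genetic_code(2)) {
  cds_seq <- check_dna(cds_seq, what = "CDS")
  n <- nchar(cds_seq)
  if (n < 4L) stop("CDS too short (< 4 nt)")
  rem <- n %% 3L
  codons <- split_codons(cds_seq)
  stop_codon <- NA_character_
  stop_complete <- FALSE
  if (rem > 0L) {
    stop_codon <- substr(cds_seq, n - rem + 1L, n)
  } else if (is_stop_codon(codons[length(codons)], code)) {
    stop_codon <- codons[length(codons)]
    stop_complete <- TRUE
    codons <- codons[-length(codons)]
  }
  internal <- which(codons %in% code$stop_codons)
  if (length(internal)) {
    stop(sprintf("internal stop codon %s at codon %d (nt offset %d)",
                 codons[internal[1]], internal[1], 3L * internal[1] - 2L))
  }
  list(codons = codons,
       classification = list(
         start_codon = codons[1L],
         start_canonical = identical(codons[1L], "ATG"),
         stop_codon = stop_codon,
         stop_complete = stop_complete))
}

#' Classify the start codon of a CDS
#'
#' @param cds_seq CDS string (length >= 3).
#' @param code A [genetic_code()].
#' @return List with `codon`, `canonical` (TRUE iff ATG), and `initiator`
#'   (TRUE iff in the code's initiation set, e.g. GTG under the vertebrate
#'   mitochondrial code).
#' @export
classify_start <- function(cds_seq, code = genetic_code(2)) {
  cds_seq <- check_dna(cds_seq, what = "CDS")
  if (nchar(cds_seq) < 3L) stop("CDS shorter than one codon")
  codon <- substr(cds_seq, 1L, 3L)
  list(codon = codon,
       canonical = identical(codon, "ATG"),
       initiator = codon %in% code$start_codons)
}

#' Count codons across one or more CDS sequences
#'
#' @param cds_seqs Character vector (or list) of in-frame CDS strings.
#' @param code A [genetic_code()].
#' @param exclude_start Drop each gene's initiation codon (default TRUE,
#'   matching the convention of reporting 3,792 analysed codons with
#'   initiation and termination codons excluded).
#' @param exclude_stop Drop terminal stop codons (always dropped for
#'   incomplete stops; default TRUE).
#' @return Named integer vector over the 64 codons.
#' @export
codon_counts <- function(cds_seqs, code = genetic_code(2),
                         exclude_start = TRUE, exclude_stop = TRUE) {
  all_codons <- names(code$map)
  counts <- stats::setNames(integer(length(all_codons)), all_codons)
  for (s in cds_seqs) {
    ec <- extract_codons(s, code)
    cods <- ec$codons
    if (exclude_start && length(cods)) cods <- cods[-1L]
    if (!exclude_stop && ec$classification$stop_complete) {
      cods <- c(cods, ec$classification$stop_codon)
    }
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size k with family total n is
#' `count_c / (n / k)`: the observed count divided by the count expected
#' under uniform usage. Stop codons never form families (under the
#' vertebrate mitochondrial code AGA/AGG are stops and are excluded); a
#' family with zero total has undefined (NA) RSCU, and the mean RSCU over
#' each family with positive total is exactly 1.
#'
#' @param counts Named integer vector codon -> count (stop-codon entries
#'   are ignored with a warning).
#' @param code A [genetic_code()].
#' @return data.frame with columns `codon`, `aa`, `family_size`, `count`,
#'   `rscu`, ordered by amino acid then codon.
#' @export
rscu <- function(counts, code = genetic_code(2)) {
  stopifnot(!is.null(names(counts)))
  in_stop <- names(counts) %in% code$stop_codons & counts > 0
  if (any(in_stop)) {
    warning("stop-codon counts ignored in RSCU: ",
            paste(names(counts)[in_stop], collapse = ", "))
  }
  rows <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    k <- length(fam)
    n <- vapply(fam, function(cd) {
      v <- counts[cd]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
    total <- sum(n)
    val <- if (total > 0L) n / (total / k) else rep(NA_real_, k)
    data.frame(codon = fam, aa = aa, family_size = k, count = n,
               rscu = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  out
}

#' Translate an in-frame CDS
#'
#' Mitochondrial translation: the terminal stop codon (or incomplete 1-2 nt
#' remainder) is dropped; codons containing ambiguity (N) translate to `X`.
#' A stop codon appearing before the final codon is reported via the
#' `internal_stop` attribute.
#'
#' @param cds_seq CDS string.
#' @param code A [genetic_code()].
#' @return Amino-acid string; attribute `internal_stop` gives the offset of
#'   a premature stop (NA when absent).
#' @export
translate_cds <- function(cds_seq, code = genetic_code(2)) {
  cds_seq <- check_dna(cds_seq, what = "CDS")
  codons <- split_codons(cds_seq)
  terminal_stop <- NA_character_
  if (length(codons) && is_stop_codon(codons[length(codons)], code) &&
      nchar(cds_seq) %% 3L == 0L) {
    terminal_stop <- codons[length(codons)]
    codons <- codons[-length(codons)]
  }
  if (!length(codons)) stop("empty translation after stop trimming")
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd, fixed = TRUE)) return("X")
    unname(code$map[cd])
  }, character(1))
  internal <- which(aa == "*")
  attr_internal <- if (length(internal)) internal[1L] else NA_integer_
  structure(paste(aa, collapse = ""),
            internal_stop = attr_internal, terminal_stop = terminal_stop)
}
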