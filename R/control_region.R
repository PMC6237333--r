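#' Scan a region for short motifs on both strands
#'
#' Finds all occurrences (overlaps allowed) of each motif with at most
#' `max_mismatch` mismatches, on the given strand and on the reverse
#' complement. Positions are 1-based offsets of the match window within the
#' scanned region (heavy-strand coordinates for both strands).
#'
#' @param region_seq DNA string (e.g. the control region).
#' @param motifs Character vector of motifs, or a data.frame with columns
#'   `name`, `sequence`, `max_mismatch` (a motif profile).
#' @param max_mismatch Mismatch allowance applied when `motifs` is a plain
#'   vector (default 0).
#' @return data.frame with columns `motif`, `position`, `strand`,
#'   `mismatches`, sorted by position. Motifs longer than the region yield
#'   no hits.
#' @export
scan_motifs <- function(region_seq, motifs, max_mismatch = 0L) {
  region_seq <- check_dna(region_seq)
  if (is.data.frame(motifs)) {
    prof <- motifs
    stopifnot(all(c("name", "sequence", "max_mismatch") %in% names(prof)))
  } else {
    prof <- data.frame(name = motifs, sequence = motifs,
                       max_mismatch = max_mismatch, stringsAsFactors = FALSE)
  }
  subj <- Biostrings::DNAString(region_seq)
  hits <- list()
  for (i in seq_len(nrow(prof))) {
    pat <- toupper(prof$sequence[i])
    mm <- as.integer(prof$max_mismatch[i])
    if (nchar(pat) > nchar(region_seq)) next
    for (strand in c("H", "L")) {
      p <- if (strand == "H") pat else reverse_complement(pat)
      m <- Biostrings::matchPattern(p, subj, max.mismatch = mm)
      if (length(m) == 0L) next
      nmis <- vapply(seq_along(m), function(j) {
        sum(seq_chars(as.character(m[[j]])) != seq_chars(p))
      }, integer(1))
      hits[[length(hits) + 1L]] <- data.frame(
        motif = prof$name[i], position = Biostrings::start(m),
        strand = strand, mismatches = nmis, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$position, out$motif, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Default conserved-block motif profile for teleost control regions
#'
#' Consensus strings for the central conserved blocks (CSB-F/E/D) and the
#' conserved sequence block domain (CSB-1/2/3) compiled from the general
#' teleost D-loop literature, plus the short conserved motifs reported for
#' beloniform control regions. These consensi are externally sourced,
#' approximate, and user-replaceable; they are scanned with the mismatch
#' allowances given in the profile.
#'
#' @return data.frame with columns `name`, `sequence`, `max_mismatch`.
#' @export
default_csb_profile <- function() {
  data.frame(
    name = c("CSB-F", "CSB-E", "CSB-D", "CSB-1", "CSB-2", "CSB-3",
             "TAS-ATGTA", "TAS-TACAT", "repeat-GGTTTTT", "conserved-CTTAATG"),
    sequence = c("ATGTAATATTACAAGGACATA", "AGGGACAAGAATTGTGG",
                 "TATTCCTGGCATTTGGTTCCTA", "TTAATGCTTGTAGGACATAA",
                 "CAAACCCCCCTACCCCCC", "TGCCAAACCCCAAAAACAA",
                 "ATGTA", "TACAT", "GGTTTTT", "CTTAATG"),
    max_mismatch = c(5L, 4L, 5L, 5L, 4L, 4L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Find exact tandem repeats
#'
#' Maximal exact tandem arrays with at least `min_copies` copies of a unit
#' of period `min_period..max_period`. Copies may be fractional (partial
#' final copy). Arrays spanning identical intervals are reported once with
#' their smallest (primitive) period.
#'
#' @param region_seq DNA string.
#' @param min_period,max_period Unit-length bounds (defaults 1 and 10).
#' @param min_copies Minimum copy number (default 2).
#' @return data.frame with columns `start`, `period`, `copies`, `span`,
#'   `consensus`, sorted by start then period.
#' @export
find_tandem_repeats <- function(region_seq, min_period = 1L, max_period = 10L,
                                min_copies = 2) {
  region_seq <- check_dna(region_seq)
  n <- nchar(region_seq)
  if (min_period < 1L || max_period < min_period) stop("invalid period bounds")
  max_period <- min(max_period, n %/% 2L)
  chars <- seq_chars(region_seq)
  out <- list()
  for (p in seq_len(max_period)) {
    if (p < min_period) next
    i <- 1L
    # match[i] TRUE when chars[i] == chars[i+p]
    match <- c(chars[seq_len(n - p)] == chars[(p + 1L):n])
    while (i <= n - p) {
      if (match[i]) {
        j <- i
        while (j <= n - p && match[j]) j <- j + 1L
        span <- (j - i) + p          # array occupies i .. i+span-1
        copies <- span / p
        if (copies >= min_copies) {
          out[[length(out) + 1L]] <- data.frame(
            start = i, period = p, copies = copies, span = span,
            consensus = substr(region_seq, i, i + p - 1L),
            stringsAsFactors = FALSE)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), period = integer(), copies = numeric(),
                      span = integer(), consensus = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  # identical spans: keep the primitive (smallest) period
  key <- paste(df$start, df$start + df$span - 1L)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx[which.min(df$period[idx])]
  }))
  df <- df[sort(keep), , drop = FALSE]
  df <- df[order(df$start, df$period), ]
  rownames(df) <- NULL
  df
}

# Watson-Crick + G.U (DNA alphabet, U == T) pairing predicate
can_pair <- function(x, y) {
  paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Check a sequence for a hairpin (stem-loop) structure
#'
#' Finds the longest stem such that the first `stem` bases pair with the
#' last `stem` bases (Watson-Crick or G.U wobble, read antiparallel) with a
#' loop of at least 3 nt, as expected for the light-strand replication
#' origin.
#'
#' @param seq DNA string, length >= 8.
#' @return Object of class `hairpin_check`: list with `stem_length`,
#'   `loop_length`, `paired_fraction`, `gu_pairs`.
#' @export
hairpin_check <- function(seq) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  if (n < 8L) stop("sequence too short for a hairpin check (< 8 nt)")
  chars <- seq_chars(seq)
  smax <- (n - 3L) %/% 2L
  stem <- 0L
  while (stem < smax && can_pair(chars[stem + 1L], chars[n - stem])) {
    stem <- stem + 1L
  }
  gu <- if (stem > 0L) {
    sum(vapply(seq_len(stem), function(i) {
      paste0(chars[i], chars[n - i + 1L]) %in% c("GT", "TG")
    }, logical(1)))
  } else 0L
  structure(list(stem_length = stem,
                 loop_length = n - 2L * stem,
                 paired_fraction = 2 * stem / n,
                 gu_pairs = gu),
            class = "hairpin_check")
}

#' @export
print.hairpin_check <- function(x, ...) {
  cat(sprintf("Hairpin: stem %d bp, loop %d nt, paired fraction %.2f (%d G.U)\n",
              x$stem_length, x$loop_length, x$paired_fraction, x$gu_pairs))
  invisible(x)
}

#' Characterize a control region
#'
#' Runs the motif/CSB scan and the tandem-repeat scan over a control-region
#' sequence.
#'
#' @param region_seq Control-region DNA string.
#' @param motifs Motif profile (default [default_csb_profile()]).
#' @param min_period,max_period,min_copies Tandem-repeat parameters.
#' @return List with `composition`, `motif_hits`, `tandem_repeats`.
#' @export
control_region_report <- function(region_seq, motifs = default_csb_profile(),
                                  min_period = 1L, max_period = 10L,
                                  min_copies = 2) {
  list(composition = base_composition(region_seq, scope = "CR"),
       motif_hits = scan_motifs(region_seq, motifs),
       tandem_repeats = find_tandem_repeats(region_seq, min_period,
                                            max_period, min_copies))
}
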