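#' AT skew and GC skew
#'
#' Strand-asymmetry statistics: AT skew = (A - T)/(A + T), GC skew =
#' (G - C)/(G + C). A zero denominator yields NA (undefined), never a
#' division error.
#'
#' @param a,t,g,c Base counts.
#' @return Skew value in \[-1, 1\] or NA.
#' @export
at_skew <- function(a, t) if ((a + t) == 0) NA_real_ else (a - t) / (a + t)

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) if ((g + c) == 0) NA_real_ else (g - c) / (g + c)

#' Base composition and strand skews of a sequence
#'
#' Counts A/C/G/T (N is excluded from percentages and from both skew
#' numerators and denominators) and computes AT%, AT skew and GC skew.
#'
#' @param seq DNA string.
#' @param scope Label recorded in the report (e.g. "genome", a gene name,
#'   "PCG-concat", "codon-pos-1").
#' @return Object of class `composition_report`: list with `scope`,
#'   `counts` (named A/C/G/T/N), `pct`, `at_pct`, `at_skew`, `gc_skew`,
#'   `length`.
#' @export
base_composition <- function(seq, scope = "genome") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("base_composition requires a non-empty DNA string")
  }
  check_dna(seq)
  chars <- seq_chars(seq)
  counts <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(chars == b), integer(1))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  pct <- if (acgt > 0) 100 * counts[c("A", "C", "G", "T")] / acgt else
    stats::setNames(rep(NA_real_, 4), c("A", "C", "G", "T"))
  structure(list(
    scope = scope,
    counts = counts,
    pct = pct,
    at_pct = unname(pct["A"] + pct["T"]),
    at_skew = at_skew(counts[["A"]], counts[["T"]]),
    gc_skew = gc_skew(counts[["G"]], counts[["C"]]),
    length = nchar(seq)
  ), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("Composition [%s]: %d bp, AT%% %.2f, AT skew %s, GC skew %s\n",
              x$scope, x$length, x$at_pct,
              formatC(x$at_skew, digits = 4, format = "f"),
              formatC(x$gc_skew, digits = 4, format = "f")))
  invisible(x)
}

#' Composition of the concatenated protein-coding genes by codon position
#'
#' Extracts the 13 PCGs strand-aware in annotation order, concatenates
#' them, and tallies composition overall and at codon positions 1/2/3.
#' Positions cycle within each gene independently, so the 1-2 trailing
#' nucleotides of an incomplete terminal codon fall at positions 1 (and 2).
#'
#' @param record A `genome_record`.
#' @param table A `feature_table` containing all 13 PCGs.
#' @return List of `composition_report`s: `overall`, `pos1`, `pos2`, `pos3`.
#' @export
pcg_concat_composition <- function(record, table) {
  stopifnot(inherits(record, "genome_record"), inherits(table, "feature_table"))
  f <- table$features[table$features$class == "PCG", , drop = FALSE]
  missing <- setdiff(PCG_ORDER, f$name)
  if (length(missing)) {
    stop("missing PCGs: ", paste(missing, collapse = ", "))
  }
  seqs <- vapply(seq_len(nrow(f)),
                 function(i) extract_gene_sequence(record, f[i, ]), character(1))
  pos <- unlist(lapply(seqs, function(s) ((seq_len(nchar(s)) - 1L) %% 3L) + 1L))
  chars <- unlist(lapply(seqs, seq_chars))
  concat <- paste(chars, collapse = "")
  list(
    overall = base_composition(concat, scope = "PCG-concat"),
    pos1 = base_composition(paste(chars[pos == 1L], collapse = ""), scope = "codon-pos-1"),
    pos2 = base_composition(paste(chars[pos == 2L], collapse = ""), scope = "codon-pos-2"),
    pos3 = base_composition(paste(chars[pos == 3L], collapse = ""), scope = "codon-pos-3")
  )
}

#' Sliding-window GC skew
#'
#' @param seq DNA string.
#' @param window Window size in bp (> 0, <= sequence length).
#' @param step Step between window starts (default `window`).
#' @param circular Logical; when TRUE windows wrap around the origin and
#'   every position starts a window row according to `step`.
#' @return data.frame with columns `start` (1-based window start) and
#'   `gc_skew` (NA where undefined).
#' @export
sliding_gc_skew <- function(seq, window, step = window, circular = FALSE) {
  check_dna(seq)
  n <- nchar(seq)
  if (window <= 0L) stop("window must be > 0")
  if (window > n) stop("window exceeds sequence length")
  if (step <= 0L) stop("step must be > 0")
  starts <- if (circular) seq(1L, n, by = step) else seq(1L, n - window + 1L, by = step)
  chars <- seq_chars(seq)
  val <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    if (circular) idx <- ((idx - 1L) %% n) + 1L
    w <- chars[idx]
    gc_skew(sum(w == "G"), sum(w == "C"))
  }, numeric(1))
  data.frame(start = starts, gc_skew = val)
}
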