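#' Per-feature lengths
#'
#' @param table A `feature_table`.
#' @return Named integer vector, length = `end - start + 1` per feature.
#' @export
feature_lengths <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features
  stats::setNames(f$end - f$start + 1L, f$name)
}

#' Overlaps and intergenic spacers between consecutive features
#'
#' For features sorted by start, the gap between a feature and the next is
#' `next.start - prev.end - 1`: negative values are overlaps of `|gap|` bp,
#' positive values spacers of `gap` bp, zero means abutting. On a circular
#' table the closing pair (last feature back to the first) is included.
#' Whether the light-strand replication origin participates as a feature is
#' controlled by `ol_as_feature`; the published annotation treats it as a
#' feature, but the trnN-trnC spacer reading requires excluding it.
#'
#' @param table A `feature_table`.
#' @param include_classes Feature classes that participate (default all).
#' @param ol_as_feature Logical; when FALSE, OL features are dropped before
#'   gap computation (default TRUE).
#' @return List with data.frames `overlaps` and `spacers`, each with columns
#'   `upstream`, `downstream`, `bp`.
#' @export
adjacent_gaps <- function(table, include_classes = FEATURE_CLASSES,
                          ol_as_feature = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features
  f <- f[f$class %in% include_classes, , drop = FALSE]
  if (!ol_as_feature) f <- f[f$class != "OL", , drop = FALSE]
  empty <- data.frame(upstream = character(), downstream = character(),
                      bp = integer(), stringsAsFactors = FALSE)
  if (nrow(f) < 2L) return(list(overlaps = empty, spacers = empty))
  if (is.unsorted(f$start)) stop("internal error: feature table not sorted by start")
  up <- seq_len(nrow(f) - 1L)
  dn <- up + 1L
  gaps <- f$start[dn] - f$end[up] - 1L
  upstream <- f$name[up]; downstream <- f$name[dn]
  if (table$circular) {
    gaps <- c(gaps, f$start[1L] + table$genome_length - f$end[nrow(f)] - 1L)
    upstream <- c(upstream, f$name[nrow(f)])
    downstream <- c(downstream, f$name[1L])
  }
  ov <- gaps < 0L
  sp <- gaps > 0L
  list(
    overlaps = data.frame(upstream = upstream[ov], downstream = downstream[ov],
                          bp = -gaps[ov], stringsAsFactors = FALSE),
    spacers = data.frame(upstream = upstream[sp], downstream = downstream[sp],
                         bp = gaps[sp], stringsAsFactors = FALSE)
  )
}

#' Feature counts per class and strand
#'
#' @param table A `feature_table`.
#' @return data.frame with columns `class`, `strand`, `n` (all class/strand
#'   combinations, zero-filled).
#' @export
strand_distribution <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features
  grid <- expand.grid(class = FEATURE_CLASSES, strand = c("H", "L"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(cl, st) sum(f$class == cl & f$strand == st),
                   grid$class, grid$strand)
  grid[order(grid$class, grid$strand), ]
}

#' Genome-organization report
#'
#' Aggregates feature lengths, overlap/spacer accounting (with the
#' light-strand origin counted both as a feature and as spacer), strand
#' distribution and total protein-coding length from an annotation table
#' alone (no sequence needed).
#'
#' @param table A `feature_table`.
#' @return Object of class `architecture_report`: list with
#'   `genome_length`, `feature_lengths`, `gaps_ol_feature`,
#'   `gaps_ol_excluded`, `strand_counts`, `pcg_total_length`,
#'   `n_overlap_bp`, `n_spacer_bp`.
#' @export
architecture_report <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lens <- feature_lengths(table)
  g1 <- adjacent_gaps(table, ol_as_feature = TRUE)
  g2 <- adjacent_gaps(table, ol_as_feature = FALSE)
  pcg <- table$features$class == "PCG"
  structure(list(
    genome_length = table$genome_length,
    feature_lengths = lens,
    gaps_ol_feature = g1,
    gaps_ol_excluded = g2,
    strand_counts = strand_distribution(table),
    pcg_total_length = sum(lens[pcg]),
    n_overlap_bp = sum(g1$overlaps$bp),
    n_spacer_bp = sum(g1$spacers$bp)
  ), class = "architecture_report")
}

#' @export
print.architecture_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Architecture: %d bp genome; PCG total %d bp\n",
    "  overlaps: %d locations, %d bp; spacers: %d locations, %d bp (OL as feature)\n"),
    x$genome_length, x$pcg_total_length,
    nrow(x$gaps_ol_feature$overlaps), x$n_overlap_bp,
    nrow(x$gaps_ol_feature$spacers), x$n_spacer_bp))
  invisible(x)
}
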