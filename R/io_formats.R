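#' Create a genome record
#'
#' A genome record holds one (typically circular) mitochondrial sequence.
#' Coordinates elsewhere in the package are 1-based and inclusive on this
#' sequence (the heavy strand).
#'
#' @param id Accession-like identifier (non-empty string).
#' @param sequence DNA string over A,C,G,T,N.
#' @param circular Logical; circular molecule (default TRUE).
#' @return Object of class `genome_record` with fields `id`, `sequence`,
#'   `circular`, `length`.
#' @export
genome_record <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- check_dna(sequence, what = sprintf("sequence of '%s'", id))
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1")
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("Genome record %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "OL", "CR")

# canonical 13 PCG symbols in mitogenome gene order
PCG_ORDER <- c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
               "nad3", "nad4l", "nad4", "nad5", "nad6", "cytb")

AA1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

#' Normalize a mitochondrial feature name
#'
#' Maps common GenBank spellings (ND1, COI, CYTB, D-loop, tRNA-Phe, ...)
#' onto the package's canonical lowercase symbols (nad1, cox1, cytb, CR,
#' trnF, ...). Already-canonical tokens pass through unchanged.
#'
#' @param name Raw feature name (gene or product string).
#' @return Canonical token, or the input (trimmed) when no synonym matches.
#' @export
normalize_feature_name <- function(name) {
  raw <- trimws(name)
  if (grepl("^(nad[1-6]$|nad4l$|cox[1-3]$|atp[68]$|cytb$|trn[A-Z][12]?$|rrn[SL]$|OL$|CR$)", raw)) {
    return(raw)
  }
  x <- toupper(gsub("[[:space:]_]+", "", raw))
  syn <- c(ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4",
           ND4L = "nad4l", ND5 = "nad5", ND6 = "nad6",
           NAD4L = "nad4l",
           COI = "cox1", COII = "cox2", COIII = "cox3",
           CO1 = "cox1", CO2 = "cox2", CO3 = "cox3",
           COX1 = "cox1", COX2 = "cox2", COX3 = "cox3",
           ATP6 = "atp6", ATP8 = "atp8", ATPASE6 = "atp6", ATPASE8 = "atp8",
           CYTB = "cytb", COB = "cytb", CYB = "cytb",
           `D-LOOP` = "CR", DLOOP = "CR", CONTROLREGION = "CR",
           `12SRRNA` = "rrnS", `16SRRNA` = "rrnL",
           `12SRIBOSOMALRNA` = "rrnS", `16SRIBOSOMALRNA` = "rrnL",
           RRNS = "rrnS", RRNL = "rrnL",
           OL = "OL", REP_ORIGIN = "OL", REPORIGIN = "OL",
           `L-STRANDORIGIN` = "OL")
  if (!is.na(syn[x])) return(unname(syn[x]))
  m <- regmatches(raw, regexec("^tRNA-?([A-Za-z]{3})", raw))[[1L]]
  if (length(m) == 2L) {
    aa3 <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
    if (!is.na(AA1[aa3])) {
      num <- regmatches(raw, regexec("\\(?([LS])\\s*([12])\\)?", raw))[[1L]]
      suffix <- if (length(num) == 3L && num[2] == AA1[aa3]) num[3] else ""
      return(paste0("trn", AA1[aa3], suffix))
    }
  }
  raw
}

#' Build a validated feature table
#'
#' The in-memory annotation of a circular mitogenome: one row per feature
#' with name, class (PCG, tRNA, rRNA, OL, CR), strand (H heavy / L light),
#' 1-based inclusive start/end, and optional start/stop codon and anticodon
#' columns. Rows are sorted by start. Duplicate tRNA names are
#' disambiguated by anticodon when available, otherwise numbered in
#' coordinate order (e.g. trnL1/trnL2).
#'
#' @param features data.frame with columns `name`, `class`, `strand`,
#'   `start`, `end`, optionally `start_codon`, `stop_codon`, `anticodon`.
#' @param genome_length Total length in bp; defaults to the maximum feature
#'   end.
#' @param circular Logical (default TRUE).
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(features, genome_length = NULL, circular = TRUE) {
  stopifnot(is.data.frame(features))
  need <- c("name", "class", "strand", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (is.null(features[[col]])) {
      features[[col]] <- rep(NA_character_, nrow(features))
    }
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end)) {
    stop("non-numeric feature coordinates")
  }
  bad <- which(features$start > features$end)
  if (length(bad)) {
    stop(sprintf("feature '%s': start (%d) > end (%d); wrap-around features are not supported",
                 features$name[bad[1]], features$start[bad[1]], features$end[bad[1]]))
  }
  if (any(features$start < 1L)) stop("feature coordinates must be >= 1")
  if (!all(features$strand %in% c("H", "L"))) {
    stop("unknown strand symbol: ",
         paste(setdiff(unique(features$strand), c("H", "L")), collapse = ", "))
  }
  if (!all(features$class %in% FEATURE_CLASSES)) {
    stop("unknown feature class: ",
         paste(setdiff(unique(features$class), FEATURE_CLASSES), collapse = ", "))
  }
  sc <- features$stop_codon
  if (any(!is.na(sc) & !(nchar(sc) %in% 1:3))) stop("stop_codon length must be 1-3")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL

  # disambiguate duplicated tRNA names in coordinate order
  dup <- names(which(table(features$name) > 1L))
  for (nm in dup) {
    idx <- which(features$name == nm)
    if (all(features$class[idx] == "tRNA")) {
      features$name[idx] <- paste0(nm, seq_along(idx))
    } else {
      stop("duplicated non-tRNA feature name: ", nm)
    }
  }

  if (is.null(genome_length) && nrow(features) == 0L) {
    stop("an empty feature table needs an explicit genome_length")
  }
  gl <- as.integer(genome_length %||% max(features$end))
  if (any(features$end > gl)) {
    stop("feature coordinates exceed genome_length")
  }
  structure(list(genome_length = gl, circular = isTRUE(circular),
                 features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cls <- table(x$features$class)
  cat(sprintf("Feature table: %d features on %d bp (%s)\n  %s\n",
              nrow(x$features), x$genome_length,
              if (x$circular) "circular" else "linear",
              paste(names(cls), as.integer(cls), sep = "=", collapse = " ")))
  invisible(x)
}

#' Read an annotation feature table from TSV
#'
#' Expects tab-separated columns `feature  class  strand  start  end
#' start_codon  stop_codon` (the codon columns optional), `#` comment
#' lines, and an optional `# genome_length: N` pragma. When the pragma is
#' absent the genome length is the maximum feature end.
#'
#' @param path Path to the TSV file.
#' @param circular Logical, passed through to [feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  gl <- NULL
  pragma <- grep("^#\\s*genome_length\\s*[:=]", lines, value = TRUE)
  if (length(pragma)) {
    gl <- as.integer(sub("^#\\s*genome_length\\s*[:=]\\s*", "", pragma[1]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("empty feature table: ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          header = TRUE, sep = "\t",
                          colClasses = "character", fill = TRUE,
                          strip.white = TRUE)
  names(df)[names(df) == "feature"] <- "name"
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed coordinate in column '%s' at data line %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!is.null(df[[col]])) {
      v <- df[[col]]
      v[is.na(v) | !nzchar(v)] <- NA_character_
      df[[col]] <- v
    }
  }
  feature_table(df, genome_length = gl, circular = circular)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: emits the same dialect including the
#' `# genome_length` pragma, so read/write round trips are content-identical.
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  f <- x$features
  out <- data.frame(feature = f$name, class = f$class, strand = f$strand,
                    start = f$start, end = f$end,
                    start_codon = ifelse(is.na(f$start_codon), "", f$start_codon),
                    stop_codon = ifelse(is.na(f$stop_codon), "", f$stop_codon),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome_length: %d", x$genome_length), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a feature's sequence from a genome record
#'
#' Returns the substring `start..end` (1-based inclusive); light-strand
#' features are reverse complemented so the returned string reads 5'->3'
#' in the gene's own sense.
#'
#' @param record A `genome_record`.
#' @param feature One-row data.frame (a `feature_table` row) or a list with
#'   `start`, `end`, `strand`.
#' @return DNA string of length `end - start + 1`.
#' @export
extract_gene_sequence <- function(record, feature) {
  stopifnot(inherits(record, "genome_record"))
  start <- as.integer(feature$start); end <- as.integer(feature$end)
  strand <- as.character(feature$strand)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid feature coordinates")
  }
  if (end > record$length) stop("feature coordinates exceed genome length")
  s <- substr(record$sequence, start, end)
  if (identical(strand, "L")) s <- reverse_complement(s)
  s
}

## ---- FASTA -----------------------------------------------------------------

#' Read a (possibly aligned) FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA (70-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

## ---- GenBank flat files ----------------------------------------------------

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", trimws(loc))
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) {
    stop("unsupported (joined/wrapped) feature location: ", loc)
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
  if (length(m) != 3L) {
    m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1L]]
    if (length(m1) == 2L) return(list(start = as.integer(m1[2]), end = as.integer(m1[2]), strand = strand))
    stop("cannot parse feature location: ", loc)
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flat file
#'
#' Minimal reader for annotated mitogenomes: parses the LOCUS line (length,
#' circular flag), the CDS / tRNA / rRNA / D-loop / rep_origin features with
#' simple or `complement()` locations (joined locations are rejected), and
#' the ORIGIN sequence. Feature names are normalized via
#' [normalize_feature_name()]; start/stop codons of CDS features are derived
#' from the sequence. Coordinates follow GenBank's 1-based inclusive
#' convention, which is also the package convention.
#'
#' @param path GenBank flat-file path.
#' @return List with elements `record` (a `genome_record`) and `table`
#'   (a `feature_table`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1L]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart)) stop("GenBank record has no FEATURES block")
  fend <- if (length(ostart)) ostart[1] - 1L else length(lines)
  fl <- lines[(fstart[1] + 1L):fend]
  fl <- fl[!grepl("^(CONTIG|BASE COUNT)", fl)]

  # group feature block lines: a new feature starts at indent 5 with a key
  keys <- grepl("^ {1,10}\\S", fl) & !grepl("^ {12,}", fl)
  idx <- cumsum(keys)
  feats <- list()
  for (g in split(fl[idx > 0], idx[idx > 0])) {
    head <- strsplit(trimws(g[1]), "\\s+")[[1L]]
    key <- head[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin")) next
    loc <- paste(head[-1], collapse = "")
    quals <- paste(trimws(g[-1]), collapse = " ")
    getq <- function(q) {
      m <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', q), quals))[[1L]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    pos <- parse_gb_location(loc)
    nm <- getq("gene")
    if (is.na(nm)) nm <- getq("product")
    if (is.na(nm)) nm <- key
    cls <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  `D-loop` = "CR", rep_origin = "OL")
    feats[[length(feats) + 1L]] <- data.frame(
      name = normalize_feature_name(nm), class = cls, strand = pos$strand,
      start = pos$start, end = pos$end,
      start_codon = NA_character_, stop_codon = NA_character_,
      anticodon = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("GenBank record has no supported features")
  df <- do.call(rbind, feats)

  n_cds <- sum(df$class == "PCG")
  if (n_cds != 13L) {
    warning(sprintf("expected 13 CDS features, found %d; continuing", n_cds))
  }

  if (!length(ostart)) {
    stop("GenBank record has no ORIGIN sequence (table-only mode: use the feature table alone)")
  }
  seqlines <- lines[(ostart[1] + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  record <- genome_record(id, seq, circular = circular)

  tab <- feature_table(df, genome_length = record$length, circular = circular)
  # derive CDS start/stop codons from the sequence
  f <- tab$features
  for (i in which(f$class == "PCG")) {
    cds <- extract_gene_sequence(record, f[i, ])
    f$start_codon[i] <- substr(cds, 1L, 3L)
    rem <- nchar(cds) %% 3L
    f$stop_codon[i] <- if (rem == 0L) substr(cds, nchar(cds) - 2L, nchar(cds))
                       else substr(cds, nchar(cds) - rem + 1L, nchar(cds))
  }
  tab$features <- f
  list(record = record, table = tab)
}

#' Write a genome record and its annotation as a GenBank flat file
#'
#' Emits a minimal flat file (LOCUS, FEATURES with gene qualifiers, ORIGIN)
#' that [read_genbank()] parses back to the identical feature table.
#'
#' @param record A `genome_record`.
#' @param table A `feature_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(record, table, path) {
  stopifnot(inherits(record, "genome_record"), inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     VRT",
                     record$id, record$length,
                     if (record$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- table$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$class[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", OL = "rep_origin")
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Feature table of the H. quoyi mitogenome annotation
#'
#' Convenience accessor for the annotation table shipped with the package
#' (GenBank accession MG851912.1, 16,525 bp).
#'
#' @return A `feature_table` with 39 features (13 PCGs, 22 tRNAs, 2 rRNAs,
#'   the light-strand replication origin and the control region).
#' @export
hquoyi_feature_table <- function() {
  read_feature_table(system.file("extdata", "hquoyi_mg851912_features.tsv",
                                 package = "mitochar"))
}
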