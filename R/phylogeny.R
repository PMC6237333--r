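#' Concatenate per-gene alignments into a supermatrix
#'
#' Each alignment is a named character vector (taxon -> aligned sequence);
#' all alignments must share the same taxon set and be true alignments
#' (equal lengths within a gene; unaligned input is refused). Genes are
#' appended in canonical mitogenome order when all names are recognized
#' PCGs, otherwise in the given order, and the column range of each gene is
#' recorded as a partition.
#'
#' @param alignments Named list of named character vectors.
#' @param type "nt" or "aa".
#' @return Object of class `supermatrix`: list with `taxa`, `seqs` (named
#'   character), `partitions` (data.frame gene/start/end), `type`.
#' @export
concatenate_alignments <- function(alignments, type = c("nt", "aa")) {
  type <- match.arg(type)
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  taxa <- sort(names(alignments[[1L]]))
  holes <- character()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    if (length(unique(nchar(aln))) != 1L) {
      stop("gene ", g, " is not aligned (unequal sequence lengths)")
    }
    miss <- setdiff(taxa, names(aln))
    extra <- setdiff(names(aln), taxa)
    if (length(miss) || length(extra)) {
      holes <- c(holes, sprintf("%s: missing {%s} extra {%s}", g,
                                paste(miss, collapse = ","),
                                paste(extra, collapse = ",")))
    }
  }
  if (length(holes)) {
    stop("taxon sets differ across genes:\n  ", paste(holes, collapse = "\n  "))
  }
  genes <- names(alignments)
  if (all(genes %in% PCG_ORDER)) genes <- PCG_ORDER[PCG_ORDER %in% genes]
  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(gene = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  pos <- 0L
  for (g in genes) {
    aln <- alignments[[g]][taxa]
    w <- nchar(aln[[1L]])
    seqs <- paste0(seqs, aln)
    parts <- rbind(parts, data.frame(gene = g, start = pos + 1L,
                                     end = pos + w, stringsAsFactors = FALSE))
    pos <- pos + w
  }
  structure(list(taxa = taxa, seqs = stats::setNames(seqs, taxa),
                 partitions = parts, type = type),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix (%s): %d taxa x %d columns, %d partitions\n",
              x$type, length(x$taxa), nchar(x$seqs[[1L]]), nrow(x$partitions)))
  invisible(x)
}

supermatrix_dnabin <- function(sm) {
  m <- do.call(rbind, strsplit(tolower(sm$seqs), "", fixed = TRUE))
  rownames(m) <- sm$taxa
  ape::as.DNAbin(m)
}

#' Pairwise distance matrix from a nucleotide supermatrix
#'
#' p distance (mismatch proportion), Jukes-Cantor (JC69) or Kimura
#' two-parameter (K2P) distances with pairwise deletion of gap/ambiguous
#' sites. Saturated pairs (undefined log) come back NaN.
#'
#' @param sm A nucleotide `supermatrix`.
#' @param model One of "p", "JC69", "K2P".
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(sm, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  stopifnot(inherits(sm, "supermatrix"))
  if (sm$type != "nt") stop("distance_matrix requires a nucleotide supermatrix")
  dna <- supermatrix_dnabin(sm)
  mod <- switch(model, p = "raw", JC69 = "JC69", K2P = "K80")
  as.matrix(ape::dist.dna(dna, model = mod, pairwise.deletion = TRUE))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape); negative branch lengths are clamped
#' to zero with the total clamped deficit recorded in the `clamped`
#' attribute.
#'
#' @param D Symmetric distance matrix (>= 3 taxa, no NA/NaN).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(D))) stop("distance matrix contains undefined entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(as.dist(D))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- deficit
  tree
}

#' Bootstrap supports for a neighbor-joining supermatrix tree
#'
#' Resamples alignment columns with replacement (within genes when
#' `per_gene = TRUE`), rebuilds the NJ tree per replicate, and annotates
#' each internal node of the original tree with the percentage of
#' replicates containing its bipartition.
#'
#' @param sm A nucleotide `supermatrix`.
#' @param model Distance model (see [distance_matrix()]).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed fixing the resampling.
#' @param per_gene Resample within partitions (default FALSE).
#' @return The NJ tree (`phylo`) with `node.label` set to support
#'   percentages (root label empty).
#' @export
bootstrap_nj <- function(sm, model = "K2P", replicates = 100L, seed = 1L,
                         per_gene = FALSE) {
  stopifnot(inherits(sm, "supermatrix"), replicates >= 1L)
  set.seed(as.integer(seed))
  chars <- do.call(rbind, strsplit(sm$seqs, "", fixed = TRUE))
  rownames(chars) <- sm$taxa
  ncol_total <- ncol(chars)
  build <- function(mat) {
    sm2 <- sm
    sm2$seqs <- stats::setNames(apply(mat, 1L, paste, collapse = ""), sm$taxa)
    neighbor_joining(distance_matrix(sm2, model = model))
  }
  tree <- build(chars)
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- if (per_gene) {
      unlist(lapply(seq_len(nrow(sm$partitions)), function(k) {
        cols <- sm$partitions$start[k]:sm$partitions$end[k]
        sample(cols, length(cols), replace = TRUE)
      }))
    } else {
      sample.int(ncol_total, ncol_total, replace = TRUE)
    }
    boots[[r]] <- tryCatch(build(chars[, idx, drop = FALSE]),
                           error = function(e) NULL)
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(round(100 * counts / length(boots)))
  attr(tree, "replicates_used") <- length(boots)
  tree
}

#' Monophyly test with intruder reporting
#'
#' Roots the tree on the outgroup and asks whether the taxon subset forms a
#' clade. When it does not, the minimal set of intruding taxa (descendants
#' of the subset's most recent common ancestor that are outside the subset)
#' is returned.
#'
#' @param tree A `phylo` tree (or newick string).
#' @param taxa Non-empty character vector of tip labels.
#' @param outgroup Tip label (or vector) to root on.
#' @return List with `monophyletic` (logical) and `intruders` (character).
#' @export
is_monophyletic_group <- function(tree, taxa, outgroup) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1L)
  unknown <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (length(taxa) == 1L) return(list(monophyletic = TRUE, intruders = character()))
  mono <- ape::is.monophyletic(rooted, taxa)
  intruders <- character()
  if (!mono) {
    mrca <- ape::getMRCA(rooted, taxa)
    desc <- ape::extract.clade(rooted, mrca)$tip.label
    intruders <- setdiff(desc, taxa)
  }
  list(monophyletic = mono, intruders = intruders)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' @param t1,t2 `phylo` trees (or newick strings) on the same taxon set.
#' @return Non-negative integer (PH85 symmetric-difference metric).
#' @export
robinson_foulds <- function(t1, t2) {
  if (is.character(t1)) t1 <- ape::read.tree(text = t1)
  if (is.character(t2)) t2 <- ape::read.tree(text = t2)
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85"))
}

#' Export a supermatrix as relaxed PHYLIP
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$seqs[[1L]])), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$seqs), con)
  invisible(path)
}

#' Export a supermatrix as NEXUS with a partition block
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_nexus <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                       nchar(sm$seqs[[1L]])),
               sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-;",
                       if (sm$type == "nt") "DNA" else "PROTEIN"),
               "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", sm$taxa, sm$seqs), con)
  writeLines(c("  ;", "END;", "BEGIN SETS;"), con)
  writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), con)
  writeLines("END;", con)
  invisible(path)
}
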