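# Synthetic mitogenomes, tRNAs and codon alignments with known ground truth.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators. Defaults emulate a
#' typical teleost mitogenome: 13 PCGs / 22 tRNAs / 2 rRNAs / OL + CR in
#' the canonical vertebrate gene order, base frequencies giving a mildly
#' positive AT skew and strongly negative GC skew, and purifying selection
#' (omega 0.1) with transition bias (kappa 2) for codon evolution.
#'
#' @param seed Integer seed; fixes all generator output.
#' @param target_at_skew,target_gc_skew Whole-genome skew targets in
#'   (-1, 1); the generator polishes composition to within 0.01 of each.
#' @param base_freqs Named A/C/G/T sampling frequencies for coding and
#'   background sequence.
#' @param spacer_max Maximum random intergenic spacer (bp) between
#'   consecutive features (default 2; no overlaps are generated).
#' @param omega Nonsynonymous/synonymous rate ratio for codon evolution.
#' @param kappa Transition/transversion rate ratio.
#' @param cr_length Control-region length (bp).
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              target_at_skew = 0.03,
                              target_gc_skew = -0.29,
                              base_freqs = c(A = 0.293, C = 0.275,
                                             G = 0.153, T = 0.279),
                              spacer_max = 2L,
                              omega = 0.1,
                              kappa = 2,
                              cr_length = 866L) {
  stopifnot(abs(target_at_skew) < 1, abs(target_gc_skew) < 1,
            omega >= 0, kappa > 0, cr_length >= 100L)
  structure(list(seed = as.integer(seed),
                 target_at_skew = target_at_skew,
                 target_gc_skew = target_gc_skew,
                 base_freqs = base_freqs / sum(base_freqs),
                 spacer_max = as.integer(spacer_max),
                 omega = omega, kappa = kappa,
                 cr_length = as.integer(cr_length)),
            class = "sim_config")
}

sample_bases <- function(n, freqs) {
  if (n <= 0L) return(character())
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# sample n sense codons by per-base frequencies, rejecting stop codons
sample_sense_codons <- function(n, freqs, code) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(sample_bases(n, freqs), sample_bases(n, freqs),
                   sample_bases(n, freqs))
    out <- c(out, cand[!cand %in% code$stop_codons])
  }
  out[seq_len(n)]
}

## ---- tRNA generator --------------------------------------------------------

#' Default tRNA arm specification
#'
#' @param acceptor,dhu_stem,dhu_loop,anticodon_stem,tpsic_stem,tpsic_loop
#'   Arm dimensions (bp / nt); `dhu_stem = 0` builds a DHU-less tRNA with
#'   `dhu_loop` acting as connector length.
#' @param g1,g2 Connector lengths flanking the DHU arm.
#' @param var Variable-region length.
#' @param disc Discriminator tail length.
#' @param anticodon Optional anticodon 3-mer (random when NULL).
#' @param gu_pairs Number of G.U wobble pairs to plant (filled into the
#'   acceptor stem first, then the T and anticodon stems).
#' @return List understood by [generate_trna()].
#' @export
trna_arms_spec <- function(acceptor = 7L, dhu_stem = 4L, dhu_loop = 8L,
                           anticodon_stem = 5L, tpsic_stem = 5L,
                           tpsic_loop = 7L, g1 = 2L, g2 = 1L, var = 4L,
                           disc = 1L, anticodon = NULL, gu_pairs = 0L) {
  if (dhu_stem == 0L) { g1 <- 1L; g2 <- 0L }  # deny slack to fake DHU folds
  list(acceptor = acceptor, dhu_stem = dhu_stem, dhu_loop = dhu_loop,
       anticodon_stem = anticodon_stem, tpsic_stem = tpsic_stem,
       tpsic_loop = tpsic_loop, g1 = g1, g2 = g2, var = var, disc = disc,
       anticodon = anticodon, gu_pairs = as.integer(gu_pairs))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Generate a tRNA sequence with a designed cloverleaf
#'
#' Builds a sequence on the cloverleaf layout of [fold_cloverleaf()] whose
#' stems are fully Watson-Crick paired except for optionally planted G.U
#' wobble pairs. Loop and connector bases adjacent to stems are chosen so
#' they cannot extend any stem, and the construction is verified against
#' the folder: if an accidental pairing elsewhere would make an alternative
#' placement tie or win, the unpaired regions are resampled
#' (deterministically under the seed) until the designed fold is the
#' recovered optimum.
#'
#' @param arms_spec A [trna_arms_spec()].
#' @param seed Integer seed.
#' @return List with `seq` (DNA string) and `truth` (the designed arm
#'   dimensions, anticodon and planted G.U count).
#' @export
generate_trna <- function(arms_spec = trna_arms_spec(), seed = 1L) {
  for (attempt in 0:24) {
    out <- build_trna_once(arms_spec, as.integer(seed) + 7717L * attempt)
    m <- fold_cloverleaf(out$seq)
    tt <- out$truth
    dhu_ok <- if (tt$dhu_stem > 0L) {
      !is.null(m$dhu_arm) && m$dhu_arm$stem == tt$dhu_stem
    } else is.null(m$dhu_arm)
    if (m$acceptor_stem$length == tt$acceptor && dhu_ok &&
        m$anticodon_arm$stem == tt$anticodon_stem &&
        m$tpsic_arm$stem == tt$tpsic_stem &&
        m$anticodon_arm$anticodon == tt$anticodon &&
        m$gu_pairs == tt$gu_pairs) {
      return(out)
    }
  }
  stop("could not realize the designed cloverleaf as the folding optimum")
}

build_trna_once <- function(arms_spec, seed) {
  s <- arms_spec
  grid_ok <- s$acceptor %in% 6:9 && s$dhu_stem %in% c(0L, 3:4) &&
    (if (s$dhu_stem > 0L) s$dhu_loop %in% 4:11 else s$dhu_loop %in% 2:8) &&
    s$anticodon_stem %in% 4:6 && s$tpsic_stem %in% 4:5 &&
    s$tpsic_loop %in% 3:9 && s$g1 %in% 1:3 && s$g2 %in% 0:2 &&
    s$var %in% 3:23 && s$disc %in% 0:4
  if (!grid_ok) stop("tRNA arm specification outside the cloverleaf constraint grid")
  set.seed(as.integer(seed))
  block <- if (s$dhu_stem > 0L) 2L * s$dhu_stem + s$dhu_loop else s$dhu_loop
  n <- 2L * s$acceptor + s$g1 + block + s$g2 + 2L * s$anticodon_stem + 7L +
    s$var + 2L * s$tpsic_stem + s$tpsic_loop + s$disc
  if (n < 55L || n > 95L) stop("designed tRNA length outside 55-95 nt: ", n)
  # unpaired regions are A/C-rich (A and C pair with neither each other nor
  # themselves), so the designed stems are the unique pairing optimum
  chars <- sample_bases(n, c(A = 0.5, C = 0.4, G = 0.05, T = 0.05))

  pr <- cloverleaf_pairs(n, s$acceptor, s$disc, s$g1, s$dhu_stem, s$dhu_loop,
                         s$g2, s$anticodon_stem, s$tpsic_stem, s$tpsic_loop)
  stems <- Filter(Negate(is.null),
                  list(acceptor = pr$acceptor, tpsic = pr$tpsic,
                       anticodon = pr$anticodon, dhu = pr$dhu))
  # Watson-Crick pair every stem position; 5' sides uniform over the alphabet
  for (m in stems) {
    for (k in seq_len(nrow(m))) {
      chars[m[k, "i"]] <- sample(c("A", "C", "G", "T"), 1L)
      chars[m[k, "j"]] <- complement_base(chars[m[k, "i"]])
    }
  }
  # plant G.U wobble pairs (5' G vs 3' T), acceptor stem first
  slots <- do.call(rbind, stems)
  if (s$gu_pairs > nrow(slots)) stop("more G.U pairs requested than stem slots")
  if (s$gu_pairs > 0L) {
    for (k in seq_len(s$gu_pairs)) {
      chars[slots[k, "i"]] <- "G"
      chars[slots[k, "j"]] <- "T"
    }
  }
  if (!is.null(s$anticodon)) {
    ac <- seq_chars(check_dna(s$anticodon, allow_n = FALSE))
    stopifnot(length(ac) == 3L)
    chars[pr$anticodon_pos] <- ac
  }

  # guards: free positions flanking stems must not extend them
  guard <- function(free, fixed) {
    if (pair_ok(chars[free], chars[fixed])) {
      choices <- setdiff(c("A", "C", "G", "T"),
                         c(chars[free],
                           c(A = "T", T = "A", G = "C", C = "G")[chars[fixed]],
                           if (chars[fixed] %in% c("G", "T"))
                             c(G = "T", T = "G")[chars[fixed]]))
      chars[free] <<- choices[1L]
    }
  }
  q <- s$acceptor + s$g1
  p <- q + block + s$g2
  r <- n - s$disc - s$acceptor
  if (s$dhu_stem > 0L) {  # DHU loop ends
    guard(q + s$dhu_stem + 1L, q + s$dhu_stem + s$dhu_loop)
  }
  guard(p + s$anticodon_stem + 7L, p + s$anticodon_stem + 1L)   # AC loop ends
  guard(r - s$tpsic_stem - s$tpsic_loop + 1L, r - s$tpsic_stem) # T loop ends
  guard(s$acceptor + 1L, r)                                     # g1[1] vs T-arm end
  if (s$var >= 2L) {
    guard(p + 2L * s$anticodon_stem + 7L + s$var, r - s$tpsic_stem)  # var end
    guard(p + 2L * s$anticodon_stem + 8L, p)                         # var[1] vs p
  }

  anticodon <- paste(chars[pr$anticodon_pos], collapse = "")
  list(seq = paste(chars, collapse = ""),
       truth = list(acceptor = s$acceptor, dhu_stem = s$dhu_stem,
                    dhu_loop = s$dhu_loop, anticodon_stem = s$anticodon_stem,
                    tpsic_stem = s$tpsic_stem, tpsic_loop = s$tpsic_loop,
                    g1 = s$g1, g2 = s$g2, var = s$var, disc = s$disc,
                    anticodon = anticodon, gu_pairs = s$gu_pairs,
                    length = n))
}

## ---- codon evolution -------------------------------------------------------

transition_pair <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

# substitution targets and relative rates for every sense codon
codon_rate_table <- function(code, omega, kappa) {
  lapply(stats::setNames(code$sense_codons, code$sense_codons), function(cd) {
    nb <- codon_neighbors(cd)
    keep <- !nb %in% code$stop_codons
    nb <- nb[keep]
    from <- seq_chars(cd)
    rates <- vapply(nb, function(tg) {
      to <- seq_chars(tg)
      pchg <- which(from != to)
      r <- if (transition_pair(from[pchg], to[pchg])) kappa else 1
      if (identical(unname(code$map[cd]), unname(code$map[tg]))) r else r * omega
    }, numeric(1))
    list(targets = nb, rates = rates, total = sum(rates))
  })
}

evolve_branch <- function(codons, t, rate_tab, mu) {
  for (i in seq_along(codons)) {
    remaining <- t
    repeat {
      entry <- rate_tab[[codons[i]]]
      R <- entry$total / mu
      if (R <= 0) break
      dt <- stats::rexp(1L, R)
      if (dt > remaining) break
      remaining <- remaining - dt
      codons[i] <- sample(entry$targets, 1L, prob = entry$rates)
    }
  }
  codons
}

#' Evolve a codon alignment along a tree
#'
#' Gillespie-style exact codon substitution: each single-nucleotide change
#' has relative rate kappa (transitions) or 1 (transversions), multiplied
#' by omega when nonsynonymous; changes into stop codons are forbidden.
#' Rates are normalized so branch lengths are expected substitutions per
#' codon at the ancestral composition. No indels: the output is aligned by
#' construction.
#'
#' @param ancestor_codons Character vector of sense codons, or an in-frame
#'   CDS string (multiple of 3, no stops).
#' @param tree `phylo` tree or newick string with branch lengths.
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param code A [genetic_code()].
#' @return Named character vector of tip CDS strings.
#' @export
evolve_codon_alignment <- function(ancestor_codons, tree, omega = 0.1,
                                   kappa = 2, seed = 1L,
                                   code = genetic_code(2)) {
  if (omega < 0) stop("omega must be >= 0")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length(ancestor_codons) == 1L && nchar(ancestor_codons) > 3L) {
    ancestor_codons <- split_codons(check_dna(ancestor_codons, allow_n = FALSE))
  }
  if (any(ancestor_codons %in% code$stop_codons)) {
    stop("ancestor contains stop codons")
  }
  set.seed(as.integer(seed))
  rate_tab <- codon_rate_table(code, omega, kappa)
  mu <- mean(vapply(ancestor_codons, function(cd) rate_tab[[cd]]$total, numeric(1)))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- ancestor_codons
  # preorder edge traversal: parents always visited before children
  ord <- order(tree$edge[, 1L])
  for (e in ord) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    states[[child]] <- evolve_branch(states[[parent]], tree$edge.length[e],
                                     rate_tab, mu)
  }
  out <- vapply(seq_len(ntip), function(i) paste(states[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}

#' Simulate per-gene codon alignments along a tree
#'
#' @param tree `phylo` or newick string.
#' @param gene_codons Named integer vector, gene -> number of codons.
#' @param omega,kappa Codon-model parameters.
#' @param seed Integer seed (per-gene seeds are derived from it).
#' @param code A [genetic_code()].
#' @param base_freqs Ancestor base-sampling frequencies.
#' @return Named list of alignments (named character vectors), suitable for
#'   [concatenate_alignments()].
#' @export
simulate_gene_alignments <- function(tree, gene_codons, omega = 0.1,
                                     kappa = 2, seed = 1L,
                                     code = genetic_code(2),
                                     base_freqs = c(A = 0.3, C = 0.27,
                                                    G = 0.16, T = 0.27)) {
  stopifnot(!is.null(names(gene_codons)))
  out <- list()
  for (k in seq_along(gene_codons)) {
    set.seed(as.integer(seed) + 7919L * k)
    anc <- sample_sense_codons(gene_codons[[k]], base_freqs / sum(base_freqs), code)
    out[[names(gene_codons)[k]]] <-
      evolve_codon_alignment(anc, tree, omega, kappa,
                             seed = as.integer(seed) + 104729L * k, code = code)
  }
  out
}

## ---- whole-mitogenome generator --------------------------------------------

# canonical gene plan: name, class, strand, length (bp; tRNAs sized by their
# arm specs at build time, lengths here are placeholders)
default_gene_plan <- function(cr_length = 866L) {
  plan <- rbind(
    c("trnF",  "tRNA", "H", 0), c("rrnS", "rRNA", "H", 944),
    c("trnV",  "tRNA", "H", 0), c("rrnL", "rRNA", "H", 1687),
    c("trnL1", "tRNA", "H", 0), c("nad1", "PCG",  "H", 975),
    c("trnI",  "tRNA", "H", 0), c("trnQ", "tRNA", "L", 0),
    c("trnM",  "tRNA", "H", 0), c("nad2", "PCG",  "H", 1047),
    c("trnW",  "tRNA", "H", 0), c("trnA", "tRNA", "L", 0),
    c("trnN",  "tRNA", "L", 0), c("OL",   "OL",   "L", 38),
    c("trnC",  "tRNA", "L", 0), c("trnY", "tRNA", "L", 0),
    c("cox1",  "PCG",  "H", 1554), c("trnS1", "tRNA", "L", 0),
    c("trnD",  "tRNA", "H", 0), c("cox2", "PCG",  "H", 691),
    c("trnK",  "tRNA", "H", 0), c("atp8", "PCG",  "H", 168),
    c("atp6",  "PCG",  "H", 684), c("cox3", "PCG", "H", 786),
    c("trnG",  "tRNA", "H", 0), c("nad3", "PCG",  "H", 351),
    c("trnR",  "tRNA", "H", 0), c("nad4l", "PCG", "H", 297),
    c("nad4",  "PCG",  "H", 1378), c("trnH", "tRNA", "H", 0),
    c("trnS2", "tRNA", "H", 0), c("trnL2", "tRNA", "H", 0),
    c("nad5",  "PCG",  "H", 1839), c("nad6", "PCG", "L", 522),
    c("trnE",  "tRNA", "L", 0), c("cytb", "PCG",  "H", 1141),
    c("trnT",  "tRNA", "H", 0), c("trnP", "tRNA", "L", 0),
    c("CR",    "CR",   "H", cr_length))
  data.frame(name = plan[, 1], class = plan[, 2], strand = plan[, 3],
             length = as.integer(plan[, 4]), stringsAsFactors = FALSE)
}

INCOMPLETE_STOP_GENES <- c("cox2", "nad4", "cytb")
TAG_STOP_GENES <- "nad2"

make_cds <- function(gene, len, freqs, code) {
  start <- if (gene == "cox1") "GTG" else "ATG"
  stop_c <- if (gene %in% INCOMPLETE_STOP_GENES) "T"
            else if (gene %in% TAG_STOP_GENES) "TAG" else "TAA"
  nbody <- (len - 3L - nchar(stop_c)) / 3L
  stopifnot(nbody == floor(nbody), nbody >= 1)
  paste0(start, paste(sample_sense_codons(nbody, freqs, code), collapse = ""),
         stop_c)
}

make_ol <- function(len, freqs) {
  stopifnot(len >= 20L)
  stem <- 12L
  loop <- len - 2L * stem
  s5 <- sample_bases(stem, freqs)
  lp <- sample_bases(loop, freqs)
  # loop ends must not extend the stem
  if (pair_ok(lp[1L], lp[loop])) {
    lp[1L] <- setdiff(c("A", "C", "G", "T"),
                      c(complement_base(lp[loop]),
                        if (lp[loop] %in% c("G", "T"))
                          c(G = "T", T = "G")[[lp[loop]]]))[1L]
  }
  s3 <- rev(vapply(s5, complement_base, character(1)))
  paste(c(s5, lp, s3), collapse = "")
}

make_cr <- function(len, seed_offset, freqs) {
  at_rich <- c(A = 0.34, C = 0.20, G = 0.13, T = 0.33)
  chars <- sample_bases(len, at_rich)
  motifs <- c("GGTTTTT", "CTTAATG", "ATGTA", "TACAT")
  offsets <- sort(sample(seq(20L, len - 40L), length(motifs)))
  # keep planted motifs from overlapping
  while (any(diff(offsets) < 10L)) {
    offsets <- sort(sample(seq(20L, len - 40L), length(motifs)))
  }
  for (k in seq_along(motifs)) {
    idx <- offsets[k]:(offsets[k] + nchar(motifs[k]) - 1L)
    chars[idx] <- seq_chars(motifs[k])
  }
  list(seq = paste(chars, collapse = ""),
       motifs = data.frame(motif = motifs, position = offsets,
                           stringsAsFactors = FALSE))
}

# flip free-position bases pairwise (T<->A, C<->G) until skews hit targets
polish_skew <- function(chars, free_idx, target_at, target_gc) {
  adjust <- function(chars, hi, lo, target) {
    nh <- sum(chars == hi); nl <- sum(chars == lo)
    flips <- round((target * (nh + nl) - (nh - nl)) / 2)
    if (flips == 0) return(chars)
    from <- if (flips > 0) lo else hi
    to <- if (flips > 0) hi else lo
    pool <- free_idx[chars[free_idx] == from]
    k <- abs(flips)
    if (length(pool) < k) {
      stop("infeasible skew target: not enough free ", from, " positions")
    }
    chars[pool[seq_len(k)]] <- to
    chars
  }
  chars <- adjust(chars, "A", "T", target_at)
  adjust(chars, "G", "C", target_gc)
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a circular genome with the canonical vertebrate mitochondrial
#' content: 13 PCGs (ATG starts except cox1 with GTG; TAA stops except a
#' TAG and three incomplete T stops), 22 designed cloverleaf tRNAs (trnS2
#' DHU-less), 2 rRNAs, a hairpin-forming OL and a control region with
#' planted conserved motifs. Whole-genome AT and GC skews are polished to
#' within 0.01 of their targets by base flips in the unconstrained (rRNA,
#' CR, spacer) positions. Gene content and lengths follow the canonical
#' plan; intergenic spacers of 0 to `spacer_max` bp are inserted and no
#' gene overlaps are generated.
#'
#' @param cfg A [simulation_config()].
#' @return List with `record` (a `genome_record`), `table`
#'   (a `feature_table`) and `truth` (gene sequences, tRNA arm truths,
#'   planted CR motif positions, spacers, config echo).
#' @export
generate_mitogenome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  code <- genetic_code(2)
  plan <- default_gene_plan(cfg$cr_length)
  freqs <- cfg$base_freqs

  aa_letters <- c(F = "GAA", V = "TAC", L1 = "TAG", I = "GAT", Q = "TTG",
                  M = "CAT", W = "TCA", A = "TGC", N = "GTT", C = "GCA",
                  Y = "GTA", S1 = "TGA", D = "GTC", K = "TTT", G = "TCC",
                  R = "TCG", H = "GTG", S2 = "GCT", L2 = "TAA", E = "TTC",
                  T = "TGT", P = "TGG")
  trna_counter <- 0L

  gene_seqs <- list(); trna_truths <- list(); spacers <- integer(0)
  rows <- list(); genome_parts <- character(0)
  pos <- 0L
  cr_truth <- NULL
  for (i in seq_len(nrow(plan))) {
    g <- plan[i, ]
    seed_i <- cfg$seed + 1000L * i
    if (g$class == "PCG") {
      set.seed(seed_i)
      s <- make_cds(g$name, g$length, freqs, code)
    } else if (g$class == "rRNA") {
      set.seed(seed_i)
      s <- paste(sample_bases(g$length, freqs), collapse = "")
    } else if (g$class == "OL") {
      set.seed(seed_i)
      s <- make_ol(g$length, freqs)
    } else if (g$class == "CR") {
      set.seed(seed_i)
      cr <- make_cr(g$length, seed_i, freqs)
      s <- cr$seq
      cr_truth <- cr$motifs
    } else { # tRNA
      trna_counter <- trna_counter + 1L
      short <- sub("^trn", "", g$name)
      spec <- if (g$name == "trnS2") {
        trna_arms_spec(dhu_stem = 0L, dhu_loop = 5L, var = 9L,
                       anticodon = aa_letters[[short]])
      } else {
        # one wobble pair in 16 of the tRNAs (a typical teleost total)
        trna_arms_spec(var = 3L + (trna_counter %% 4L),
                       tpsic_loop = 6L + (trna_counter %% 3L),
                       anticodon = aa_letters[[short]],
                       gu_pairs = as.integer(trna_counter <= 16L))
      }
      tr <- generate_trna(spec, seed = seed_i)
      s <- tr$seq
      trna_truths[[g$name]] <- tr$truth
    }
    gene_seqs[[g$name]] <- s
    # spacer before this feature (none before the first)
    set.seed(seed_i + 1L)
    sp <- if (i == 1L) 0L else sample(0:cfg$spacer_max, 1L)
    spacers <- c(spacers, sp)
    if (sp > 0L) genome_parts <- c(genome_parts,
                                   paste(sample_bases(sp, freqs), collapse = ""))
    start <- pos + sp + 1L
    end <- start + nchar(s) - 1L
    genome_parts <- c(genome_parts,
                      if (g$strand == "L") reverse_complement(s) else s)
    rows[[i]] <- data.frame(name = g$name, class = g$class, strand = g$strand,
                            start = start, end = end,
                            start_codon = NA_character_,
                            stop_codon = NA_character_,
                            anticodon = NA_character_,
                            stringsAsFactors = FALSE)
    if (g$class == "PCG") {
      ec <- extract_codons(s, code)
      rows[[i]]$start_codon <- ec$classification$start_codon
      rows[[i]]$stop_codon <- ec$classification$stop_codon
    }
    pos <- end
  }

  chars <- unlist(strsplit(genome_parts, "", fixed = TRUE))
  tab <- do.call(rbind, rows)

  # free positions for skew polishing: rRNA spans, CR outside planted
  # motifs, and spacers
  free <- logical(length(chars))
  for (i in seq_len(nrow(tab))) {
    if (tab$class[i] %in% c("rRNA")) free[tab$start[i]:tab$end[i]] <- TRUE
  }
  cr_row <- tab[tab$class == "CR", ]
  free[cr_row$start:cr_row$end] <- TRUE
  for (k in seq_len(nrow(cr_truth))) {
    idx <- (cr_row$start + cr_truth$position[k] - 1L):
      (cr_row$start + cr_truth$position[k] + nchar(cr_truth$motif[k]) - 2L)
    free[idx] <- FALSE
  }
  covered <- logical(length(chars))
  for (i in seq_len(nrow(tab))) covered[tab$start[i]:tab$end[i]] <- TRUE
  free[!covered] <- TRUE

  set.seed(cfg$seed + 999983L)
  chars <- polish_skew(chars, which(free), cfg$target_at_skew, cfg$target_gc_skew)

  record <- genome_record(sprintf("SYNTH%06d", cfg$seed),
                          paste(chars, collapse = ""), circular = TRUE)
  # re-extract sequences of free-region features after polishing
  ft <- feature_table(tab, genome_length = record$length, circular = TRUE)
  for (nm in names(gene_seqs)) {
    row <- ft$features[ft$features$name == nm, ]
    if (row$class %in% c("rRNA", "CR")) {
      gene_seqs[[nm]] <- extract_gene_sequence(record, row)
    }
  }
  list(record = record, table = ft,
       truth = list(gene_seqs = gene_seqs, trna = trna_truths,
                    cr_motifs = cr_truth, spacers = spacers, config = cfg))
}
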