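# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Sites: at each codon position the synonymous fraction is the share of
# single-nucleotide neighbors coding the same amino acid; neighbors that are
# stop codons leave the denominator. Differences: averaged over all minimal
# mutational pathways between two codons that avoid stop intermediates.

BASES <- c("A", "C", "G", "T")

codon_neighbors <- function(codon) {
  chars <- seq_chars(codon)
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(BASES, chars[p])) {
      x <- chars; x[p] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

ng_sites_one <- function(codon, code) {
  chars <- seq_chars(codon)
  s <- 0
  for (p in 1:3) {
    nb <- vapply(setdiff(BASES, chars[p]), function(b) {
      x <- chars; x[p] <- b; paste(x, collapse = "")
    }, character(1))
    keep <- !nb %in% code$stop_codons
    if (any(keep)) {
      syn <- sum(code$map[nb[keep]] == code$map[codon])
      s <- s + syn / sum(keep)
    }
  }
  c(s = s, n = 3 - s)
}

# memoised per-code site table
ng_cache <- new.env(parent = emptyenv())

ng_site_table <- function(code) {
  key <- as.character(code$table_id)
  if (is.null(ng_cache[[key]])) {
    tab <- t(vapply(code$sense_codons, ng_sites_one, numeric(2), code = code))
    colnames(tab) <- c("s", "n")
    ng_cache[[key]] <- tab
  }
  ng_cache[[key]]
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' @param codon Sense codon (3-mer).
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n = 3`.
#' @export
count_sites <- function(codon, code = genetic_code(2)) {
  codon <- check_dna(codon, allow_n = FALSE, what = "codon")
  if (nchar(codon) != 3L) stop("codon must be a 3-mer")
  if (is_stop_codon(codon, code)) stop("stop codon has no site counts: ", codon)
  tab <- ng_site_table(code)
  tab[codon, ]
}

# enumerate all orderings of the differing positions; count syn/nonsyn steps
# along pathways whose intermediate codons are not stops
ng_paths <- function(ca, cb, code, allow_stops = FALSE) {
  a <- seq_chars(ca); b <- seq_chars(cb)
  diffpos <- which(a != b)
  nd <- length(diffpos)
  if (nd == 0L) return(list(sd = 0, nd = 0, npaths = 1L))
  perms <- if (nd == 1L) list(diffpos) else {
    idx <- if (nd == 2L) list(c(1, 2), c(2, 1)) else {
      do.call(c, lapply(1:3, function(i) {
        rest <- setdiff(1:3, i)
        list(c(i, rest[1], rest[2]), c(i, rest[2], rest[1]))
      }))
    }
    lapply(idx, function(o) diffpos[o])
  }
  sd_tot <- 0; nd_tot <- 0; nvalid <- 0L
  for (ord in perms) {
    cur <- a
    sd <- 0; nd_ <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
      if (!allow_stops && cto %in% code$stop_codons && !identical(cto, cb)) {
        ok <- FALSE; break
      }
      if (cto %in% code$stop_codons) { # endpoint stop never happens for sense input
        ok <- ok && identical(cto, cb)
      }
      if (identical(unname(code$map[cfrom]), unname(code$map[cto]))) sd <- sd + 1
      else nd_ <- nd_ + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd_; nvalid <- nvalid + 1L }
  }
  list(sd = sd_tot, nd = nd_tot, npaths = nvalid)
}

#' Nei-Gojobori synonymous/nonsynonymous differences between two codons
#'
#' Averages over all minimal mutational pathways between the codons,
#' discarding pathways that pass through a stop codon. If every pathway is
#' blocked, the average over all pathways (ignoring the stop constraint)
#' is returned with a warning.
#'
#' @param codon_a,codon_b Sense codons.
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(sd = ..., nd = ...)`;
#'   `sd + nd` = number of differing positions.
#' @export
count_differences <- function(codon_a, codon_b, code = genetic_code(2)) {
  codon_a <- check_dna(codon_a, allow_n = FALSE, what = "codon_a")
  codon_b <- check_dna(codon_b, allow_n = FALSE, what = "codon_b")
  if (nchar(codon_a) != 3L || nchar(codon_b) != 3L) stop("codons must be 3-mers")
  if (is_stop_codon(codon_a, code) || is_stop_codon(codon_b, code)) {
    stop("stop codons are not compared")
  }
  res <- ng_paths(codon_a, codon_b, code)
  if (res$npaths == 0L) {
    warning(sprintf("all pathways %s->%s blocked by stops; averaging over all orderings",
                    codon_a, codon_b))
    res <- ng_paths(codon_a, codon_b, code, allow_stops = TRUE)
  }
  c(sd = res$sd / res$npaths, nd = res$nd / res$npaths)
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' `d = -(3/4) log(1 - (4/3) p)`; p >= 3/4 is saturated (NA).
#'
#' @param p Proportion of differences.
#' @return Corrected distance or NA when saturated.
#' @export
jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Takes a gap-stripped, in-frame aligned CDS pair; codon columns containing
#' gaps, ambiguity, or stop codons in either sequence are dropped pairwise.
#' Synonymous (S) and nonsynonymous (N) site totals are averaged over the
#' two sequences; differences are pathway-averaged per codon pair;
#' ps = Sd/S and pn = Nd/N are Jukes-Cantor corrected into Ks and Ka.
#'
#' @param cds_a,cds_b Aligned CDS strings of equal length.
#' @param code A [genetic_code()].
#' @param gene Optional gene label carried into the result.
#' @return Object of class `kaks_result`: list with `gene`, `codons_used`,
#'   `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ratio` (NA when Ks is
#'   0 or undefined), `saturated`.
#' @export
kaks_pair <- function(cds_a, cds_b, code = genetic_code(2), gene = NA_character_) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS pair must have equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("aligned CDS length must be a multiple of 3")
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% code$stop_codons) & !(cb %in% code$stop_codons)
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no analysable codons after pairwise exclusion")
  tab <- ng_site_table(code)
  Sa <- sum(tab[ca, "s"]); Sb <- sum(tab[cb, "s"])
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) {
      d <- count_differences(ca[i], cb[i], code)
      Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    }
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  saturated <- (is.na(Ks) && !is.na(ps) && ps >= 0.75) ||
    (is.na(Ka) && !is.na(pn) && pn >= 0.75)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(gene = gene, codons_used = length(ca),
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, Ks = Ks, Ka = Ka,
                 ratio = ratio, saturated = saturated),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka/Ks [%s]: %d codons, Ka=%.4f Ks=%.4f ratio=%s%s\n",
              if (is.na(x$gene)) "pair" else x$gene, x$codons_used,
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}
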