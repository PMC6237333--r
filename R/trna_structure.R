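# Architecture-constrained cloverleaf folding.
#
# A mitochondrial tRNA is modelled on the fixed layout
#   acc5 | g1 | DHU5 loop DHU3 | g2 | AC5 loop(7) AC3 | var | T5 loop T3 | acc3 | disc
# with acceptor stem 6-9 bp, DHU stem 0 or 3-4 bp (loop 4-11 when present,
# a 2-8 nt connector when absent), anticodon stem 4-6 bp with a 7 nt loop,
# T-arm stem 4-5 bp with a 3-9 nt loop, connectors g1 1-3 / g2 0-2 nt, a
# 3-23 nt variable region and a 0-4 nt discriminator tail. The fold chosen
# maximizes the number of paired positions (Watson-Crick + G.U), with ties
# broken by more acceptor pairs, fewer G.U pairs, then leftmost DHU arm.

pair_ok <- function(x, y) paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
pair_gu <- function(x, y) paste0(x, y) %in% c("GT", "TG")

# score a set of (i, j) index pairs against a character vector
stem_score <- function(chars, i, j) {
  ok <- i >= 1L & j <= length(chars) & i < j
  if (!all(ok)) return(c(paired = NA_real_, gu = NA_real_))
  p <- pair_ok(chars[i], chars[j])
  c(paired = sum(p), gu = sum(pair_gu(chars[i], chars[j]) & p))
}

# index pairs of each stem for a given parameter set
cloverleaf_pairs <- function(n, a, disc, g1, d, dl, g2, c, t, tl) {
  block <- if (d > 0L) 2L * d + dl else dl
  q <- a + g1
  p <- q + block + g2
  r <- n - disc - a
  list(
    acceptor = if (a > 0) cbind(i = seq_len(a), j = n - disc - seq_len(a) + 1L) else NULL,
    dhu = if (d > 0L) cbind(i = q + seq_len(d), j = q + 2L * d + dl + 1L - seq_len(d)) else NULL,
    anticodon = cbind(i = p + seq_len(c), j = p + 2L * c + 8L - seq_len(c)),
    tpsic = cbind(i = r - 2L * t - tl + seq_len(t), j = r - seq_len(t) + 1L),
    anticodon_pos = (p + c + 3L):(p + c + 5L)
  )
}

DHU_CASES <- rbind(
  expand.grid(d = 0L, dl = 2:8),      # connector when DHU arm absent
  expand.grid(d = 3:4, dl = 4:11)     # stem + loop when present
)

#' Fold a tRNA sequence into a constrained cloverleaf
#'
#' Exhaustive search over the cloverleaf placement grid (see source header
#' for the layout and bounds) maximizing paired positions with
#' Watson-Crick and G.U pairs. The DHU arm is reported absent when its
#' best stem pairs fewer than 3 positions, mirroring the DHU-less
#' mitochondrial serine tRNA.
#'
#' @param trna_seq DNA string, 55-95 nt.
#' @return Object of class `cloverleaf_model`: list with `acceptor_stem`,
#'   `dhu_arm` (NULL when absent), `anticodon_arm` (including the
#'   anticodon 3-mer), `tpsic_arm`, `variable`, `gaps`, `discriminator`,
#'   `gu_pairs`, `score` (total paired positions) and `pairs` (data.frame
#'   of paired index pairs).
#' @export
fold_cloverleaf <- function(trna_seq) {
  trna_seq <- check_dna(trna_seq, allow_n = FALSE, what = "tRNA")
  n <- nchar(trna_seq)
  if (n < 55L || n > 95L) stop("tRNA length outside 55-95 nt: ", n)
  chars <- seq_chars(trna_seq)

  grid <- expand.grid(a = 6:9, disc = 0:4, g1 = 1:3, g2 = 0:2,
                      c = 4:6, t = 4:5, tl = 3:9,
                      dcase = seq_len(nrow(DHU_CASES)))
  grid$d <- DHU_CASES$d[grid$dcase]
  grid$dl <- DHU_CASES$dl[grid$dcase]
  block <- ifelse(grid$d > 0L, 2L * grid$d + grid$dl, grid$dl)
  grid$v <- n - grid$disc - 2L * grid$a - grid$g1 - block - grid$g2 -
    2L * grid$c - 7L - 2L * grid$t - grid$tl
  keep <- grid$v >= 3L & grid$v <= 23L
  grid <- grid[keep, , drop = FALSE]
  block <- block[keep]
  if (nrow(grid) == 0L) stop("no feasible cloverleaf layout for length ", n)

  # memoised component scores
  score_tab <- function(keys, fn) {
    u <- unique(keys)
    vals <- vapply(u, fn, numeric(2))
    list(paired = stats::setNames(vals[1, ], u), gu = stats::setNames(vals[2, ], u))
  }
  acc_key <- paste(grid$a, grid$disc)
  acc_tab <- score_tab(acc_key, function(k) {
    kv <- as.integer(strsplit(k, " ")[[1]])
    stem_score(chars, seq_len(kv[1]), n - kv[2] - seq_len(kv[1]) + 1L)
  })
  q <- grid$a + grid$g1
  dhu_key <- paste(q, grid$d, grid$dl)
  dhu_tab <- score_tab(dhu_key, function(k) {
    kv <- as.integer(strsplit(k, " ")[[1]])
    if (kv[2] == 0L) return(c(0, 0))
    stem_score(chars, kv[1] + seq_len(kv[2]),
               kv[1] + 2L * kv[2] + kv[3] + 1L - seq_len(kv[2]))
  })
  p <- q + block + grid$g2
  ac_key <- paste(p, grid$c)
  ac_tab <- score_tab(ac_key, function(k) {
    kv <- as.integer(strsplit(k, " ")[[1]])
    stem_score(chars, kv[1] + seq_len(kv[2]),
               kv[1] + 2L * kv[2] + 8L - seq_len(kv[2]))
  })
  r <- n - grid$disc - grid$a
  t_key <- paste(r, grid$t, grid$tl)
  t_tab <- score_tab(t_key, function(k) {
    kv <- as.integer(strsplit(k, " ")[[1]])
    stem_score(chars, kv[1] - 2L * kv[2] - kv[3] + seq_len(kv[2]),
               kv[1] - seq_len(kv[2]) + 1L)
  })

  total <- acc_tab$paired[acc_key] + dhu_tab$paired[dhu_key] +
    ac_tab$paired[ac_key] + t_tab$paired[t_key]
  gu <- acc_tab$gu[acc_key] + dhu_tab$gu[dhu_key] +
    ac_tab$gu[ac_key] + t_tab$gu[t_key]
  # ties: more acceptor pairs, fewer G.U, most parsimonious stem declaration
  # (no stem wider than its paired span), leftmost DHU
  slots <- grid$a + grid$d + grid$c + grid$t
  ord <- order(-total, -acc_tab$paired[acc_key], gu, slots, q,
               seq_len(nrow(grid)))
  w <- grid[ord[1L], ]

  pr <- cloverleaf_pairs(n, w$a, w$disc, w$g1, w$d, w$dl, w$g2, w$c, w$t, w$tl)
  arm_pairs <- function(m, arm) {
    if (is.null(m)) return(NULL)
    ok <- pair_ok(chars[m[, "i"]], chars[m[, "j"]])
    if (!any(ok)) return(NULL)
    data.frame(i = m[ok, "i"], j = m[ok, "j"], arm = arm,
               gu = pair_gu(chars[m[ok, "i"]], chars[m[ok, "j"]]),
               stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, Filter(Negate(is.null), list(
    arm_pairs(pr$acceptor, "acceptor"),
    arm_pairs(pr$dhu, "dhu"),
    arm_pairs(pr$anticodon, "anticodon"),
    arm_pairs(pr$tpsic, "tpsic"))))

  npaired <- function(arm) if (is.null(pairs)) 0L else sum(pairs$arm == arm)
  ngu <- function(arm) if (is.null(pairs)) 0L else sum(pairs$gu[pairs$arm == arm])
  dhu_arm <- NULL
  if (w$d > 0L && npaired("dhu") >= 3L) {
    dhu_arm <- list(stem = w$d, loop = w$dl, paired = npaired("dhu"), gu = ngu("dhu"))
  }
  structure(list(
    acceptor_stem = list(length = w$a, paired = npaired("acceptor"), gu = ngu("acceptor")),
    dhu_arm = dhu_arm,
    anticodon_arm = list(stem = w$c, loop = 7L, paired = npaired("anticodon"),
                         gu = ngu("anticodon"),
                         anticodon = paste(chars[pr$anticodon_pos], collapse = "")),
    tpsic_arm = list(stem = w$t, loop = w$tl, paired = npaired("tpsic"), gu = ngu("tpsic")),
    variable = w$v, gaps = c(g1 = w$g1, g2 = w$g2), discriminator = w$disc,
    gu_pairs = if (is.null(pairs)) 0L else sum(pairs$gu),
    score = unname(total[ord[1L]]),
    pairs = pairs
  ), class = "cloverleaf_model")
}

#' @export
print.cloverleaf_model <- function(x, ...) {
  cat(sprintf(
    "Cloverleaf: acceptor %d bp (%d paired), DHU %s, anticodon stem %d (%s), T-arm %d/%d; %d paired, %d G.U\n",
    x$acceptor_stem$length, x$acceptor_stem$paired,
    if (is.null(x$dhu_arm)) "absent" else sprintf("%d bp", x$dhu_arm$stem),
    x$anticodon_arm$stem, x$anticodon_arm$anticodon,
    x$tpsic_arm$stem, x$tpsic_arm$loop, x$score, x$gu_pairs))
  invisible(x)
}

#' Count G.U wobble pairs in a folded tRNA
#'
#' Counts paired positions of the model whose bases are G/T (U == T on the
#' DNA alphabet).
#'
#' @param model A `cloverleaf_model` from [fold_cloverleaf()].
#' @param seq The tRNA sequence the model was fit to.
#' @return Integer count of G.U pairs.
#' @export
count_gu_pairs <- function(model, seq) {
  stopifnot(inherits(model, "cloverleaf_model"))
  chars <- seq_chars(check_dna(seq, allow_n = FALSE))
  if (is.null(model$pairs)) return(0L)
  sum(pair_gu(chars[model$pairs$i], chars[model$pairs$j]) &
        pair_ok(chars[model$pairs$i], chars[model$pairs$j]))
}
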