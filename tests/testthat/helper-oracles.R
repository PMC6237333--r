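# Independent oracles used by the tests. These deliberately share no code
# with the package implementation.

oracle_bases <- c("A", "C", "G", "T")

# synonymous/nonsynonymous site counts by direct neighbor enumeration
oracle_ng_sites <- function(codon, map, stops) {
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in oracle_bases) {
      if (b == substr(codon, p, p)) next
      nb <- codon
      substr(nb, p, p) <- b
      if (nb %in% stops) next
      valid <- valid + 1
      if (map[[nb]] == map[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# pathway-averaged differences by recursive enumeration of all step orders
oracle_ng_diffs <- function(ca, cb, map, stops) {
  recurse <- function(cur) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(dp)) return(list(c(0, 0)))
    paths <- list()
    for (p in dp) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (nxt %in% stops && nxt != cb) next
      step <- if (map[[cur]] == map[[nxt]]) c(1, 0) else c(0, 1)
      for (tail in recurse(nxt)) paths[[length(paths) + 1]] <- step + tail
    }
    paths
  }
  paths <- recurse(ca)
  if (!length(paths)) return(NULL)  # all pathways blocked
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# brute-force maximal exact tandem arrays (same reporting definition as the
# package: maximal arrays, identical spans collapsed to the smallest period)
oracle_tandem <- function(seq, min_period, max_period, min_copies) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  # every left-maximal periodic start, extended right as far as the
  # periodicity identity holds
  out <- list()
  for (p in min_period:min(max_period, n %/% 2)) {
    for (start in 1:(n - p)) {
      if (ch[start] != ch[start + p]) next
      if (start > 1 && ch[start - 1] == ch[start - 1 + p]) next
      end <- start + p
      while (end + 1 <= n && ch[end + 1] == ch[end + 1 - p]) end <- end + 1
      span <- end - start + 1
      copies <- span / p
      if (copies >= min_copies) {
        out[[length(out) + 1]] <- data.frame(start = start, period = p,
                                             copies = copies, span = span)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), period = integer(),
                                      copies = numeric(), span = integer()))
  df <- do.call(rbind, out)
  key <- paste(df$start, df$span)
  keep <- vapply(split(seq_len(nrow(df)), key),
                 function(idx) idx[which.min(df$period[idx])], integer(1))
  df <- df[sort(unname(keep)), , drop = FALSE]
  df[order(df$start, df$period), ]
}

# exhaustive constrained cloverleaf search: plain nested loops, returns the
# maximum number of paired positions over the placement grid
oracle_cloverleaf_score <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  ok <- function(x, y) {
    xy <- paste0(x, y)
    xy == "AT" || xy == "TA" || xy == "GC" || xy == "CG" ||
      xy == "GT" || xy == "TG"
  }
  stem <- function(i, j) {
    # i ascending 5' indices, j descending 3' indices
    sum(mapply(ok, ch[i], ch[j]))
  }
  best <- -1
  for (a in 6:9) for (disc in 0:4) for (g1 in 1:3) {
    acc <- stem(1:a, (n - disc):(n - disc - a + 1))
    for (dcase in 1:2) {
      drange <- if (dcase == 1) 0 else 3:4
      for (d in drange) {
        dls <- if (d == 0) 2:8 else 4:11
        for (dl in dls) {
          q <- a + g1
          dhu <- if (d == 0) 0 else stem(q + 1:d, (q + 2 * d + dl):(q + d + dl + 1))
          blk <- if (d == 0) dl else 2 * d + dl
          for (g2 in 0:2) for (cc in 4:6) {
            p <- q + blk + g2
            if (p + 2 * cc + 7 > n) next
            acarm <- stem(p + 1:cc, (p + 2 * cc + 7):(p + cc + 8))
            for (tt in 4:5) for (tl in 3:9) {
              v <- n - disc - 2 * a - g1 - blk - g2 - 2 * cc - 7 - 2 * tt - tl
              if (v < 3 || v > 23) next
              r <- n - disc - a
              tarm <- stem((r - 2 * tt - tl + 1):(r - tt - tl), r:(r - tt + 1))
              tot <- acc + dhu + acarm + tarm
              if (tot > best) best <- tot
            }
          }
        }
      }
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared synthetic mitogenome fixture (built once per test run)
.sim_env <- new.env()
get_sim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.sim_env[[key]])) {
    .sim_env[[key]] <- generate_mitogenome(simulation_config(seed = seed))
  }
  .sim_env[[key]]
}
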