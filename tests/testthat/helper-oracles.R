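# Independent brute-force oracles. These re-derive expected values from
# first principles (plain loops, exhaustive enumeration, stats::dhyper) and
# deliberately share no code with the implementation they check.

# ---- hypergeometric upper tail by direct enumeration -------------------
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- stats::dhyper(ks, K, N - K, n)
  sum(probs[ks >= k])
}

# ---- exact Mann-Whitney p by permuting the raw data --------------------
# Statistic: U = #{(i,j): x_i > y_j} + 0.5 #{x_i == y_j}; enumerate every
# assignment of the pooled values to the two groups.
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y); nx <- length(x)
  U_of <- function(xs, ys) {
    u <- 0
    for (a in xs) for (b in ys) u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  U <- U_of(x, y)
  idx <- utils::combn(length(pool), nx)
  Us <- apply(idx, 2, function(ii) U_of(pool[ii], pool[-ii]))
  eps <- 1e-9
  p_less <- mean(Us <= U + eps)
  p_greater <- mean(Us >= U - eps)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# ---- brute-force splice-event oracle -----------------------------------
# Plain interval algebra over two exon chains (matrices with columns
# start/end, sorted), returning sorted "TYPE coords" strings.
oracle_events <- function(ex_a, ex_b, strand) {
  juncs <- function(ex) {
    if (nrow(ex) < 2) return(character())
    sprintf("%d>%d", ex[-nrow(ex), 2], ex[-1, 1])
  }
  ja <- juncs(ex_a); jb <- juncs(ex_b)
  ka <- sprintf("%d-%d", ex_a[, 1], ex_a[, 2])
  kb <- sprintf("%d-%d", ex_b[, 1], ex_b[, 2])
  out <- character()
  add <- function(type, coords) out <<- c(out, paste(type, coords))

  se <- function(exi, jo, keys_o) {
    n <- nrow(exi)
    if (n >= 3) for (i in 2:(n - 1)) {
      if (sprintf("%d>%d", exi[i - 1, 2], exi[i + 1, 1]) %in% jo &&
          !(sprintf("%d-%d", exi[i, 1], exi[i, 2]) %in% keys_o))
        add("SE", sprintf("%d-%d", exi[i, 1], exi[i, 2]))
    }
  }
  se(ex_a, jb, kb); se(ex_b, ja, ka)

  ri <- function(exi, exo) {
    if (nrow(exo) >= 2) for (i in seq_len(nrow(exi))) {
      for (k in seq_len(nrow(exo) - 1)) {
        if (exo[k, 1] == exi[i, 1] && exo[k + 1, 2] == exi[i, 2] &&
            exi[i, 1] < exo[k, 2] && exo[k + 1, 1] < exi[i, 2])
          add("RI", sprintf("%d-%d", exo[k, 2], exo[k + 1, 1]))
      }
    }
  }
  ri(ex_a, ex_b); ri(ex_b, ex_a)

  pa <- do.call(rbind, lapply(strsplit(ja, ">"), as.integer))
  pb <- do.call(rbind, lapply(strsplit(jb, ">"), as.integer))
  if (length(ja) && length(jb)) {
    for (i in seq_len(nrow(pa))) for (k in seq_len(nrow(pb))) {
      d1 <- pa[i, 1]; a1 <- pa[i, 2]; d2 <- pb[k, 1]; a2 <- pb[k, 2]
      if (a1 == a2 && d1 != d2) {
        sa <- ex_a[ex_a[, 2] == d1, 1][1]; sb <- ex_b[ex_b[, 2] == d2, 1][1]
        if (max(sa, sb) < min(d1, d2))
          add(if (strand == "+") "A5SS" else "A3SS",
              sprintf("%d-%d", min(d1, d2), max(d1, d2)))
      }
      if (d1 == d2 && a1 != a2) {
        ea <- ex_a[ex_a[, 1] == a1, 2][1]; eb <- ex_b[ex_b[, 1] == a2, 2][1]
        if (max(a1, a2) < min(ea, eb))
          add(if (strand == "+") "A3SS" else "A5SS",
              sprintf("%d-%d", min(a1, a2), max(a1, a2)))
      }
    }
  }

  na <- nrow(ex_a); nb <- nrow(ex_b)
  if (na >= 3 && nb >= 3) for (i in 2:(na - 1)) for (k in 2:(nb - 1)) {
    ea <- ex_a[i, ]; eb <- ex_b[k, ]
    disjoint <- ea[2] <= eb[1] || eb[2] <= ea[1]
    if (!disjoint) next
    if (sprintf("%d-%d", ea[1], ea[2]) %in% kb) next
    if (sprintf("%d-%d", eb[1], eb[2]) %in% ka) next
    if (ex_a[i - 1, 2] == ex_b[k - 1, 2] && ex_a[i + 1, 1] == ex_b[k + 1, 1]) {
      lo <- if (ea[1] < eb[1]) ea else eb
      hi <- if (ea[1] < eb[1]) eb else ea
      add("MXE", sprintf("%d-%d|%d-%d", lo[1], lo[2], hi[1], hi[2]))
    }
  }

  if (na >= 2 && nb >= 2) {
    fa <- ex_a[1, ]; fb <- ex_b[1, ]
    if (!all(fa == fb) && ex_a[2, 1] == ex_b[2, 1] &&
        (fa[2] <= fb[1] || fb[2] <= fa[1])) {
      lo <- if (fa[1] < fb[1]) fa else fb
      hi <- if (fa[1] < fb[1]) fb else fa
      add(if (strand == "+") "AFE" else "ALE",
          sprintf("%d-%d|%d-%d", lo[1], lo[2], hi[1], hi[2]))
    }
    la <- ex_a[na, ]; lb <- ex_b[nb, ]
    if (!all(la == lb) && ex_a[na - 1, 2] == ex_b[nb - 1, 2] &&
        (la[2] <= lb[1] || lb[2] <= la[1])) {
      lo <- if (la[1] < lb[1]) la else lb
      hi <- if (la[1] < lb[1]) lb else la
      add(if (strand == "+") "ALE" else "AFE",
          sprintf("%d-%d|%d-%d", lo[1], lo[2], hi[1], hi[2]))
    }
  }
  sort(unique(out))
}

# Event list of a classify_pair result as sorted "TYPE coords" strings.
event_keys <- function(ev) sort(unique(paste(ev$event_type, ev$coords)))
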