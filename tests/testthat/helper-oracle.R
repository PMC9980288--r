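# Independent oracles: written against the definitions, not the package's
# code paths (enumeration, cumulative sums, step-up arithmetic).

# One-sided ("greater") Fisher p by exhaustive enumeration over all tables
# with the observed margins.
oracle_fisher_greater <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  lo <- max(0L, col1 - (n - row1))
  hi <- min(row1, col1)
  xs <- lo:hi
  pr <- choose(col1, xs) * choose(n - col1, row1 - xs) / choose(n, row1)
  sum(pr[xs >= a])
}

# Definitional BH step-up: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Brute-force motif count: scan every position of the window.
oracle_count_motifs <- function(w) {
  v <- strsplit(w, "")[[1L]]
  n <- length(v)
  tcw <- 0L
  for (i in seq_len(n)) {
    if (i >= 2L && i <= n - 1L && v[i] == "C" && v[i - 1L] == "T" &&
        v[i + 1L] %in% c("A", "T"))
      tcw <- tcw + 1L
  }
  c(tcw = tcw, c = sum(v == "C"))
}

# Exact site-enumeration expectation of the enrichment score for a sample of
# n substitutions with planted TCW fraction `frac` (background uniform over
# all sites, alternate uniform over the three non-reference bases).
# Independent route: per-position indicator vectors and cumulative sums.
oracle_expected_score <- function(genome, n, frac, half_width = 20L) {
  tot <- list(n_cg = 0, n_tcw = 0, n_pos = 0,
              conc_tcwsites = 0, contcw_tcwsites = 0,
              conc_cgsites = 0, contcw_cgsites = 0)
  for (s in unclass(genome)) {
    v <- strsplit(s, "")[[1L]]
    L <- length(v)
    isC <- v == "C"; isG <- v == "G"
    prev <- c(NA, v[-L]); nxt <- c(v[-1L], NA)
    tcwC <- !is.na(prev) & !is.na(nxt) & isC & prev == "T" & nxt %in% c("A", "T")
    tcwG <- !is.na(prev) & !is.na(nxt) & isG & nxt == "A" & prev %in% c("T", "A")
    cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
    cumTC <- c(0, cumsum(tcwC)); cumTG <- c(0, cumsum(tcwG))
    p <- seq_len(L)
    lo <- pmax(1L, p - half_width); hi <- pmin(L, p + half_width)
    # motif centers need both neighbours inside the window
    mlo <- lo + 1L; mhi <- hi - 1L
    win_c <- ifelse(isC, cumC[hi + 1L] - cumC[lo], cumG[hi + 1L] - cumG[lo])
    win_tcw <- ifelse(isC, cumTC[mhi + 1L] - cumTC[mlo],
                      cumTG[mhi + 1L] - cumTG[mlo])
    cg <- isC | isG
    tcw <- tcwC | tcwG
    tot$n_pos <- tot$n_pos + L
    tot$n_cg <- tot$n_cg + sum(cg)
    tot$n_tcw <- tot$n_tcw + sum(tcw)
    tot$conc_tcwsites <- tot$conc_tcwsites + sum(win_c[tcw])
    tot$contcw_tcwsites <- tot$contcw_tcwsites + sum(win_tcw[tcw])
    tot$conc_cgsites <- tot$conc_cgsites + sum(win_c[cg])
    tot$contcw_cgsites <- tot$contcw_cgsites + sum(win_tcw[cg])
  }
  n_apo <- round(n * frac)
  n_bg <- n - n_apo
  p_keep_bg <- (2 / 3) * tot$n_cg / tot$n_pos          # C:G site, not C>A
  e_mut_c <- n_apo + n_bg * p_keep_bg
  e_mut_tcw <- n_apo + n_bg * (2 / 3) * tot$n_tcw / tot$n_pos
  e_con_c <- n_apo * tot$conc_tcwsites / tot$n_tcw +
    n_bg * (2 / 3) * tot$conc_cgsites / tot$n_pos
  e_con_tcw <- n_apo * tot$contcw_tcwsites / tot$n_tcw +
    n_bg * (2 / 3) * tot$contcw_cgsites / tot$n_pos
  (e_mut_tcw / e_con_tcw) / (e_mut_c / e_con_c)
}
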