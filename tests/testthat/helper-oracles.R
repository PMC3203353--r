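# Independent oracles the implementation is checked against. These follow
# the definitions literally (sliding windows, exhaustive enumeration,
# per-record lookup) and never share code with the package internals.

# Literal 1 bp sliding-window CIS oracle: every window [w, w + width) is
# examined; qualifying windows contribute the interval spanned by their
# member VIS; overlapping/touching intervals are unioned.
oracle_cis <- function(vis, rules) {
  out <- NULL
  for (ch in unique(vis$chrom)) {
    p <- sort(vis$pos[vis$chrom == ch])
    iv_s <- numeric(0); iv_e <- numeric(0)
    for (r in seq_len(nrow(rules))) {
      width <- rules$window[r]; y <- rules$min_count[r]
      for (w in seq(max(1, min(p) - width), max(p))) {
        inside <- p[p >= w & p < w + width]
        if (length(inside) >= y) {
          iv_s <- c(iv_s, min(inside)); iv_e <- c(iv_e, max(inside))
        }
      }
    }
    if (length(iv_s) == 0) next
    ord <- order(iv_s, iv_e)
    iv_s <- iv_s[ord]; iv_e <- iv_e[ord]
    ms <- iv_s[1]; me <- iv_e[1]
    for (k in seq_along(iv_s)[-1]) {
      if (iv_s[k] <= me[length(me)]) {
        me[length(me)] <- max(me[length(me)], iv_e[k])
      } else { ms <- c(ms, iv_s[k]); me <- c(me, iv_e[k]) }
    }
    out <- rbind(out, data.frame(chrom = ch, start = ms, end = me))
  }
  out
}

# Exhaustive two-sided Fisher oracle: enumerate every table with the
# observed margins and sum the point probabilities <= the observed one.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- function(k) lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)
  lp <- vapply(ks, logp, 0)
  obs <- logp(a)
  sum(exp(lp[lp <= obs + 1e-7]))
}

# Per-record linear-search bin assignment oracle.
oracle_bin_counts <- function(vis, partition) {
  counts <- integer(nrow(partition))
  for (r in seq_len(nrow(vis))) {
    for (k in seq_len(nrow(partition))) {
      if (partition$chrom[k] == vis$chrom[r] &&
          vis$pos[r] > partition$start[k] && vis$pos[r] <= partition$end[k]) {
        counts[k] <- counts[k] + 1L
        break
      }
    }
  }
  counts
}

# Exact change-point posterior by enumeration of all 2^(n-1) partitions of
# the product-partition Gaussian model, with the prior integrals evaluated
# by stats::integrate (not the closed incomplete-beta forms the sampler
# uses). Returns exact change probabilities and the exact value of the
# shrunken-block-mean functional the sampler averages.
oracle_bcp <- function(x, p0 = 0.2, w0 = 0.2) {
  n <- length(x)
  stopifnot(n <= 16)
  xbar <- mean(x)
  iw <- function(a, W, B) {
    integrate(function(w) exp(a * log(w) - ((n - 1) / 2) * log(W + B * w)),
              lower = 0, upper = w0, rel.tol = 1e-10)$value
  }
  ip <- function(b) {
    integrate(function(p) p^(b - 1) * (1 - p)^(n - b),
              lower = 0, upper = p0, rel.tol = 1e-12)$value
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n - 1))
  wgt <- numeric(nrow(combos))
  mu_fun <- matrix(0, nrow(combos), n)
  cp_mat <- as.matrix(combos)
  for (r in seq_len(nrow(combos))) {
    cuts <- c(0, which(cp_mat[r, ]), n)
    b <- length(cuts) - 1
    W <- 0; B <- 0
    bm <- numeric(n)
    for (j in seq_len(b)) {
      seg <- x[(cuts[j] + 1):cuts[j + 1]]
      W <- W + sum((seg - mean(seg))^2)
      B <- B + length(seg) * (mean(seg) - xbar)^2
      bm[(cuts[j] + 1):cuts[j + 1]] <- mean(seg)
    }
    num <- iw((b - 1) / 2, W, B)
    wgt[r] <- ip(b) * num
    what <- iw((b + 1) / 2, W, B) / num # E[w | partition]
    mu_fun[r, ] <- xbar + (1 - what) * (bm - xbar)
  }
  wgt <- wgt / sum(wgt)
  list(change_prob = colSums(cp_mat * wgt),
       post_mean = colSums(mu_fun * wgt))
}
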