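# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Hyndman-Fan type-7 percentile evaluated from its defining formula.
quantile7_hand <- function(values, q) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exact lower binomial tail by term-wise enumeration (null prob 1/2).
binom_tail_enum <- function(k, n) {
  sum(vapply(0:k, function(i) choose(n, i), numeric(1))) / 2^n
}

# Pearson correlation from the covariance/SD definition.
pearson_hand <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * stats::sd(x) * stats::sd(y))
}

# Benjamini-Hochberg step-up from the definition:
# adj_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j, capped at 1.
bh_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ranked[i:m] / seq.int(i, m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive UPGMA: at every step recompute all average inter-cluster
# distances from the raw distance matrix (no Lance-Williams update), with
# the same smallest-original-index tie-break.
upgma_bruteforce <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dv <- mean(D[clusters[[i]], clusters[[j]]])
        rep_ab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || dv < best$d ||
          (dv == best$d && (rep_ab[1] < best$rep[1] ||
                            (rep_ab[1] == best$rep[1] && rep_ab[2] < best$rep[2])))
        if (better) best <- list(i = i, j = j, d = dv, rep = rep_ab)
      }
    }
    heights[s] <- best$d
    merges[[s]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Member sets of each internal node of an hclust object, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get1 <- function(nd) if (nd < 0) -nd else sets[[nd]]
    sets[[s]] <- sort(c(get1(hc$merge[s, 1]), get1(hc$merge[s, 2])))
  }
  sets
}

# Small deterministic counts matrix for normalization tests.
toy_counts <- function(seed = 1, G = 60, S = 6, size = 8) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mu <- stats::rlnorm(G, 3.5, 1)
    lib <- stats::runif(S, 0.6, 1.8)
    m <- sapply(lib, function(l) stats::rnbinom(G, size = size, mu = mu * l))
    storage.mode(m) <- "integer"
    rownames(m) <- sprintf("g%03d", seq_len(G))
    colnames(m) <- sprintf("s%02d", seq_len(S))
    m
  })
}
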