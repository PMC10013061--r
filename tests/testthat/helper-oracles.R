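# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations: brute force, enumeration, or textbook
# formulas written without reference to the package code paths.

# Floyd-Warshall all-pairs shortest paths on a weighted undirected graph.
# nodes: character vector; edges: data.frame(from, to, weight)
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]
    b <- edges$to[i]
    w <- edges$weight[i]
    d[a, b] <- min(d[a, b], w)
    d[b, a] <- min(d[b, a], w)
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# topology indices from first principles via Floyd-Warshall
topology_oracle <- function(nodes, edges) {
  deg <- sapply(nodes, function(v) {
    sum(edges$weight[edges$from == v]) + sum(edges$weight[edges$to == v])
  })
  d <- fw_distances(nodes, edges)
  ut <- d[upper.tri(d)]
  fin <- ut[is.finite(ut)]
  list(degree = deg,
       mean_centrality = mean(deg),
       sd_centrality = if (length(nodes) > 1) sd(deg) else 0,
       char_path_length = if (length(fin)) mean(fin) else 0,
       diameter = if (length(fin)) max(fin) else 0,
       global_efficiency = if (length(ut)) {
         mean(ifelse(is.finite(ut), 1 / ut, 0))
       } else 0)
}

# orthogonal deviation from the two residual legs (the method's original
# formulation):
# v = vertical residual, h = v/|b| horizontal residual, delta = v*h/sqrt(v^2+h^2)
delta_leg_product <- function(x0, y0, slope, intercept) {
  v <- abs(y0 - (intercept + slope * x0))
  if (slope == 0) return(v)       # stated limit for horizontal lines
  if (v == 0) return(0)           # point on the line
  h <- v / abs(slope)
  v * h / sqrt(v^2 + h^2)
}

# AUC by exhaustive pair counting: concordant pairs + half ties
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p-value by enumerating group assignments
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  mu <- n1 * length(y) / 2
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Efron-approximation Cox log partial likelihood for a single covariate
efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(event == 1 & time == t)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_d <- sum(exp(eta[d_idx]))
    sum_r <- sum(exp(eta[r_idx]))
    ll <- ll + sum(eta[d_idx]) -
      sum(log(sum_r - (seq_len(d) - 1) / d * sum_d))
  }
  ll
}

# log-rank (Mantel-Cox) chi-square from hand-tabulated risk sets
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1
  u <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    u <- u + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  u^2 / v
}

# Spearman rho as Pearson correlation of midranks
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
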