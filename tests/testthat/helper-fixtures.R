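# Shared fixtures and independent oracles, built in code.

toy_table <- function(values, scale = "counts", otus = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- otus %||% paste0("OTU_", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  sample_table(m, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# correlated lognormal pair via the same copula construction the
# generator uses (independent code path: plain R, no package calls)
coupled_rows <- function(n, rho) {
  w <- rnorm(n)
  x <- qlnorm(pnorm(sqrt(rho) * w + sqrt(1 - rho) * rnorm(n)))
  y <- qlnorm(pnorm(sqrt(rho) * w + sqrt(1 - rho) * rnorm(n)))
  rbind(x, y)
}

# --- independent R oracles -------------------------------------------

# symmetrized KL on Laplace-smoothed profiles
oracle_kl <- function(x, y) {
  n <- length(x)
  p <- (x + 1) / (sum(x) + n)
  q <- (y + 1) / (sum(y) + n)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

# equal-frequency bin labels, ties broken by original index
oracle_bins <- function(x, B) {
  ord <- order(x, seq_along(x))
  bin <- integer(length(x))
  bin[ord] <- pmin(floor((seq_along(x) - 1) * B / length(x)), B - 1)
  bin
}

oracle_mi <- function(x, y) {
  n <- length(x)
  B <- max(2, floor(sqrt(n)))
  bx <- oracle_bins(x, B)
  by <- oracle_bins(y, B)
  tab <- table(factor(bx, 0:(B - 1)), factor(by, 0:(B - 1))) / n
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (a in seq_len(B)) for (b in seq_len(B))
    if (tab[a, b] > 0)
      mi <- mi + tab[a, b] * log(tab[a, b] / (px[a] * py[b]))
  unname(mi)
}

# brute-force Benjamini-Hochberg step-up straight from the definition:
# q_i = min over {j : p_(j) >= p_(i)} of min(1, p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  vapply(seq_len(m), function(i) {
    js <- which(ps >= p[i])
    min(1, min(ps[js] * m / js))
  }, 0)
}

# all-pairs shortest-path centralities by Floyd-Warshall plus
# shortest-path counting (independent of igraph)
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # sigma[s, v]: number of shortest s-v paths
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      pred <- which(adj[, v] > 0 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- acc / ((n - 1) * (n - 2) / 2)
  }
  cls <- vapply(1:n, function(v) {
    r <- setdiff(which(is.finite(d[v, ])), v)
    if (length(r) == 0) 0 else length(r) / sum(d[v, r])
  }, 0)
  list(betweenness = btw, closeness = cls)
}
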