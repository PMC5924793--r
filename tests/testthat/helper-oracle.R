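# Brute-force tricube-weighted local polynomial oracle, written directly
# from the definition and kept independent of the package's prediction
# engine: for each query point, take the ceil(span*n) nearest points
# (clamped to degree+2, ties at the cutoff included), tricube-weight them,
# and solve the weighted normal equations of a polynomial centered at the
# query point.
loess_oracle <- function(x, y, xnew, span = 0.75, degree = 2) {
  n <- length(x)
  k <- min(max(ceiling(span * n), degree + 2L), n)
  vapply(xnew, function(q) {
    if (q < min(x) || q > max(x)) return(NA_real_)
    d <- abs(x - q)
    dk <- sort(d)[k]
    sel <- which(d <= dk)
    if (dk == 0) return(mean(y[sel]))
    w <- (1 - (d[sel] / dk)^3)^3
    if (all(w == 0)) w <- rep(1, length(sel))
    X <- outer(x[sel] - q, 0:degree, `^`)
    beta <- solve(t(X * w) %*% X, t(X * w) %*% y[sel])
    beta[1]
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# of the pooled ranks (no ties assumed).
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_stat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_stat)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# small long_table fixture: two groups, three subjects each, y separated
make_two_group_table <- function(n_per_group = 3, n_time = 6,
                                 offset = 0, seed = 100) {
  set.seed(seed)
  rows <- list()
  for (g in c("g1", "g2")) {
    for (i in seq_len(n_per_group)) {
      x <- seq(0, 1, length.out = n_time)
      y <- rnorm(n_time, mean = if (g == "g2") offset else 0, sd = 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        subject = paste0(g, "_", i), x = x, y = y, grp = g)
    }
  }
  as_long_table(do.call(rbind, rows), "subject", "x", "y", "grp")
}
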