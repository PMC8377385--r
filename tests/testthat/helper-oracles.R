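# Independent oracles, kept deliberately naive: per-sample scalar loops,
# brute-force pair enumeration, direct formulas. They never call the code
# paths they check.

# Edge transform, one scalar at a time, straight from the defining formula.
oracle_edge_loop <- function(values, class, kinase, substrate) {
  lv <- sort(unique(as.character(class)))
  out <- matrix(NA_real_, length(kinase), ncol(values))
  rownames(out) <- paste(kinase, substrate, sep = "-")
  colnames(out) <- colnames(values)
  for (e in seq_along(kinase)) {
    for (j in seq_len(ncol(values))) {
      k <- as.character(class)[j]
      idx <- which(as.character(class) == k)
      xu <- values[kinase[e], idx]
      xv <- values[substrate[e], idx]
      mu_u <- sum(xu) / length(xu)
      mu_v <- sum(xv) / length(xv)
      sd_u <- sqrt(sum((xu - mu_u)^2) / length(xu))
      sd_v <- sqrt(sum((xv - mu_v)^2) / length(xv))
      zu <- (values[kinase[e], j] - mu_u) / sd_u
      zv <- (values[substrate[e], j] - mu_v) / sd_v
      out[e, j] <- zu * zv
    }
  }
  out
}

# Uncorrected-sigma within-class Pearson correlation (equals cor()).
oracle_class_cor <- function(values, class, kinase, substrate, k) {
  idx <- as.character(class) == k
  stats::cor(values[kinase, idx], values[substrate, idx])
}

# AUC by brute force over all positive-negative pairs, ties = 1/2.
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Harrell's C by enumeration: comparable iff earlier time is an event.
oracle_cindex_pairs <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj) next
    first <- if (ti < tj) i else j
    later <- if (ti < tj) j else i
    if (event[first] != 1) next
    den <- den + 1
    if (risk[first] > risk[later]) num <- num + 1
    else if (risk[first] == risk[later]) num <- num + 0.5
  }
  num / den
}

# Cox partial log-likelihood for a single covariate, no ties assumed.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk_set <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk_set])))
  }
  ll
}

# Two-group log-rank chi-squared from the observed-vs-expected formula.
oracle_logrank_chisq <- function(group, time, event) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Small disjoint kinase-substrate network.
toy_network <- function(n_pairs = 5) {
  ks_network(sprintf("K%02d", seq_len(n_pairs)),
             sprintf("S%02d", seq_len(n_pairs)))
}

# Random two-class expression instance for property tests.
random_ks_expr <- function(n_genes, n_per_class, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    n <- 2 * n_per_class
    m <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    ks_expr(m, rep(c("A", "B"), each = n_per_class))
  })
}
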