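# Independent oracles used to validate the package's computations. These
# deliberately re-derive quantities by a different route than the
# implementation (exact integer binomial coefficients, quadratic DP,
# exhaustive enumeration) and must stay that way.

# Exact term-by-term negative log-likelihood: log C(n,r) via exact integer
# binomial coefficients (choose() is exact below 2^53; C(40,20) ~ 1.4e11),
# plus r*log(p) + (n-r)*log1p(-p), with the same frequency clamp.
oracle_nll <- function(colony, panel, admixture, eps_p = 1e-6) {
  keep <- which(!colony$missing)
  total <- 0
  for (j in keep) {
    p <- sum(admixture * panel$freqs[, j])
    p <- min(max(p, eps_p), 1 - eps_p)
    r <- colony$counts[[j]]
    n <- colony$n_alleles
    total <- total - (log(choose(n, r)) + r * log(p) + (n - r) * log1p(-p))
  }
  total
}

# Quadratic dynamic-programming edit distance in plain R, same cost model
# (unit substitutions/indels, N matches anything free).
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (a[i] == b[j] || a[i] == "N" || b[j] == "N") 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j] + sub, d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[n + 1L, m + 1L]
}

# Minimum spanning-forest weight by exhaustive enumeration of edge subsets,
# feasible for <= 7 nodes. D is the full distance matrix; edges above
# max_steps are unusable.
oracle_min_spanning_weight <- function(D, max_steps) {
  n <- nrow(D)
  pairs <- which(upper.tri(D) & D <= max_steps, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  # components of the usable graph (DFS)
  adj <- lapply(seq_len(n), function(i) {
    c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])
  })
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      stack <- c(stack, adj[[v]])
    }
  }
  total <- 0
  for (k in seq_len(cid)) {
    nodes <- which(comp == k)
    if (length(nodes) < 2L) next
    e <- pairs[pairs[, 1] %in% nodes & pairs[, 2] %in% nodes, , drop = FALSE]
    w <- D[e]
    need <- length(nodes) - 1L
    best <- Inf
    for (subset in utils::combn(nrow(e), need, simplify = FALSE)) {
      # spanning check: union-find over chosen edges
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      ok <- TRUE
      for (idx in subset) {
        ra <- find(e[idx, 1]); rb <- find(e[idx, 2])
        if (ra == rb) { ok <- FALSE; break }
        parent[ra] <- rb
      }
      if (ok) best <- min(best, sum(w[subset]))
    }
    stopifnot(is.finite(best))
    total <- total + best
  }
  total
}

# E[max pairwise |difference|] of three iid Beta(a, b) variables = E[range]
# of three order statistics, by numerical integration.
oracle_beta_range_expectation <- function(a, b) {
  emax <- stats::integrate(function(x) 3 * x * stats::pbeta(x, a, b)^2 *
                             stats::dbeta(x, a, b), 0, 1)$value
  emin <- stats::integrate(function(x) 3 * x * (1 - stats::pbeta(x, a, b))^2 *
                             stats::dbeta(x, a, b), 0, 1)$value
  emax - emin
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
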