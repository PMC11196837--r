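#' Options for the admixture optimizer
#'
#' @param n_starts total optimization starts: the three simplex corners, the
#'   barycenter, and `n_starts - 4` seeded random points (default 8).
#' @param seed seed for the random starts.
#' @param gradtol convergence tolerance on the objective gradient (default 1e-8).
#' @param iterlim maximum iterations per start (default 500).
#' @param flat_tol likelihood-spread tolerance below which a fit is flagged
#'   non-identifiable (default 1e-6).
#' @param eps_p clamp applied to mixture frequencies so the log-likelihood
#'   stays finite at fixed loci (default 1e-6).
#' @return A list of class `admix_options`.
#' @export
admix_options <- function(n_starts = 8L, seed = 1L, gradtol = 1e-8,
                          iterlim = 500L, flat_tol = 1e-6, eps_p = 1e-6) {
  if (n_starts < 4L) stop("n_starts must be at least 4", call. = FALSE)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 gradtol = gradtol, iterlim = as.integer(iterlim),
                 flat_tol = flat_tol, eps_p = eps_p),
            class = "admix_options")
}

#' Admixture mixture frequency at one SNP
#'
#' The classical admixture relation: the expected reference-allele frequency
#' in a colony with ancestry proportions (A, M, C) is the ancestry-weighted
#' mean of the lineage frequencies, `A*pA_j + M*pM_j + C*pC_j`, clamped to
#' `[eps_p, 1 - eps_p]` so downstream log-likelihoods stay finite.
#'
#' @param panel a [lineage_panel()].
#' @param admixture length-3 (A, M, C) on the simplex.
#' @param snp_index SNP column index (or vector of indices; default all SNPs).
#' @param eps_p clamping constant (default 1e-6).
#' @return Mixture frequency (vector over `snp_index`).
#' @export
mixture_freq <- function(panel, admixture, snp_index = seq_along(panel$snp_ids),
                         eps_p = 1e-6) {
  assert_simplex(admixture)
  p <- as.vector(admixture %*% panel$freqs[, snp_index, drop = FALSE])
  clamp(p, eps_p, 1 - eps_p)
}

#' Binomial log-probability
#'
#' `log[C(n, r) p^r (1 - p)^(n - r)]`, evaluated in log space.
#'
#' @param r successes, `0 <= r <= n`.
#' @param n trials.
#' @param p success probability in (0, 1).
#' @return Log-probability (vectorized).
#' @export
binomial_log_prob <- function(r, n, p) {
  dbinom(r, n, p, log = TRUE)
}

#' Negative log-likelihood of an admixture vector for one colony
#'
#' The pooled count at each SNP is modelled as
#' `r_j ~ Binomial(n_alleles, p_j)` with `p_j` the admixture mixture
#' frequency; SNPs are multiplied as independent, so the negative
#' log-likelihood is minus the sum of binomial log-probabilities over the
#' colony's non-missing SNPs (missing SNPs contribute zero).
#'
#' @param colony a [colony_observation()] aligned to `panel`.
#' @param panel a [lineage_panel()].
#' @param admixture length-3 (A, M, C) on the simplex.
#' @param eps_p mixture-frequency clamp (default 1e-6).
#' @return The negative log-likelihood (finite whenever at least one SNP is
#'   observed).
#' @export
neg_log_likelihood <- function(colony, panel, admixture, eps_p = 1e-6) {
  keep <- !colony$missing
  if (!any(keep)) stop("colony has no non-missing SNPs", call. = FALSE)
  p <- mixture_freq(panel, admixture, which(keep), eps_p = eps_p)
  -sum(binomial_log_prob(colony$counts[keep], colony$n_alleles, p))
}

# nll over a matrix of admixture vectors (rows), vectorized over lattice x SNP
nll_matrix <- function(colony, panel, amc_matrix, eps_p = 1e-6) {
  keep <- !colony$missing
  r <- colony$counts[keep]
  P <- clamp(amc_matrix %*% panel$freqs[, keep, drop = FALSE], eps_p, 1 - eps_p)
  ll <- matrix(dbinom(rep(r, each = nrow(P)), colony$n_alleles, as.vector(P),
                      log = TRUE), nrow = nrow(P))
  -rowSums(ll)
}

softmax3 <- function(t) {
  z <- exp(c(t, 0) - max(c(t, 0)))
  z / sum(z)
}

#' Maximum-likelihood admixture estimate for one colony
#'
#' Minimizes [neg_log_likelihood()] over the simplex. The simplex constraint
#' is handled by a softmax reparameterization over three logits (the third
#' pinned to 0 for identifiability) optimized unconstrained with
#' [stats::nlm()], with multi-start: the three simplex corners, the
#' barycenter, and seeded random starts. A fit is flagged non-identifiable
#' (`flat_likelihood_flag`) when both the spread of the multi-start optima
#' and the spread of the likelihood across the three simplex corners fall
#' below `flat_tol`.
#'
#' @param colony a [colony_observation()] with at least one informative
#'   non-missing SNP.
#' @param panel a [lineage_panel()].
#' @param options an [admix_options()].
#' @return A list of class `admixture_estimate`: `colony_id`, `A`, `M`, `C`,
#'   `neg_log_likelihood`, `converged`, `n_starts_used`,
#'   `flat_likelihood_flag`.
#' @export
estimate_admixture <- function(colony, panel, options = admix_options()) {
  obj <- function(t) neg_log_likelihood(colony, panel, softmax3(t),
                                        eps_p = options$eps_p)
  corners <- diag(3)
  corner_nll <- nll_matrix(colony, panel, corners, eps_p = options$eps_p)
  # moderate corner logits: softmax((4,0,-...)) ~ 0.96 at the corner but with
  # usable gradients, unlike near-infinite logits
  starts <- list(c(4, 0), c(0, 4), c(-4, -4), c(0, 0))
  n_random <- options$n_starts - 4L
  if (n_random > 0L) {
    rand <- with_seed(options$seed,
                      matrix(rnorm(2L * n_random, sd = 2), ncol = 2L))
    starts <- c(starts, lapply(seq_len(n_random), function(i) rand[i, ]))
  }
  minima <- numeric(length(starts))
  best <- NULL
  any_converged <- FALSE
  for (i in seq_along(starts)) {
    fit <- suppressWarnings(nlm(obj, starts[[i]], gradtol = options$gradtol,
                                iterlim = options$iterlim))
    minima[i] <- fit$minimum
    if (fit$code <= 2L) any_converged <- TRUE
    if (is.null(best) || fit$minimum < best$minimum) best <- fit
  }
  est <- softmax3(best$estimate)
  flat <- (max(minima) - min(minima) < options$flat_tol) &&
    (max(corner_nll) - min(corner_nll) < options$flat_tol)
  structure(list(colony_id = colony$colony_id,
                 A = est[1], M = est[2], C = est[3],
                 neg_log_likelihood = best$minimum,
                 converged = any_converged,
                 n_starts_used = length(starts),
                 flat_likelihood_flag = flat),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat(sprintf("<admixture_estimate> %s: A=%.3f M=%.3f C=%.3f (nll=%.2f%s%s)\n",
              x$colony_id, x$A, x$M, x$C, x$neg_log_likelihood,
              if (x$converged) "" else ", NOT converged",
              if (x$flat_likelihood_flag) ", FLAT likelihood" else ""))
  invisible(x)
}

#' Exhaustive simplex grid oracle for the likelihood minimum
#'
#' Evaluates the negative log-likelihood on the lattice
#' `{(a, m, 1 - a - m) : a, m >= 0, a + m <= 1, multiples of step}` and
#' returns the best point. Ties are broken toward the lexicographically
#' smallest (A, M). Used as an independent check on the smooth optimizer.
#'
#' @param colony a [colony_observation()].
#' @param panel a [lineage_panel()].
#' @param step lattice step in (0, 0.1].
#' @param eps_p mixture-frequency clamp.
#' @return A list: `admixture` (named A/M/C), `value`, `n_points`.
#' @export
grid_oracle <- function(colony, panel, step = 0.01, eps_p = 1e-6) {
  if (step <= 0 || step > 0.5 + 1e-12) {
    stop("step must be in (0, 0.5]", call. = FALSE)
  }
  a_vals <- seq(0, 1, by = step)
  grid <- do.call(rbind, lapply(a_vals, function(a) {
    m <- seq(0, 1 - a + 1e-12, by = step)
    m <- m[m <= 1 - a + 1e-9]
    cbind(a, m)
  }))
  amc <- cbind(grid[, 1], grid[, 2], pmax(0, 1 - grid[, 1] - grid[, 2]))
  vals <- nll_matrix(colony, panel, amc, eps_p = eps_p)
  i <- which.min(vals)   # lattice enumerated in lex (A, M) order: first min wins
  list(admixture = setNames(amc[i, ], LINEAGES_NUCLEAR),
       value = vals[i], n_points = nrow(amc))
}

#' Batch admixture estimation
#'
#' Runs [estimate_admixture()] over a list of colonies; per-colony failures
#' are caught and recorded so the batch continues.
#'
#' @param colonies list of [colony_observation()].
#' @param panel a [lineage_panel()].
#' @param options an [admix_options()].
#' @param verbose log progress every 50 colonies.
#' @return A data frame with one row per colony: `colony_id, A, M, C, nll,
#'   converged, flat_flag, error` (error `NA` on success).
#' @export
estimate_batch <- function(colonies, panel, options = admix_options(),
                           verbose = FALSE) {
  rows <- lapply(seq_along(colonies), function(i) {
    if (verbose && i %% 50L == 0L) message(sprintf("  colony %d / %d", i, length(colonies)))
    col <- colonies[[i]]
    res <- tryCatch(estimate_admixture(col, panel, options),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(colony_id = col$colony_id, A = NA_real_, M = NA_real_,
                 C = NA_real_, nll = NA_real_, converged = FALSE,
                 flat_flag = NA, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(colony_id = res$colony_id, A = res$A, M = res$M, C = res$C,
                 nll = res$neg_log_likelihood, converged = res$converged,
                 flat_flag = res$flat_likelihood_flag, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
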