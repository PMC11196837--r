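#' Simulation configuration for synthetic honey-bee colony data
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study design the estimators assume: 94 ancestry-informative SNPs, 20
#' sampled workers per colony (40 allele copies), queens mated to 12 drones,
#' a national mean admixture of (A, M, C) = (0.59, 0.24, 0.17), and maternal
#' lineage frequencies dominated by the African lineage with the Eastern
#' European lineage second and the Western European lineage rare.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param n_snps number of panel SNPs L (default 94).
#' @param panel_mode `"diagnostic"` (each SNP nearly fixed for one lineage:
#'   frequency `1 - epsilon` in that lineage, `epsilon` elsewhere, cycling
#'   through lineages) or `"beta"` (each lineage frequency iid
#'   `Beta(beta_shape[1], beta_shape[2])`).
#' @param epsilon diagnostic-panel frequency offset (default 0.01, kept off 0
#'   so log-likelihoods stay finite for any observation).
#' @param beta_shape shape pair for beta panels (default `c(0.5, 0.5)`).
#' @param true_admixture default colony (A, M, C) truth on the simplex.
#' @param n_drones number of drone fathers d per queen (default 12).
#' @param n_workers workers pooled per colony (default 20; 40 allele copies).
#' @param sampling_mode `"idealized"` (pooled counts drawn directly
#'   `Binomial(n_alleles, p_j)` at the admixture-mixture frequency — exactly
#'   the estimator's model) or `"family"` (explicit queen + drone + patriline
#'   structure; see [simulate_colony()]).
#' @param n_colonies colonies per dataset (default 48).
#' @param n_apiaries apiaries the colonies are grouped into (default 8).
#' @param prop_managed probability a colony is managed rather than feral
#'   (default 0.713).
#' @param maternal_lineage_probs probabilities of maternal lineage A/M/C
#'   (default `c(A = 0.59, M = 0.02, C = 0.39)`), drawn independently of the
#'   nuclear truth so mito-nuclear discordance scenarios can be simulated.
#' @param seq_length COI-COII stand-in sequence length (default 600 bp).
#' @param between_lineage_substitutions substitutions separating each lineage
#'   ancestor from the shared root (default 10); ancestors differ pairwise by
#'   at least this many positions.
#' @param within_lineage_mutations maximum extra substitutions per colony
#'   sequence (default 2).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_snps = 94L,
                              panel_mode = c("diagnostic", "beta"),
                              epsilon = 0.01,
                              beta_shape = c(0.5, 0.5),
                              true_admixture = c(A = 0.59, M = 0.24, C = 0.17),
                              n_drones = 12L,
                              n_workers = 20L,
                              sampling_mode = c("idealized", "family"),
                              n_colonies = 48L,
                              n_apiaries = 8L,
                              prop_managed = 0.713,
                              maternal_lineage_probs = c(A = 0.59, M = 0.02, C = 0.39),
                              seq_length = 600L,
                              between_lineage_substitutions = 10L,
                              within_lineage_mutations = 2L) {
  panel_mode <- match.arg(panel_mode)
  sampling_mode <- match.arg(sampling_mode)
  true_admixture <- true_admixture / sum(true_admixture)
  assert_simplex(true_admixture, "true_admixture")
  counts <- c(n_snps = n_snps, n_drones = n_drones, n_workers = n_workers,
              n_colonies = n_colonies, n_apiaries = n_apiaries,
              seq_length = seq_length)
  if (any(counts < 1L)) {
    stop(sprintf("%s must be positive", names(counts)[which(counts < 1L)[1]]),
         call. = FALSE)
  }
  if (any(beta_shape <= 0)) stop("beta_shape must be positive", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)", call. = FALSE)
  maternal_lineage_probs <- maternal_lineage_probs / sum(maternal_lineage_probs)
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 panel_mode = panel_mode, epsilon = epsilon,
                 beta_shape = beta_shape,
                 true_admixture = setNames(true_admixture, LINEAGES_NUCLEAR),
                 n_drones = as.integer(n_drones),
                 n_workers = as.integer(n_workers),
                 sampling_mode = sampling_mode,
                 n_colonies = as.integer(n_colonies),
                 n_apiaries = as.integer(n_apiaries),
                 prop_managed = prop_managed,
                 maternal_lineage_probs =
                   setNames(maternal_lineage_probs, LINEAGES_NUCLEAR),
                 seq_length = as.integer(seq_length),
                 between_lineage_substitutions = as.integer(between_lineage_substitutions),
                 within_lineage_mutations = as.integer(within_lineage_mutations)),
            class = "simulation_config")
}

# ---- panel ------------------------------------------------------------------

panel_core <- function(config) {
  L <- config$n_snps
  if (config$panel_mode == "diagnostic") {
    eps <- config$epsilon
    freqs <- matrix(eps, nrow = 3L, ncol = L)
    fixed_in <- rep_len(1:3, L)                 # cycle A, M, C along the panel
    freqs[cbind(fixed_in, seq_len(L))] <- 1 - eps
  } else {
    freqs <- matrix(rbeta(3L * L, config$beta_shape[1], config$beta_shape[2]),
                    nrow = 3L, ncol = L)
  }
  lineage_panel(sprintf("snp%03d", seq_len(L)), freqs, LINEAGES_NUCLEAR)
}

#' Simulate a lineage reference panel
#'
#' Diagnostic mode builds a maximally informative panel (each SNP nearly fixed
#' in one lineage); beta mode draws each lineage frequency independently from
#' a Beta distribution, giving panels with a realistic spread of
#' informativeness.
#'
#' @param config a [simulation_config()]; `config$seed` seeds the draw.
#' @return A [lineage_panel()]. Deterministic given the config.
#' @export
simulate_panel <- function(config) {
  with_seed(config$seed, panel_core(config))
}

# ---- single colony ----------------------------------------------------------

colony_core <- function(panel, truth, config, colony_id = "sim1",
                        apiary_id = NA_character_, region = NA_character_,
                        management = NA_character_,
                        latitude = NA_real_, longitude = NA_real_,
                        altitude = NA_real_) {
  assert_simplex(truth, "truth")
  L <- length(panel$snp_ids)
  n_alleles <- 2L * config$n_workers
  p_mix <- as.vector(truth %*% panel$freqs)   # Eq.-style mixture frequency
  maternal <- sample(LINEAGES_NUCLEAR, 1L, prob = config$maternal_lineage_probs)
  worker_counts <- NULL
  drone_lineages <- NULL
  if (config$sampling_mode == "idealized") {
    counts <- rbinom(L, n_alleles, p_mix)
  } else {
    d <- config$n_drones
    w <- config$n_workers
    # lineage of origin for each queen allele and each drone allele, per locus
    queen_lin <- matrix(sample.int(3L, 2L * L, replace = TRUE,
                                   prob = truth), nrow = 2L)
    queen_allele <- matrix(rbinom(2L * L, 1L,
                                  panel$freqs[cbind(as.vector(queen_lin),
                                                    rep(seq_len(L), each = 2L))]),
                           nrow = 2L)
    drone_lin <- matrix(sample.int(3L, d * L, replace = TRUE,
                                   prob = truth), nrow = d)
    drone_allele <- matrix(rbinom(d * L, 1L,
                                  panel$freqs[cbind(as.vector(drone_lin),
                                                    rep(seq_len(L), each = d))]),
                           nrow = d)
    father <- sample.int(d, w, replace = TRUE)  # multinomial patrilines
    # each worker: one queen allele (independent meiosis per locus) + father's allele
    meiosis <- matrix(sample.int(2L, w * L, replace = TRUE), nrow = w)
    queen_side <- matrix(queen_allele[cbind(as.vector(meiosis),
                                            rep(seq_len(L), each = w))], nrow = w)
    drone_side <- drone_allele[father, , drop = FALSE]
    worker_counts <- queen_side + drone_side    # 0/1/2 per worker per locus
    counts <- colSums(worker_counts)
    drone_lineages <- LINEAGES_NUCLEAR[drone_lin[, 1L]]  # per-drone label at locus 1
  }
  obs <- colony_observation(colony_id, counts, panel, n_alleles = n_alleles,
                            apiary_id = apiary_id, region = region,
                            management = management, latitude = latitude,
                            longitude = longitude, altitude = altitude,
                            maternal_lineage = maternal)
  truth_rec <- list(colony_id = colony_id,
                    true_admixture = setNames(truth, LINEAGES_NUCLEAR),
                    maternal_lineage = maternal,
                    drone_lineages = drone_lineages,
                    worker_counts = worker_counts)
  list(observation = obs, truth = truth_rec)
}

#' Simulate one colony's pooled SNP observation
#'
#' Idealized mode draws the pooled reference-allele count at each SNP directly
#' from `Binomial(n_alleles, p_j)` with `p_j` the admixture mixture frequency
#' — exactly the model the maximum-likelihood estimator assumes. Family mode
#' builds the colony explicitly: the queen carries two alleles and each of `d`
#' drones one allele (lineage of origin sampled from the truth vector per
#' locus), each worker inherits one queen allele plus the allele of a father
#' drone assigned uniformly at random (multinomial patrilines), and the pooled
#' count sums the workers' alleles. Family mode therefore has extra
#' between-replicate variance from the finite queen/drone allele pool, which
#' the estimator (like the study design) ignores.
#'
#' @param panel a [lineage_panel()].
#' @param truth length-3 (A, M, C) vector on the simplex.
#' @param config a [simulation_config()]; `seed`, `sampling_mode`,
#'   `n_workers`, `n_drones`, `maternal_lineage_probs` are used.
#' @return A list with `observation` (a [colony_observation()], maternal
#'   lineage attached) and `truth` (colony truth record; in family mode it
#'   carries the per-worker 0/1/2 genotype matrix, whose column means times
#'   2 reproduce the pooled frequency exactly).
#' @export
simulate_colony <- function(panel, truth, config) {
  with_seed(config$seed, colony_core(panel, truth, config))
}

# ---- whole dataset ----------------------------------------------------------

STUDY_REGIONS <- c("North", "Central Highlands", "Pacific Coast",
                   "Gulf Coast", "Yucatan Peninsula")

#' Simulate a full colony dataset with known truth
#'
#' Draws a panel, then `n_colonies` colonies grouped into `n_apiaries`
#' apiaries (assigned round-robin to the five beekeeping regions, each apiary
#' georeferenced), each colony managed or feral with probability
#' `prop_managed`, plus lineage-structured COI-COII stand-in sequences. All
#' draws come from one generator seeded by `config$seed`, so outputs are fully
#' reproducible.
#'
#' @param config a [simulation_config()].
#' @param true_admixture optional L x 3 matrix (or length-3 vector recycled to
#'   all colonies) of per-colony truths; defaults to `config$true_admixture`
#'   for every colony.
#' @param dir optional directory: when given, panel/colony/truth tables and
#'   the two FASTA files are written there in the package's text formats.
#' @return A list of class `simulated_dataset`: `panel`, `colonies` (list of
#'   [colony_observation()]), `truth` (data frame `colony_id, true_A, true_M,
#'   true_C, maternal_lineage, seed`), `sequences` (from
#'   [simulate_haplotypes()]), `config`, and `paths` when `dir` was given.
#' @export
simulate_dataset <- function(config, true_admixture = NULL, dir = NULL) {
  truths <- true_admixture
  if (is.null(truths)) truths <- config$true_admixture
  if (is.null(dim(truths))) {
    truths <- matrix(truths, nrow = config$n_colonies, ncol = 3L, byrow = TRUE)
  }
  if (nrow(truths) != config$n_colonies) {
    stop("true_admixture must have one row per colony", call. = FALSE)
  }
  res <- with_seed(config$seed, {
    panel <- panel_core(config)
    apiary_of <- rep_len(seq_len(config$n_apiaries), config$n_colonies)
    region_of_apiary <- rep_len(STUDY_REGIONS, config$n_apiaries)
    lat <- runif(config$n_apiaries, 16, 32)
    lon <- runif(config$n_apiaries, -115, -88)
    alt <- runif(config$n_apiaries, 0, 2600)
    colonies <- vector("list", config$n_colonies)
    truth_rows <- vector("list", config$n_colonies)
    for (k in seq_len(config$n_colonies)) {
      a <- apiary_of[k]
      managed <- runif(1) < config$prop_managed
      sim <- colony_core(panel, truths[k, ], config,
                         colony_id = sprintf("col%03d", k),
                         apiary_id = sprintf("apiary%02d", a),
                         region = region_of_apiary[a],
                         management = if (managed) "managed" else "feral",
                         latitude = lat[a], longitude = lon[a],
                         altitude = alt[a])
      colonies[[k]] <- sim$observation
      truth_rows[[k]] <- data.frame(colony_id = sim$truth$colony_id,
                                    true_A = truths[k, 1], true_M = truths[k, 2],
                                    true_C = truths[k, 3],
                                    maternal_lineage = sim$truth$maternal_lineage,
                                    seed = config$seed,
                                    stringsAsFactors = FALSE)
    }
    maternal <- vapply(colonies, function(x) x$maternal_lineage, character(1))
    sequences <- haplotype_core(config,
                                setNames(maternal,
                                         vapply(colonies, function(x) x$colony_id,
                                                character(1))))
    list(panel = panel, colonies = colonies,
         truth = do.call(rbind, truth_rows), sequences = sequences)
  })
  res$config <- config
  class(res) <- "simulated_dataset"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(panel = file.path(dir, "panel.csv"),
                  colonies = file.path(dir, "colonies.csv"),
                  truth = file.path(dir, "truth.csv"),
                  references = file.path(dir, "references.fasta"),
                  colony_seqs = file.path(dir, "colony_seqs.fasta"))
    write_panel(res$panel, paths$panel)
    write_colonies(res$colonies, paths$colonies)
    write.table(res$truth, paths$truth, sep = ",", row.names = FALSE, quote = FALSE)
    write_fasta(res$sequences$references, paths$references)
    write_fasta(res$sequences$colonies, paths$colony_seqs)
    res$paths <- paths
  }
  res
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d colonies / %d apiaries, L=%d (%s panel, %s sampling), seed=%d\n",
              length(x$colonies), x$config$n_apiaries, x$config$n_snps,
              x$config$panel_mode, x$config$sampling_mode, x$config$seed))
  invisible(x)
}

# ---- mtDNA sequences --------------------------------------------------------

haplotype_core <- function(config, maternal_lineages) {
  b <- config$between_lineage_substitutions
  w <- config$within_lineage_mutations
  if (b <= 2L * w) {
    stop("separability requires between_lineage_substitutions > 2 * within_lineage_mutations",
         call. = FALSE)
  }
  len <- config$seq_length
  bases <- c("A", "C", "G", "T")
  if (len < b * length(LINEAGES_MITO)) {
    stop("seq_length too short for disjoint lineage-diagnostic sites", call. = FALSE)
  }
  root <- sample(bases, len, replace = TRUE)
  # each lineage mutates its own disjoint block of b sites, so ancestors
  # differ pairwise at >= 2b > b positions
  site_pool <- sample.int(len, b * length(LINEAGES_MITO))
  refs <- list()
  for (i in seq_along(LINEAGES_MITO)) {
    s <- root
    sites <- site_pool[((i - 1L) * b + 1L):(i * b)]
    s[sites] <- vapply(s[sites], function(x) sample(setdiff(bases, x), 1L),
                       character(1))
    refs[[LINEAGES_MITO[i]]] <- paste(s, collapse = "")
  }
  colony_seqs <- character(0)
  if (length(maternal_lineages)) {
    colony_seqs <- vapply(maternal_lineages, function(lin) {
      s <- strsplit(refs[[lin]], "")[[1]]
      k <- sample.int(w + 1L, 1L) - 1L          # 0..w extra substitutions
      if (k > 0L) {
        sites <- sample.int(len, k)
        s[sites] <- vapply(s[sites], function(x) sample(setdiff(bases, x), 1L),
                           character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    names(colony_seqs) <- names(maternal_lineages)
  }
  ref_seqs <- unlist(refs)
  names(ref_seqs) <- sprintf("%s|ref_%s", LINEAGES_MITO, LINEAGES_MITO)
  list(references = ref_seqs, colonies = colony_seqs,
       maternal_lineages = maternal_lineages)
}

#' Simulate lineage-structured COI-COII stand-in sequences
#'
#' Builds one ancestral sequence per mtDNA lineage (A, M, C, O, Y), each
#' carrying substitutions at its own disjoint block of
#' `between_lineage_substitutions` sites so ancestors differ pairwise by at
#' least that many positions, then derives each colony's sequence from its
#' maternal lineage's ancestor with at most `within_lineage_mutations` extra
#' substitutions. The alphabet is `{A, C, G, T}`; no indels are simulated.
#'
#' @param config a [simulation_config()]; requires
#'   `between_lineage_substitutions > 2 * within_lineage_mutations` so that
#'   nearest-reference classification is guaranteed to recover the truth.
#' @param maternal_lineages named character vector (names = colony ids) of
#'   maternal lineages in `A/M/C/O/Y`; when `NULL`, lineages for
#'   `config$n_colonies` colonies are drawn from `maternal_lineage_probs`.
#' @return A list with `references` (named `lineage|name`), `colonies` (named
#'   by colony id) and `maternal_lineages`.
#' @export
simulate_haplotypes <- function(config, maternal_lineages = NULL) {
  with_seed(config$seed, {
    if (is.null(maternal_lineages)) {
      maternal_lineages <- setNames(
        sample(LINEAGES_NUCLEAR, config$n_colonies, replace = TRUE,
               prob = config$maternal_lineage_probs),
        sprintf("col%03d", seq_len(config$n_colonies)))
    }
    haplotype_core(config, maternal_lineages)
  })
}
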