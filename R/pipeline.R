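#' Run the full colony-ancestry pipeline
#'
#' Composes the whole analysis: load (or simulate) a panel, colony SNP table
#' and mtDNA sequences; estimate per-colony (A, M, C) admixture by maximum
#' likelihood; classify maternal lineages, deduplicate haplotypes, build the
#' haplotype network and apiary-level mitochondrial Africanization; then
#' produce group-level mito-vs-nuclear comparisons. Writes delimited-text
#' reports plus a run log into the output directory.
#'
#' The config (YAML file or equivalent list) must name either a `simulate:`
#' block (arguments for [simulation_config()]) or an `inputs:` block with
#' `panel`, `colonies`, `colony_fasta`, `reference_fasta` paths, plus an
#' `out_dir`. Optional `params:` block: `max_steps`, `n_starts`, `seed`,
#' `drone_matings`, `z`, `group_by`.
#'
#' @param config path to a YAML config file, or a list with the same shape.
#' @return Invisibly, a list with `estimates`, `mito`, `haplotypes`,
#'   `network`, `africanization`, `groups`, and `paths` of everything
#'   written. Stage failures stop with the stage name.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("out_dir")) {
    if (is.null(config[[key]])) stop(sprintf("config missing key '%s'", key),
                                     call. = FALSE)
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config missing key 'simulate' or 'inputs'", call. = FALSE)
  }
  params <- config$params
  if (is.null(params)) params <- list()
  max_steps <- if (is.null(params$max_steps)) 10L else as.integer(params$max_steps)
  drone_matings <- if (is.null(params$drone_matings)) 12L else as.integer(params$drone_matings)
  z <- if (is.null(params$z)) 1.96 else params$z
  group_by <- if (is.null(params$group_by)) c("region", "management") else params$group_by
  opts <- admix_options(
    n_starts = if (is.null(params$n_starts)) 8L else as.integer(params$n_starts),
    seed = if (is.null(params$seed)) 1L else as.integer(params$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sim_cfg <- do.call(simulation_config, config$simulate)
      sim <- simulate_dataset(sim_cfg)
      list(panel = sim$panel, colonies = sim$colonies,
           colony_seqs = sim$sequences$colonies,
           references = sim$sequences$references, truth = sim$truth,
           sim_config = sim_cfg)
    } else {
      for (key in c("panel", "colonies", "colony_fasta", "reference_fasta")) {
        if (is.null(config$inputs[[key]])) {
          stop(sprintf("config missing key 'inputs.%s'", key), call. = FALSE)
        }
      }
      panel <- load_panel(config$inputs$panel)
      list(panel = panel,
           colonies = load_colonies(config$inputs$colonies, panel),
           colony_seqs = read_fasta(config$inputs$colony_fasta),
           references = read_fasta(config$inputs$reference_fasta),
           truth = NULL, sim_config = NULL)
    }
  })

  estimates <- stage("admixture", estimate_batch(inputs$colonies, inputs$panel, opts))

  refs <- stage("mtdna", {
    parts <- strsplit(names(inputs$references), "|", fixed = TRUE)
    data.frame(lineage = vapply(parts, `[`, character(1), 1L),
               name = names(inputs$references),
               sequence = unname(inputs$references), stringsAsFactors = FALSE)
  })
  mito <- stage("mtdna", classify_colonies(inputs$colony_seqs, refs))
  metadata <- stage("mtdna", do.call(rbind, lapply(inputs$colonies, function(x) {
    data.frame(colony_id = x$colony_id, apiary_id = x$apiary_id,
               region = x$region, management = x$management,
               latitude = x$latitude, longitude = x$longitude,
               altitude = x$altitude, stringsAsFactors = FALSE)
  })))
  haplos <- stage("mtdna", dedupe_haplotypes(
    merge(data.frame(colony_id = names(inputs$colony_seqs),
                     sequence = unname(inputs$colony_seqs),
                     stringsAsFactors = FALSE),
          mito[, c("colony_id", "lineage")], by = "colony_id")))
  network <- stage("mtdna", build_network(haplos, max_steps = max_steps))
  african <- stage("mtdna", mito_africanization(
    merge(mito[, c("colony_id", "lineage")],
          metadata[, c("colony_id", "apiary_id")], by = "colony_id")))

  groups <- stage("summary", summarize_groups(estimates, mito, metadata,
                                              group_by = group_by,
                                              drone_matings = drone_matings,
                                              z = z))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage("write", {
    p <- list(estimates = file.path(out_dir, "estimates.csv"),
              mito = file.path(out_dir, "mito_report.csv"),
              haplotypes = file.path(out_dir, "haplotypes.csv"),
              network = file.path(out_dir, "network_edges.csv"),
              africanization = file.path(out_dir, "mito_africanization.csv"),
              groups = file.path(out_dir, "group_summary.csv"),
              verdicts = file.path(out_dir, "verdicts.csv"),
              log = file.path(out_dir, "run_log.txt"))
    wr <- function(df, path) write.table(df, path, sep = ",", row.names = FALSE,
                                         quote = FALSE)
    wr(estimates, p$estimates)
    wr(merge(mito, metadata, by = "colony_id"), p$mito)
    hdf <- haplos
    hdf$member_colony_ids <- vapply(hdf$member_colony_ids, paste,
                                    character(1), collapse = ";")
    wr(hdf, p$haplotypes)
    wr(network$edges, p$network)
    wr(african, p$africanization)
    wr(groups, p$groups)
    wr(groups[!is.na(groups$verdict),
              c(group_by, "lineage", "verdict")], p$verdicts)
    log_lines <- c(
      "apiadmix run log",
      sprintf("package version: %s", as.character(utils::packageVersion("apiadmix"))),
      sprintf("colonies: %d, SNPs: %d", length(inputs$colonies),
              length(inputs$panel$snp_ids)),
      sprintf("options: n_starts=%d seed=%d max_steps=%d drone_matings=%d z=%g",
              opts$n_starts, opts$seed, max_steps, drone_matings, z),
      if (!is.null(inputs$sim_config))
        sprintf("simulation seed: %d", inputs$sim_config$seed) else
          "inputs: files supplied")
    writeLines(log_lines, p$log)
    p
  })

  invisible(list(estimates = estimates, mito = mito, haplotypes = haplos,
                 network = network, africanization = african, groups = groups,
                 truth = inputs$truth, paths = paths))
}
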