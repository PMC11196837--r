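#' Effective nuclear allele count for a group of colonies
#'
#' Each colony contributes two queen alleles plus one haploid allele from
#' each of the queen's drone mates (12 matings is a conservative estimate of
#' honey-bee queen mating frequency), so a group of `n` colonies carries
#' `(2 + drone_matings) * n` effective alleles.
#'
#' @param n_colonies number of colonies (>= 1).
#' @param drone_matings assumed matings per queen (default 12).
#' @return Integer effective allele count.
#' @export
nuclear_effective_n <- function(n_colonies, drone_matings = 12L) {
  if (n_colonies < 1L || drone_matings < 1L) {
    stop("n_colonies and drone_matings must be positive", call. = FALSE)
  }
  as.integer((2L + as.integer(drone_matings)) * as.integer(n_colonies))
}

#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat * (1 - p_hat) / n_effective)`, truncated to
#' `[0, 1]`. At `p_hat` of exactly 0 or 1 the interval collapses to zero
#' width and is flagged degenerate.
#'
#' @param p_hat proportion in `[0, 1]`.
#' @param n_effective effective sample size (>= 1).
#' @param z critical value (default 1.96 for a 95% interval).
#' @return A list of class `proportion_ci`: `p_hat`, `n_effective`, `z`,
#'   `half_width` (pre-truncation), `lower`, `upper`, `degenerate_flag`.
#' @export
proportion_ci <- function(p_hat, n_effective, z = 1.96) {
  if (is.na(p_hat) || p_hat < 0 || p_hat > 1) {
    stop("p_hat must be a proportion in [0, 1]", call. = FALSE)
  }
  if (n_effective < 1) stop("n_effective must be >= 1", call. = FALSE)
  hw <- z * sqrt(p_hat * (1 - p_hat) / n_effective)
  structure(list(p_hat = p_hat, n_effective = n_effective, z = z,
                 half_width = hw,
                 lower = max(0, p_hat - hw), upper = min(1, p_hat + hw),
                 degenerate_flag = p_hat == 0 || p_hat == 1),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("<proportion_ci> %.4f [%.4f, %.4f] (n_eff=%d, z=%.2f%s)\n",
              x$p_hat, x$lower, x$upper, as.integer(x$n_effective), x$z,
              if (x$degenerate_flag) ", degenerate" else ""))
  invisible(x)
}

#' Compare mitochondrial vs nuclear ancestry proportions by CI overlap
#'
#' Overlapping 95% confidence intervals are read as no distinguishable
#' difference; disjoint intervals give the verdict of the side with the
#' higher point estimate.
#'
#' @param mito_ci,nuclear_ci [proportion_ci()] objects.
#' @return `"mito_higher"`, `"nuclear_higher"` or `"not_distinguishable"`.
#' @export
compare_mt_vs_nuclear <- function(mito_ci, nuclear_ci) {
  if (!inherits(mito_ci, "proportion_ci") || !inherits(nuclear_ci, "proportion_ci")) {
    stop("both arguments must be proportion_ci objects", call. = FALSE)
  }
  overlap <- mito_ci$lower <= nuclear_ci$upper && nuclear_ci$lower <= mito_ci$upper
  if (overlap) {
    "not_distinguishable"
  } else if (mito_ci$p_hat > nuclear_ci$p_hat) {
    "mito_higher"
  } else {
    "nuclear_higher"
  }
}

#' Group-level mitochondrial vs nuclear ancestry summaries
#'
#' For each group (e.g. region x management, or apiary), computes per lineage
#' the mitochondrial ancestry proportion (share of classified colonies whose
#' maternal lineage is that lineage, `n_effective` = number of classified
#' colonies) and the mean nuclear admixture proportion (`n_effective` =
#' `(2 + drone_matings) * n_colonies` alleles), their Wald intervals, and the
#' overlap verdict. Mito-only lineages (O, Y) appear with `NA` nuclear
#' columns since the nuclear panel spans A/M/C only.
#'
#' @param estimates data frame from [estimate_batch()] (`colony_id, A, M, C`).
#' @param mito data frame `colony_id, lineage` (e.g. from
#'   [classify_colonies()]).
#' @param metadata data frame with `colony_id` and the grouping columns.
#' @param group_by character vector of metadata columns to group on
#'   (default `c("region", "management")`).
#' @param drone_matings assumed matings per queen for the nuclear effective n.
#' @param z CI critical value.
#' @param min_group_size groups smaller than this are flagged.
#' @return A data frame of class `group_ancestry_summary`, one row per group
#'   x lineage: group columns, `n_colonies`, `n_classified`, `lineage`,
#'   `mito_p, mito_lower, mito_upper`, `nuclear_p, nuclear_lower,
#'   nuclear_upper`, `verdict`, `small_group_flag`; ordered by group key.
#' @export
summarize_groups <- function(estimates, mito, metadata,
                             group_by = c("region", "management"),
                             drone_matings = 12L, z = 1.96,
                             min_group_size = 3L) {
  if (!all(group_by %in% names(metadata))) {
    stop(sprintf("metadata lacks grouping column(s): %s",
                 paste(setdiff(group_by, names(metadata)), collapse = ", ")),
         call. = FALSE)
  }
  df <- merge(metadata[, c("colony_id", group_by)], estimates, by = "colony_id")
  df <- merge(df, mito[, c("colony_id", "lineage")], by = "colony_id",
              all.x = TRUE)
  lost <- setdiff(metadata$colony_id, df$colony_id)
  if (length(lost)) {
    warning(sprintf("colonies without nuclear estimates dropped: %s",
                    paste(lost, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(df[, group_by, drop = FALSE], drop = TRUE, sep = " / ")
  groups <- split(df, key)
  groups <- groups[order(names(groups))]
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    if (n == 0L) return(NULL)
    classified <- g$lineage[!is.na(g$lineage) & g$lineage %in% LINEAGES_MITO]
    n_class <- length(classified)
    mito_lineages <- union(LINEAGES_NUCLEAR, unique(classified))
    per_lineage <- lapply(mito_lineages, function(lin) {
      mito_p <- if (n_class > 0L) mean(classified == lin) else NA_real_
      mci <- if (!is.na(mito_p)) proportion_ci(mito_p, n_class, z) else NULL
      nuc <- if (lin %in% LINEAGES_NUCLEAR) mean(g[[lin]], na.rm = TRUE) else NA_real_
      nci <- if (!is.na(nuc))
        proportion_ci(nuc, nuclear_effective_n(n, drone_matings), z) else NULL
      verdict <- if (!is.null(mci) && !is.null(nci))
        compare_mt_vs_nuclear(mci, nci) else NA_character_
      out <- g[1, group_by, drop = FALSE]
      out$n_colonies <- n
      out$n_classified <- n_class
      out$lineage <- lin
      out$mito_p <- if (is.null(mci)) NA_real_ else mci$p_hat
      out$mito_lower <- if (is.null(mci)) NA_real_ else mci$lower
      out$mito_upper <- if (is.null(mci)) NA_real_ else mci$upper
      out$nuclear_p <- nuc
      out$nuclear_lower <- if (is.null(nci)) NA_real_ else nci$lower
      out$nuclear_upper <- if (is.null(nci)) NA_real_ else nci$upper
      out$verdict <- verdict
      out$small_group_flag <- n < min_group_size
      out
    })
    do.call(rbind, per_lineage)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_ancestry_summary", "data.frame")
  out
}
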