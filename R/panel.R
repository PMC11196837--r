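#' Construct a lineage reference-allele frequency panel
#'
#' A `lineage_panel` stores, for each ancestry-informative SNP, the frequency
#' of a designated reference allele in each source lineage (by default the
#' African A, Western European M and Eastern European C lineages). Loci are
#' assumed biallelic, so the alternate allele's frequency is `1 - p` and a
#' single number per lineage per SNP suffices.
#'
#' @param snp_ids character vector of unique locus identifiers (length L).
#' @param freqs numeric matrix of reference-allele frequencies, one row per
#'   lineage and one column per SNP; all values in `[0, 1]`.
#' @param lineages character vector of lineage labels, one per row of `freqs`.
#' @return An object of class `lineage_panel` with elements `snp_ids`,
#'   `lineages` and `freqs` (rows named by lineage, columns by SNP).
#' @export
lineage_panel <- function(snp_ids, freqs, lineages = c("A", "M", "C")) {
  snp_ids <- as.character(snp_ids)
  freqs <- as.matrix(freqs)
  if (length(snp_ids) != ncol(freqs)) {
    stop("freqs must have one column per snp_id", call. = FALSE)
  }
  if (length(lineages) != nrow(freqs)) {
    stop("freqs must have one row per lineage", call. = FALSE)
  }
  dup <- snp_ids[duplicated(snp_ids)]
  if (length(dup)) {
    stop(sprintf("duplicate SNP id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(is.na(freqs) | freqs < 0 | freqs > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("frequency outside [0, 1] at SNP %s (lineage %s)",
                 snp_ids[bad[1, 2]], lineages[bad[1, 1]]), call. = FALSE)
  }
  dimnames(freqs) <- list(lineages, snp_ids)
  structure(list(snp_ids = snp_ids, lineages = as.character(lineages),
                 freqs = freqs),
            class = "lineage_panel")
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat(sprintf("<lineage_panel> %d SNPs x lineages {%s}; mean divergence %.3f\n",
              length(x$snp_ids), paste(x$lineages, collapse = ", "),
              mean(snp_divergence(x))))
  invisible(x)
}

# per-SNP max pairwise |frequency difference| (= range for >= 2 lineages)
snp_divergence <- function(panel) {
  apply(panel$freqs, 2L, max) - apply(panel$freqs, 2L, min)
}

#' Read a lineage panel from delimited text
#'
#' Expects a UTF-8 comma- or tab-delimited file (delimiter auto-detected from
#' the header) with one row per SNP: an identifier column and one frequency
#' column per lineage.
#'
#' @param path file path.
#' @param lineage_columns named character vector mapping lineage labels to
#'   their frequency columns, default `c(A = "freq_A", M = "freq_M", C = "freq_C")`.
#' @param id_column name of the SNP identifier column.
#' @return A validated [lineage_panel()]; file row order is preserved.
#' @export
load_panel <- function(path,
                       lineage_columns = c(A = "freq_A", M = "freq_M", C = "freq_C"),
                       id_column = "snp_id") {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(c(id_column, unname(lineage_columns)), names(df))
  if (length(missing_cols)) {
    stop(sprintf("panel file lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  freqs <- t(as.matrix(df[, unname(lineage_columns), drop = FALSE]))
  if (!is.numeric(freqs)) {
    stop("panel frequency columns contain non-numeric values", call. = FALSE)
  }
  lineage_panel(df[[id_column]], freqs, lineages = names(lineage_columns))
}

#' Write a lineage panel to delimited text
#'
#' Inverse of [load_panel()]: columns `snp_id` then `freq_<lineage>`.
#'
#' @param panel a [lineage_panel()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  df <- data.frame(snp_id = panel$snp_ids, check.names = FALSE)
  for (lin in panel$lineages) df[[paste0("freq_", lin)]] <- panel$freqs[lin, ]
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Panel informativeness report
#'
#' Quantifies how well each SNP separates the source lineages: the per-SNP
#' divergence is the maximum pairwise absolute frequency difference between
#' lineages. SNPs with zero divergence carry no ancestry information and are
#' flagged.
#'
#' @param panel a [lineage_panel()].
#' @return A list of class `panel_informativeness`: `per_snp` (data frame with
#'   `snp_id`, `divergence`, `uninformative`), `mean_divergence`, and
#'   `n_uninformative`.
#' @export
panel_informativeness <- function(panel) {
  div <- snp_divergence(panel)
  per_snp <- data.frame(snp_id = panel$snp_ids, divergence = unname(div),
                        uninformative = unname(div == 0),
                        stringsAsFactors = FALSE)
  structure(list(per_snp = per_snp,
                 mean_divergence = mean(div),
                 n_uninformative = sum(div == 0)),
            class = "panel_informativeness")
}

#' @export
print.panel_informativeness <- function(x, ...) {
  cat(sprintf("<panel_informativeness> mean divergence %.4f over %d SNPs (%d uninformative)\n",
              x$mean_divergence, nrow(x$per_snp), x$n_uninformative))
  invisible(x)
}
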