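COLONY_META_COLS <- c("colony_id", "apiary_id", "region", "management",
                      "latitude", "longitude", "altitude", "n_alleles")

#' Construct a colony observation
#'
#' One colony's pooled reference-allele counts at the SNPs of a panel, plus
#' sampling metadata. In the study design DNA from 20 workers is pooled, so a
#' colony contributes `n_alleles = 40` allele copies per locus and the pooled
#' frequency at SNP j is `r_j / n_alleles`.
#'
#' @param colony_id,apiary_id identifiers.
#' @param counts integer vector of reference-allele copy numbers, aligned to
#'   `panel$snp_ids` (names are set from the panel). `NA` marks a missing SNP.
#' @param panel the [lineage_panel()] the counts are aligned to.
#' @param n_alleles total allele copies per locus (default 40 = 2 x 20 workers).
#' @param region,management,latitude,longitude,altitude sampling metadata;
#'   `management` must be `"managed"` or `"feral"` (or `NA`).
#' @param maternal_lineage optional mtDNA lineage label in
#'   `c("A","M","C","O","Y","unknown")`.
#' @return An object of class `colony_observation`.
#' @export
colony_observation <- function(colony_id, counts, panel, n_alleles = 40L,
                               apiary_id = NA_character_, region = NA_character_,
                               management = NA_character_,
                               latitude = NA_real_, longitude = NA_real_,
                               altitude = NA_real_,
                               maternal_lineage = NA_character_) {
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L) {
    stop("n_alleles must be a positive integer", call. = FALSE)
  }
  if (length(counts) != length(panel$snp_ids)) {
    stop("counts must align to the panel's SNPs", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  bad <- which(!is.na(counts) & (counts < 0L | counts > n_alleles))
  if (length(bad)) {
    stop(sprintf("colony %s: count %d at SNP %s outside [0, %d]",
                 colony_id, counts[bad[1]], panel$snp_ids[bad[1]], n_alleles),
         call. = FALSE)
  }
  if (all(is.na(counts))) {
    stop(sprintf("colony %s has no non-missing SNPs", colony_id), call. = FALSE)
  }
  if (!is.na(management) && !management %in% c("managed", "feral")) {
    stop(sprintf("colony %s: unknown management label '%s'", colony_id, management),
         call. = FALSE)
  }
  if (!is.na(maternal_lineage) &&
      !maternal_lineage %in% c(LINEAGES_MITO, "unknown")) {
    stop(sprintf("colony %s: unknown maternal lineage '%s'", colony_id,
                 maternal_lineage), call. = FALSE)
  }
  names(counts) <- panel$snp_ids
  structure(list(colony_id = as.character(colony_id),
                 apiary_id = as.character(apiary_id),
                 region = as.character(region),
                 management = as.character(management),
                 latitude = as.numeric(latitude),
                 longitude = as.numeric(longitude),
                 altitude = as.numeric(altitude),
                 n_alleles = n_alleles,
                 counts = counts,
                 missing = is.na(counts),
                 maternal_lineage = as.character(maternal_lineage)),
            class = "colony_observation")
}

#' @export
print.colony_observation <- function(x, ...) {
  cat(sprintf("<colony_observation> %s (apiary %s, %s): %d/%d SNPs observed, n_alleles=%d\n",
              x$colony_id, x$apiary_id, x$management,
              sum(!x$missing), length(x$counts), x$n_alleles))
  invisible(x)
}

#' Observed pooled allele frequencies of a colony
#'
#' @param colony a [colony_observation()].
#' @return Numeric vector `counts / n_alleles` (NA where missing).
#' @export
observed_freq <- function(colony) {
  colony$counts / colony$n_alleles
}

#' Read colony observations from delimited text
#'
#' The file carries the metadata columns `colony_id, apiary_id, region,
#' management, latitude, longitude, altitude, n_alleles` followed by one
#' column per SNP holding either reference-allele counts or pooled
#' frequencies. Frequencies are converted once, at load time, to counts by
#' rounding `p * n_alleles` half away from zero; panel SNPs absent from the
#' file are marked missing and later dropped from the likelihood.
#'
#' Whether SNP columns hold counts or frequencies is taken from (in order):
#' the `values` argument; a first-line directive comment
#' `# values: counts|frequencies`; or inference (any value > 1 and all whole
#' numbers = counts, any fractional value within `[0, 1]` = frequencies).
#' Files where every value is 0 or 1 are ambiguous and rejected unless
#' `values` is given.
#'
#' @param path file path (comma- or tab-delimited, auto-detected).
#' @param panel the [lineage_panel()] to align against.
#' @param values `"auto"`, `"counts"` or `"frequencies"`.
#' @return A list of [colony_observation()] objects, aligned to panel SNP order.
#' @export
load_colonies <- function(path, panel, values = c("auto", "counts", "frequencies")) {
  values <- match.arg(values)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    directive <- sub("^#\\s*values:\\s*", "", first)
    if (values == "auto" && directive %in% c("counts", "frequencies")) {
      values <- directive
    }
  }
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  missing_meta <- setdiff(COLONY_META_COLS, names(df))
  if (length(missing_meta)) {
    stop(sprintf("colony file lacks column(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  snp_cols <- intersect(panel$snp_ids, names(df))
  if (!length(snp_cols)) {
    stop("colony file shares no SNP columns with the panel", call. = FALSE)
  }
  vals <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (values == "auto") {
    finite <- vals[!is.na(vals)]
    whole <- all(abs(finite - round(finite)) < 1e-9)
    if (whole && any(finite > 1)) {
      values <- "counts"
    } else if (!whole && all(finite >= 0 & finite <= 1)) {
      values <- "frequencies"
    } else {
      stop("cannot infer whether SNP columns are counts or frequencies; ",
           "pass values= or add a '# values:' directive", call. = FALSE)
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    n_alleles <- as.integer(df$n_alleles[i])
    row <- vals[i, ]
    if (values == "frequencies") {
      if (any(!is.na(row) & (row < 0 | row > 1))) {
        stop(sprintf("colony %s: frequency outside [0, 1]", df$colony_id[i]),
             call. = FALSE)
      }
      row <- round_half_up(row * n_alleles)
    }
    counts <- rep(NA_integer_, length(panel$snp_ids))
    names(counts) <- panel$snp_ids
    counts[snp_cols] <- as.integer(row)
    colony_observation(df$colony_id[i], counts, panel,
                       n_alleles = n_alleles,
                       apiary_id = df$apiary_id[i], region = df$region[i],
                       management = df$management[i],
                       latitude = df$latitude[i], longitude = df$longitude[i],
                       altitude = df$altitude[i],
                       maternal_lineage =
                         if ("maternal_lineage" %in% names(df))
                           df$maternal_lineage[i] else NA_character_)
  })
}

#' Write colony observations to delimited text
#'
#' @param colonies list of [colony_observation()].
#' @param path output path.
#' @param values write `"counts"` (default) or `"frequencies"`; a
#'   `# values:` directive line is prepended so round-trips are unambiguous.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_colonies <- function(colonies, path, values = c("counts", "frequencies"),
                           sep = ",") {
  values <- match.arg(values)
  snp_ids <- names(colonies[[1]]$counts)
  meta <- do.call(rbind, lapply(colonies, function(x) {
    data.frame(colony_id = x$colony_id, apiary_id = x$apiary_id,
               region = x$region, management = x$management,
               latitude = x$latitude, longitude = x$longitude,
               altitude = x$altitude, n_alleles = x$n_alleles,
               maternal_lineage = x$maternal_lineage,
               stringsAsFactors = FALSE)
  }))
  mat <- do.call(rbind, lapply(colonies, function(x) {
    if (values == "counts") x$counts else x$counts / x$n_alleles
  }))
  colnames(mat) <- snp_ids
  out <- cbind(meta, as.data.frame(mat, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# values: %s", values), con)
  write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
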