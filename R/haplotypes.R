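#' Normalize a raw DNA sequence
#'
#' Uppercases, strips alignment gap characters (`-`), and rejects any
#' character outside `{A, C, G, T, N}`, reporting the (gap-stripped) position
#' of the first offender.
#'
#' @param raw non-empty DNA string.
#' @return The normalized sequence string.
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  s <- gsub("-", "", toupper(raw), fixed = TRUE)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Unit-cost edit distance between DNA sequences
#'
#' Minimal number of substitutions plus indels (all unit cost) transforming
#' one sequence into the other, by global alignment. The ambiguity code `N`
#' matches any base at zero cost, so uncertain base calls do not create
#' spurious differences; on N-free sequences the distance is a metric.
#'
#' @param s1,s2 normalized sequences (see [normalize_sequence()]).
#' @return Integer distance.
#' @export
edit_distance <- function(s1, s2) {
  if (grepl("[^ACGTN]", s1) || grepl("[^ACGTN]", s2)) {
    stop("sequences must be normalized first (see normalize_sequence)", call. = FALSE)
  }
  .edit_distance_cpp(s1, s2)
}

#' Read lineage reference sequences from FASTA
#'
#' Headers follow `lineage|name` (e.g. `A|ref_A`); the part before the first
#' `|` is the lineage label.
#'
#' @param path FASTA file.
#' @return Data frame `lineage, name, sequence` (sequences normalized).
#' @export
read_reference_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(lineage = vapply(parts, `[`, character(1), 1L),
             name = vapply(parts, function(p) paste(p[-1], collapse = "|"),
                           character(1)),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""),
                 character(1))
  vapply(seqs, normalize_sequence, character(1))
}

write_fasta <- function(seqs, path) {
  dna <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Classify a sequence to its nearest-lineage reference
#'
#' Assigns the lineage of the reference sequence at minimum edit distance.
#' When two or more lineages tie for the minimum the call is ambiguous: the
#' lineage is `"unknown"` and the flag is set.
#'
#' @param query normalized DNA string.
#' @param references data frame `lineage, name, sequence` (as from
#'   [read_reference_fasta()]) or a named character vector (names =
#'   lineage labels).
#' @return List: `lineage`, `distance`, `ambiguous`.
#' @export
classify_lineage <- function(query, references) {
  if (is.character(references)) {
    references <- data.frame(lineage = names(references),
                             name = names(references),
                             sequence = unname(references),
                             stringsAsFactors = FALSE)
  }
  if (!nrow(references)) stop("empty reference set", call. = FALSE)
  d <- vapply(references$sequence, function(ref) .edit_distance_cpp(query, ref),
              integer(1))
  dmin <- min(d)
  lins <- unique(references$lineage[d == dmin])
  if (length(lins) > 1L) {
    list(lineage = "unknown", distance = dmin, ambiguous = TRUE)
  } else {
    list(lineage = lins, distance = dmin, ambiguous = FALSE)
  }
}

#' Classify many colony sequences
#'
#' @param sequences named character vector (names = colony ids) of normalized
#'   sequences.
#' @param references as in [classify_lineage()].
#' @return Data frame `colony_id, lineage, distance, ambiguous`.
#' @export
classify_colonies <- function(sequences, references) {
  rows <- lapply(seq_along(sequences), function(i) {
    cl <- classify_lineage(sequences[[i]], references)
    data.frame(colony_id = names(sequences)[i], lineage = cl$lineage,
               distance = cl$distance, ambiguous = cl$ambiguous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deduplicate colony sequences into haplotypes
#'
#' Groups colonies whose normalized sequences match exactly. Haplotype ids
#' are assigned by count (descending), ties broken by first appearance in the
#' input, so ids are stable under input reordering up to count ties.
#'
#' @param sequences data frame `colony_id, sequence` (optionally `lineage`),
#'   or a named character vector (names = colony ids).
#' @return Data frame of class `haplotype_records`: `haplotype_id, sequence,
#'   lineage, count` plus a list column `member_colony_ids`. The lineage of a
#'   record is its members' shared label (`"unknown"` if members disagree or
#'   no labels were supplied).
#' @export
dedupe_haplotypes <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- data.frame(colony_id = names(sequences),
                            sequence = unname(sequences),
                            stringsAsFactors = FALSE)
  }
  sequences$sequence <- vapply(sequences$sequence, normalize_sequence,
                               character(1))
  has_lineage <- "lineage" %in% names(sequences)
  groups <- split(seq_len(nrow(sequences)),
                  factor(sequences$sequence, levels = unique(sequences$sequence)))
  counts <- lengths(groups)
  first_seen <- vapply(groups, min, integer(1))
  ord <- order(-counts, first_seen)
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    lin <- "unknown"
    if (has_lineage) {
      labs <- unique(sequences$lineage[idx])
      if (length(labs) == 1L && !is.na(labs)) lin <- labs
    }
    data.frame(haplotype_id = sprintf("H%d", i),
               sequence = sequences$sequence[idx[1]],
               lineage = lin, count = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$member_colony_ids <- I(lapply(groups, function(idx) sequences$colony_id[idx]))
  class(out) <- c("haplotype_records", "data.frame")
  out
}

#' Build a parsimony-style haplotype network
#'
#' Computes all pairwise edit distances between haplotypes, discards pairs
#' farther apart than `max_steps` mutational steps, and retains a
#' minimum-total-distance spanning forest of the remaining graph (Kruskal via
#' [igraph::mst()]). Non-forest edges that could replace a forest edge at
#' equal total weight (weight equal to the maximum weight on the forest path
#' between their endpoints) are retained too, flagged as alternates.
#' Connected components are the parsimony-connected haplotype groups.
#'
#' @param records a `haplotype_records` data frame from [dedupe_haplotypes()].
#' @param max_steps maximum mutational steps for a connection (default 10;
#'   stands in for a statistical-parsimony connection limit).
#' @return A list of class `haplotype_network`: `records`, `edges` (data
#'   frame `h1, h2, steps, alternate_flag`), `membership` (component id per
#'   haplotype), `n_components`, `max_steps`, `spanning_weight`.
#' @export
build_network <- function(records, max_steps = 10L) {
  n <- nrow(records)
  if (n < 1L) stop("need at least one haplotype record", call. = FALSE)
  ids <- records$haplotype_id
  if (n == 1L) {
    return(structure(list(records = records,
                          edges = data.frame(h1 = character(0), h2 = character(0),
                                             steps = integer(0),
                                             alternate_flag = logical(0)),
                          membership = setNames(1L, ids), n_components = 1L,
                          max_steps = as.integer(max_steps),
                          spanning_weight = 0),
                     class = "haplotype_network"))
  }
  D <- .edit_distance_matrix_cpp(records$sequence)
  pairs <- which(upper.tri(D) & D <= max_steps, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
               weight = D[pairs]),
    directed = FALSE, vertices = data.frame(name = ids))
  forest <- igraph::mst(g, weights = igraph::E(g)$weight)
  fe <- igraph::as_data_frame(forest, what = "edges")
  in_forest <- paste(pmin(fe$from, fe$to), pmax(fe$from, fe$to)) # unordered key
  edge_df <- igraph::as_data_frame(g, what = "edges")
  edge_key <- paste(pmin(edge_df$from, edge_df$to), pmax(edge_df$from, edge_df$to))
  keep <- edge_key %in% in_forest
  # tied alternates: non-forest edge whose weight equals the max forest-edge
  # weight on the path between its endpoints (swapping preserves total weight)
  alt <- logical(nrow(edge_df))
  for (i in which(!keep)) {
    path <- igraph::shortest_paths(forest, edge_df$from[i], edge_df$to[i],
                                   output = "epath")$epath[[1]]
    if (length(path) && edge_df$weight[i] == max(igraph::E(forest)$weight[path])) {
      alt[i] <- TRUE
    }
  }
  retained <- keep | alt
  edges <- data.frame(h1 = edge_df$from[retained], h2 = edge_df$to[retained],
                      steps = as.integer(edge_df$weight[retained]),
                      alternate_flag = alt[retained], stringsAsFactors = FALSE)
  comp <- igraph::components(g)
  structure(list(records = records, edges = edges,
                 membership = setNames(comp$membership[ids], ids),
                 n_components = comp$no,
                 max_steps = as.integer(max_steps),
                 spanning_weight = sum(fe$weight)),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d haplotypes, %d edges (%d alternates), %d component(s), max_steps=%d\n",
              nrow(x$records), nrow(x$edges), sum(x$edges$alternate_flag),
              x$n_components, x$max_steps))
  invisible(x)
}

#' Apiary-level mitochondrial Africanization
#'
#' The percentage of colonies in each apiary carrying an African-lineage (A)
#' mtDNA haplotype, computed over colonies with a known lineage; colonies
#' classified `unknown` are excluded from the denominator. Apiaries with no
#' known-lineage colony get `NA` with a warning.
#'
#' @param colony_lineages data frame `colony_id, apiary_id, lineage`.
#' @return Data frame `apiary_id, n_colonies, n_known, pct_african`, ordered
#'   by apiary id.
#' @export
mito_africanization <- function(colony_lineages) {
  needed <- c("colony_id", "apiary_id", "lineage")
  if (!all(needed %in% names(colony_lineages))) {
    stop("colony_lineages needs columns colony_id, apiary_id, lineage", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(colony_lineages,
                                     colony_lineages$apiary_id), function(g) {
    known <- g$lineage %in% LINEAGES_MITO
    pct <- if (any(known)) 100 * sum(g$lineage[known] == "A") / sum(known) else NA_real_
    data.frame(apiary_id = g$apiary_id[1], n_colonies = nrow(g),
               n_known = sum(known), pct_african = pct, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$apiary_id), , drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out$pct_african)) {
    warning(sprintf("apiary(ies) with no known-lineage colonies: %s",
                    paste(out$apiary_id[is.na(out$pct_african)], collapse = ", ")),
            call. = FALSE)
  }
  out
}
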