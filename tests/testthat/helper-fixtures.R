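# Small in-code fixtures shared across test files.

make_panel <- function(freqA, freqM, freqC, ids = sprintf("s%d", seq_along(freqA))) {
  lineage_panel(ids, rbind(freqA, freqM, freqC), c("A", "M", "C"))
}

# a panel where every SNP has identical frequencies across lineages:
# the likelihood is constant on the simplex
flat_panel <- function(L = 5, p = 0.5) {
  make_panel(rep(p, L), rep(p, L), rep(p, L))
}

make_colony <- function(counts, panel, n_alleles = 40L, id = "c1", ...) {
  colony_observation(id, counts, panel, n_alleles = n_alleles, ...)
}

random_instance <- function(L, n_alleles = 40L) {
  panel <- make_panel(runif(L), runif(L), runif(L))
  counts <- sample(0:n_alleles, L, replace = TRUE)
  list(panel = panel,
       colony = make_colony(counts, panel, n_alleles = n_alleles))
}

random_simplex <- function() {
  x <- -log(runif(3))
  x / sum(x)
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

refs_df <- function(seqs) {
  data.frame(lineage = names(seqs), name = names(seqs),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}
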