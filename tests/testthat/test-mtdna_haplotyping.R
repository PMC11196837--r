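test_that("sequence normalization uppercases, strips gaps and rejects junk", {
  expect_identical(normalize_sequence("acgt"), "ACGT")
  expect_identical(normalize_sequence("AC-GT"), "ACGT")
  expect_identical(normalize_sequence("acNg-t"), "ACNGT")
  expect_error(normalize_sequence("ACXT"), "position 3")
  expect_error(normalize_sequence(""), "non-empty")
})

test_that("edit distance matches a DP oracle and utils::adist on plain sequences", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "ACCT"), 1L)
  expect_equal(edit_distance("ACGT", "ACGTT"), 1L)
  expect_equal(edit_distance("GATTACA", "GCATGCT"), 4L)
  # N matches anything at zero cost
  expect_equal(edit_distance("ANGT", "ACGT"), 0L)
  expect_equal(edit_distance("NNNN", "ACGT"), 0L)
  set.seed(31)
  for (i in 1:40) {
    a <- random_dna(sample(10:30, 1), c("A", "C", "G", "T", "N"))
    b <- random_dna(sample(10:30, 1), c("A", "C", "G", "T", "N"))
    expect_identical(edit_distance(a, b), oracle_edit_distance(a, b))
  }
  # third, independent route on N-free strings: base R generalized Levenshtein
  for (i in 1:20) {
    a <- random_dna(sample(10:30, 1))
    b <- random_dna(sample(10:30, 1))
    expect_identical(edit_distance(a, b), as.integer(utils::adist(a, b)))
  }
})

test_that("edit distance is a metric on N-free sequences", {
  set.seed(32)
  for (i in 1:60) {
    s <- replicate(3, random_dna(sample(8:25, 1)))
    d12 <- edit_distance(s[1], s[2]); d13 <- edit_distance(s[1], s[3])
    d23 <- edit_distance(s[2], s[3])
    expect_identical(d12, edit_distance(s[2], s[1]))
    expect_identical(edit_distance(s[1], s[1]), 0L)
    expect_lte(d13, d12 + d23)
    if (s[1] != s[2]) expect_gt(d12, 0L)
  }
})

test_that("lineage classification picks the nearest reference and flags ties", {
  refs <- refs_df(c(A = "AAAAAAAA", C = "CCCCCCCC", M = "GGGGGGGG"))
  hit <- classify_lineage("AAAAAAAA", refs)
  expect_identical(hit, list(lineage = "A", distance = 0L, ambiguous = FALSE))
  near <- classify_lineage("AAAAAACC", refs)
  expect_identical(near$lineage, "A")
  expect_equal(near$distance, 2L)
  tie <- classify_lineage("AAAACCCC", refs)
  expect_identical(tie$lineage, "unknown")
  expect_true(tie$ambiguous)
  expect_error(classify_lineage("AAAA", refs[0, ]), "empty")
})

test_that("simulated colonies classify back to their true maternal lineage", {
  cfg <- simulation_config(seed = 33, n_colonies = 40,
                           between_lineage_substitutions = 10L,
                           within_lineage_mutations = 2L)
  haps <- simulate_haplotypes(cfg)
  refs <- data.frame(lineage = sub("[|].*$", "", names(haps$references)),
                     name = names(haps$references),
                     sequence = unname(haps$references))
  calls <- classify_colonies(haps$colonies, refs)
  expect_identical(calls$lineage, unname(haps$maternal_lineages))
  expect_false(any(calls$ambiguous))
})

test_that("haplotype deduplication conserves counts and is order-invariant", {
  seqs <- c(c1 = "AAAA", c2 = "CCCC", c3 = "AAAA", c4 = "GGGG", c5 = "TTTT")
  rec <- dedupe_haplotypes(seqs)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$count, c(2L, 1L, 1L, 1L))
  expect_identical(rec$haplotype_id[1], "H1")
  expect_setequal(rec$member_colony_ids[[1]], c("c1", "c3"))
  expect_equal(sum(rec$count), length(seqs))

  all_same <- dedupe_haplotypes(setNames(rep("ACGT", 7), paste0("k", 1:7)))
  expect_equal(nrow(all_same), 1L)
  expect_equal(all_same$count, 7L)

  set.seed(34)
  shuffled <- seqs[sample(length(seqs))]
  rec2 <- dedupe_haplotypes(shuffled)
  expect_identical(sort(rec2$sequence), sort(rec$sequence))
  expect_identical(rec2$count, rec$count)
  expect_identical(rec2$sequence[1], "AAAA")  # the count-2 haplotype stays H1

  # normalization happens before grouping; lineage labels propagate
  df <- data.frame(colony_id = c("x", "y"), sequence = c("ac-gt", "ACGT"),
                   lineage = c("A", "A"))
  expect_equal(dedupe_haplotypes(df)$count, 2L)
  expect_identical(dedupe_haplotypes(df)$lineage, "A")
})

test_that("network retains a minimum spanning structure under the step limit", {
  rec1 <- dedupe_haplotypes(c(c1 = "AAAA"))
  net1 <- build_network(rec1)
  expect_equal(nrow(net1$edges), 0L)
  expect_equal(net1$n_components, 1L)

  # d(H1,H2)=1, d(H2,H3)=2, d(H1,H3)=3: MST keeps {H1-H2, H2-H3}
  rec3 <- dedupe_haplotypes(c(a = "AAAAAA", b = "AAAAAC", c = "AAACCC"))
  net3 <- build_network(rec3)
  keyed <- paste(pmin(net3$edges$h1, net3$edges$h2),
                 pmax(net3$edges$h1, net3$edges$h2))
  expect_setequal(keyed[!net3$edges$alternate_flag], c("H1 H2", "H2 H3"))
  expect_equal(net3$spanning_weight, 3)
  expect_equal(net3$spanning_weight,
               oracle_min_spanning_weight(.edit_distance_matrix_cpp(rec3$sequence), 10L))

  # pairs beyond max_steps split into components
  far <- dedupe_haplotypes(c(a = "AAAAAAAAAAAA", b = "CCCCCCCCCCCC"))
  net_far <- build_network(far, max_steps = 10L)
  expect_equal(net_far$n_components, 2L)
  expect_equal(nrow(net_far$edges), 0L)
  expect_true(all(net_far$edges$steps <= 10L))
})

test_that("network spanning weight equals exhaustive enumeration on random fixtures", {
  set.seed(35)
  for (rep in 1:6) {
    n <- sample(3:7, 1)
    seqs <- setNames(replicate(n, random_dna(12)), paste0("c", seq_len(n)))
    rec <- dedupe_haplotypes(seqs)
    max_steps <- sample(3:12, 1)
    net <- build_network(rec, max_steps = max_steps)
    D <- .edit_distance_matrix_cpp(rec$sequence)
    expect_equal(net$spanning_weight, oracle_min_spanning_weight(D, max_steps))
    expect_true(all(net$edges$steps <= max_steps))
    # alternates never reduce the forest weight: each has weight equal to the
    # heaviest forest edge it could replace, so total is unchanged
    expect_true(all(net$edges$steps[net$edges$alternate_flag] >= 1L))
  }
})

test_that("mitochondrial Africanization is the share of A haplotypes per apiary", {
  df <- data.frame(colony_id = sprintf("c%d", 1:8),
                   apiary_id = c(rep("ap1", 5), rep("ap2", 2), "ap3"),
                   lineage = c("A", "A", "A", "A", "C", "C", "M", "unknown"))
  expect_warning(out <- mito_africanization(df), "ap3")
  expect_equal(out$pct_african[out$apiary_id == "ap1"], 80)
  expect_equal(out$pct_african[out$apiary_id == "ap2"], 0)
  expect_true(is.na(out$pct_african[out$apiary_id == "ap3"]))
  expect_equal(out$n_known, c(5L, 2L, 0L))

  # unknowns shrink the denominator rather than counting as non-African
  df2 <- data.frame(colony_id = c("x", "y", "z"), apiary_id = "ap",
                    lineage = c("A", "unknown", "unknown"))
  expect_equal(mito_africanization(df2)$pct_african, 100)
})
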