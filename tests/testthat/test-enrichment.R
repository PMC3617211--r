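# Worked toy example: pathway {A..E}, stringent negatives A-B, A-C, D-E,
# complex {D, E}. Counts (3, 1), proportion (3-1)/10 = 0.2.
toy_pathway <- gene_set("toy", c("A", "B", "C", "D", "E"))
toy_complex <- gene_set("cx1", c("D", "E"))
toy_neg <- toy_negatives(list(c("A", "B"), c("A", "C"), c("D", "E")))

test_that("the stringent negative filter keeps, drops and deduplicates", {
  records <- tibble::tibble(
    gene_a = c("A", "A", "B", "C", "C"),
    gene_b = c("B", "C", "A", "D", "E"),
    epsilon = c(-0.2, -0.05, -0.3, -0.2, -0.2),
    p_value = c(0.01, 0.01, 0.001, 0.2, 0.01)
  )
  kept <- filter_negative(records, epsilon_max = -0.12, p_max = 0.05)
  # (A,C) too mild, (C,D) p too high; (A,B)/(B,A) deduplicated to most negative
  expect_equal(nrow(kept), 2)
  ab <- kept[kept$gene_a == "A" & kept$gene_b == "B", ]
  expect_equal(ab$epsilon, -0.3)
  expect_true(all(kept$gene_a < kept$gene_b))

  expect_error(filter_negative(records, epsilon_max = 0.1), "negative")
  expect_error(
    filter_negative(dplyr::mutate(records, gene_b = gene_a)),
    "self-interactions"
  )
})

test_that("within-pathway counts match the hand count and the brute-force oracle", {
  counts <- within_pathway_counts(toy_neg, toy_pathway$gene, toy_complex)
  expect_equal(counts, c(n_neg_within = 3L, n_neg_within_complex = 1L))

  oracle <- brute_force_enrichment(toy_neg, toy_pathway$gene, toy_complex)
  expect_equal(unname(counts["n_neg_within"]), oracle$n_neg_within)
  expect_equal(unname(counts["n_neg_within_complex"]), oracle$n_neg_within_complex)
  expect_equal(
    normalized_proportion(counts["n_neg_within"] - counts["n_neg_within_complex"], 5),
    c(n_neg_within = 0.2)
  )

  # empty negatives and pairs straddling the pathway boundary
  expect_equal(
    within_pathway_counts(toy_neg[0, ], toy_pathway$gene, toy_complex),
    c(n_neg_within = 0L, n_neg_within_complex = 0L)
  )
  straddle <- toy_negatives(list(c("A", "Z")))
  expect_equal(
    within_pathway_counts(straddle, toy_pathway$gene, NULL)[["n_neg_within"]],
    0L
  )
})

test_that("the normalization follows S(S-1)/2", {
  expect_equal(normalized_proportion(27, 20), 27 / 190)
  expect_equal(normalized_proportion(0, 10), 0)
  expect_error(normalized_proportion(1, 1), "size < 2")
})

test_that("pathway ranking sorts, filters and breaks ties as documented", {
  pathways <- dplyr::bind_rows(
    toy_pathway,
    gene_set("quiet", c("U", "V", "W", "X", "Y", "Z"))
  )
  ranked <- rank_pathways(toy_neg, pathways, toy_complex)
  expect_equal(ranked$pathway, "toy") # quiet pathway: 0 < 1% filter
  expect_equal(ranked$n_neg_within, 3L)
  expect_equal(ranked$n_neg_excl_complex, 2L)
  expect_equal(ranked$normalized_proportion, 0.2)

  # all below the display filter -> empty table
  expect_equal(nrow(rank_pathways(toy_neg[0, ], pathways, toy_complex)), 0)

  # ties: equal proportion, larger pathway first, then identifier
  neg2 <- toy_negatives(list(c("A", "B"), c("U", "V"), c("U", "W"), c("V", "W")))
  tied <- dplyr::bind_rows(
    gene_set("b_small", c("A", "B")), # 1/1 = 1
    gene_set("a_small", c("U", "V")), # 1/1 = 1 (U-V)
    gene_set("big", c("U", "V", "W")) # 3/3 = 1
  )
  ranked2 <- rank_pathways(neg2, tied, NULL)
  expect_equal(ranked2$pathway, c("big", "a_small", "b_small"))
})

test_that("results are invariant under swapping gene_a and gene_b", {
  swapped <- dplyr::rename(toy_neg, gene_a = gene_b, gene_b = gene_a)
  expect_equal(
    within_pathway_counts(swapped, toy_pathway$gene, toy_complex),
    within_pathway_counts(toy_neg, toy_pathway$gene, toy_complex)
  )
  expect_equal(
    rank_pathways(swapped, toy_pathway, toy_complex),
    rank_pathways(toy_neg, toy_pathway, toy_complex)
  )
})

test_that("random toys agree with the brute-force recount oracle", {
  set.seed(99)
  genes <- LETTERS[1:15]
  for (rep in 1:10) {
    pw <- sample(genes, 8)
    cx <- gene_set("cx", sample(pw, 3))
    all_pairs <- t(utils::combn(genes, 2))
    take <- sample(nrow(all_pairs), 20)
    neg <- tibble::tibble(
      gene_a = all_pairs[take, 1], gene_b = all_pairs[take, 2],
      epsilon = -0.3, p_value = 0.001
    )
    counts <- within_pathway_counts(neg, pw, cx)
    oracle <- brute_force_enrichment(neg, pw, cx)
    expect_equal(unname(counts["n_neg_within"]), oracle$n_neg_within)
    expect_equal(
      unname(counts["n_neg_within_complex"]),
      oracle$n_neg_within_complex
    )
    expect_lte(counts["n_neg_within_complex"], counts["n_neg_within"])
    expect_equal(
      normalized_proportion(
        counts[["n_neg_within"]] - counts[["n_neg_within_complex"]],
        length(pw)
      ),
      oracle$proportion
    )
  }
})

test_that("the complex fraction counts pairs once across pathways", {
  expect_equal(complex_fraction(toy_neg, toy_pathway, toy_complex), 1 / 3)
  expect_equal(complex_fraction(toy_neg, toy_pathway, NULL), 0)
  # duplicated pathway membership must not double-count the global tally
  double_pw <- dplyr::bind_rows(
    toy_pathway, gene_set("toy2", toy_pathway$gene)
  )
  expect_equal(complex_fraction(toy_neg, double_pw, toy_complex), 1 / 3)
  outside <- toy_negatives(list(c("Q", "Z")))
  expect_error(complex_fraction(outside, toy_pathway, toy_complex), "undefined")
})

test_that("interaction tables and gene sets round-trip through disk formats", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "int.tsv")
  readr::write_tsv(toy_neg, tsv)
  expect_equal(read_interactions(tsv), toy_neg, ignore_attr = TRUE)

  gmt <- file.path(dir, "sets.gmt")
  sets <- dplyr::bind_rows(toy_pathway, toy_complex)
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_setequal(back$set_id, c("toy", "cx1"))
  expect_equal(
    sort(back$gene[back$set_id == "toy"]),
    sort(toy_pathway$gene)
  )
  writeLines("only_two_fields\tdesc", gmt)
  expect_error(read_gmt(gmt), "malformed")
})
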