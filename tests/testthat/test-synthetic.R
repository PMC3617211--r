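test_that("reference rate sets sit in the stated normal regimes", {
  refs <- reference_ratesets()
  expect_equal(classify_baseline(refs$NR)$label, "NR")
  expect_equal(classify_baseline(refs$NF)$label, "NF")
  for (r in refs) {
    expect_gt(r[["k1"]], r[["k_m1"]]) # forward faster than backward
    expect_gt(r[["k2"]], r[["k_m2"]])
  }
  # F2 knockout of the fragile reference leaves P^s = 0.01/0.13
  f2_ko <- apply_perturbations(refs$NF, perturbation("F2", "KNOCKOUT"))
  expect_equal(limiting_state(f2_ko)[["P"]], 0.01 / 0.13, tolerance = 1e-9)
})

test_that("screen configs reject infeasible layouts", {
  expect_error(screen_config(n_genes = 10, pathway_sizes = c(8, 8)), "universe")
  expect_error(
    screen_config(pathway_sizes = c(5), complex_sizes = list(c(4, 3))),
    "complexes exceed"
  )
  expect_error(screen_config(p_bg = 0.5, p_wp = 0.1), "p_bg <= p_wp")
  expect_error(
    screen_config(pathway_sizes = c(10), complex_sizes = list(2),
      planted_pathways = 3),
    "planted"
  )
})

test_that("the generator is reproducible from its seed", {
  config <- screen_config(
    n_genes = 60, pathway_sizes = c(12, 10),
    complex_sizes = list(4, integer(0))
  )
  a <- simulate_interaction_screen(config, seed = 11)
  b <- simulate_interaction_screen(config, seed = 11)
  expect_identical(a, b)
  c <- simulate_interaction_screen(config, seed = 12)
  expect_false(identical(a$interactions, c$interactions))

  # byte-identical on disk too
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_screen(a, dir_a)
  write_screen(b, dir_b)
  for (f in c("interactions.tsv", "pathways.gmt", "complexes.gmt", "truth.tsv")) {
    expect_identical(
      readLines(file.path(dir_a, f)),
      readLines(file.path(dir_b, f))
    )
  }
})

test_that("degenerate rates give exact pair counts", {
  # p_bg = 0, p_wp = 1, one planted pathway of size 5: exactly C(5,2) negatives
  config <- screen_config(
    n_genes = 30, pathway_sizes = 5, complex_sizes = list(integer(0)),
    p_bg = 0, p_wp = 1, null_fraction = 0
  )
  screen <- simulate_interaction_screen(config, seed = 4)
  expect_equal(nrow(screen$interactions), 10)
  pw_genes <- screen$pathways$gene
  expect_true(all(screen$interactions$gene_a %in% pw_genes))
  expect_true(all(screen$interactions$gene_b %in% pw_genes))
  # and every emitted epsilon passes the stringent filter
  expect_equal(nrow(filter_negative(screen$interactions)), 10)
})

test_that("expected proportions follow the closed form", {
  # no complexes: Bernoulli mean
  cfg <- screen_config(
    n_genes = 50, pathway_sizes = c(10, 10), planted_pathways = 1,
    complex_sizes = list(integer(0), integer(0)), p_wp = 0.2
  )
  ep <- expected_proportions(cfg)
  expect_equal(ep$expected_proportion, c(0.2, cfg$p_bg))
  expect_equal(ep$planted, c(TRUE, FALSE))

  # complex covering the whole pathway: everything excluded
  cfg2 <- screen_config(
    n_genes = 20, pathway_sizes = 6, complex_sizes = list(6),
    p_wp = 0.3, p_c = 1
  )
  expect_equal(expected_proportions(cfg2)$expected_proportion, 0)

  # inversion of the S(S-1)/2 normalization: expected count 27 on a size-20
  # pathway needs p_wp = 27/190
  cfg3 <- screen_config(
    n_genes = 40, pathway_sizes = 20, complex_sizes = list(integer(0)),
    p_wp = 27 / 190
  )
  ep3 <- expected_proportions(cfg3)
  expect_equal(ep3$expected_proportion * ep3$n_pairs, 27)

  # null model: planted rate equal to background
  cfg4 <- screen_config(
    n_genes = 40, pathway_sizes = c(8, 8), planted_pathways = 1,
    complex_sizes = list(integer(0), integer(0)), p_bg = 0.05, p_wp = 0.05
  )
  expect_equal(
    expected_proportions(cfg4)$expected_proportion,
    c(0.05, 0.05)
  )
})

test_that("emitted files parse cleanly through the enrichment readers", {
  config <- screen_config(
    n_genes = 60, pathway_sizes = c(12, 10),
    complex_sizes = list(4, 3), planted_pathways = 1:2
  )
  dir <- withr::local_tempdir()
  write_screen(simulate_interaction_screen(config, seed = 2), dir)
  expect_no_warning({
    interactions <- read_interactions(file.path(dir, "interactions.tsv"))
    pathways <- read_gmt(file.path(dir, "pathways.gmt"))
    complexes <- read_gmt(file.path(dir, "complexes.gmt"))
  })
  expect_equal(sort(unique(pathways$set_id)), c("pw01", "pw02"))
  expect_equal(sort(unique(complexes$set_id)), c("pw01_cx01", "pw02_cx01"))
  expect_true(all(complexes$gene %in% pathways$gene))
  ranked <- rank_pathways(filter_negative(interactions), pathways, complexes)
  expect_true(all(c("pw01", "pw02") %in% ranked$pathway))
})
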