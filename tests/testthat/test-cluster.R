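test_that("DRE clustering chains neighbours within the gap", {
  dres <- tibble::tibble(dre_id = c("a", "b", "c"), chrom = "chr1",
                         start = c(0L, 4000L, 20000L),
                         end = c(100L, 4100L, 20100L))
  cl <- cluster_dres(dres, gap = 5000)
  expect_equal(cl$cluster_id, c("dcl_00001", "dcl_00001", "dcl_00002"))

  single <- cluster_dres(dres[1, ])
  expect_equal(single$cluster_id, "dcl_00001")

  # a chain 4 kb apart stays one cluster regardless of total span
  chain <- tibble::tibble(dre_id = sprintf("d%02d", 1:20), chrom = "chr1",
                          start = seq(0L, by = 4200L, length.out = 20))
  chain$end <- chain$start + 100L
  expect_equal(length(unique(cluster_dres(chain)$cluster_id)), 1)

  # clusters never span chromosomes, even at coordinate 0 on both
  two <- tibble::tibble(dre_id = c("x", "y"), chrom = c("chr1", "chr2"),
                        start = c(0L, 0L), end = c(100L, 100L))
  expect_equal(length(unique(cluster_dres(two)$cluster_id)), 2)
})

test_that("clustering equals the transitive closure of the pairwise-gap relation", {
  withr::with_seed(41, {
    dres <- rand_intervals(500, c("chr1", "chr2", "chr3"), 400000, c(50, 300))
    dres$dre_id <- sprintf("d%03d", 1:500)
    got <- cluster_dres(dres, gap = 5000)
    comp <- oracle_cluster(got, gap = 5000)  # same row order as got
    # identical partitions: cluster labels are a bijection of components
    expect_equal(length(unique(got$cluster_id)), length(unique(comp)))
    expect_true(all(tapply(comp, got$cluster_id,
                           function(x) length(unique(x))) == 1))
  })
})

test_that("cluster summaries report spans, members and target unions", {
  dres <- tibble::tibble(dre_id = c("a", "b", "c"), chrom = "chr1",
                         start = c(0L, 3000L, 50000L),
                         end = c(100L, 3100L, 50100L))
  preds <- tibble::tibble(dre_id = c("a", "b", "b", "c"),
                          gene_id = c("g1", "g1", "g2", "g3"))
  summ <- cluster_summary(cluster_dres(dres), preds)
  expect_equal(summ$start, c(0L, 50000L))
  expect_equal(summ$end, c(3100L, 50100L))
  expect_equal(summ$members[[1]], c("a", "b"))
  expect_equal(summ$target_genes[[1]], c("g1", "g2"))
  expect_equal(summ$n_targets, c(2L, 1L))
})

test_that("information content is computed from descendant-inclusive counts", {
  corpus <- toy_corpus(min_genes = 1)
  td <- tidy(corpus)
  ic <- setNames(td$ic, td$term)
  expect_equal(ic[["root"]], 0)            # every gene sits under the root
  expect_equal(ic[["a"]], log(2))          # 2 of 4 genes under 'a'
  expect_equal(ic[["b"]], log(4))
  # IC never decreases from parent to child
  expect_true(ic[["a"]] >= ic[["root"]] && ic[["b"]] >= ic[["a"]])
})

test_that("Resnik similarity is the IC of the best common ancestor", {
  corpus <- toy_corpus(min_genes = 1)
  expect_equal(resnik_similarity(corpus, "g1", "g2"), log(2))
  expect_equal(resnik_similarity(corpus, "g1", "g3"), 0)  # only root shared
  expect_equal(resnik_similarity(corpus, "g1", "g1"), log(4))
  expect_true(is.na(resnik_similarity(corpus, "g1", "nosuch")))
  # symmetry and self-dominance
  expect_equal(resnik_similarity(corpus, "g2", "g1"),
               resnik_similarity(corpus, "g1", "g2"))
  for (g in c("g2", "g3")) {
    expect_gte(resnik_similarity(corpus, "g1", "g1"),
               resnik_similarity(corpus, "g1", g))
  }
})

test_that("corpus building drops IEA evidence and under-annotated terms", {
  terms <- tibble::tibble(
    term = c("root", "a", "b"),
    name = c("r", "a", "b"), namespace = "biological_process",
    parents = list(character(0), "root", "a"), obsolete = FALSE)
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g4"),
    term = c("b", "b", "b", "root", "b"),
    evidence = c("EXP", "EXP", "IEA", "EXP", "IEA"))
  corpus <- build_go_corpus(terms, ann, min_genes = 3)
  # g3's only (IEA) annotation is gone; b keeps g1/g2 -> under min_genes
  expect_false("g3" %in% corpus$universe)
  expect_false(any(c("b") %in% unlist(corpus$gene_terms)))
  cyc <- tibble::tibble(term = c("x", "y"), name = c("x", "y"),
                        namespace = "biological_process",
                        parents = list("y", "x"), obsolete = FALSE)
  expect_error(build_go_corpus(cyc, ann[4, ]), "cycle")
})

test_that("mean pairwise scores skip undefined pairs and distance-filtered pairs", {
  corpus <- toy_corpus(min_genes = 1)
  fn <- resnik_metric(corpus)
  expect_equal(mean_pairwise_score(c("g1", "g2", "g3"), fn),
               mean(c(log(2), 0, 0)))
  # undefined pairs are skipped, not zeroed
  expect_equal(mean_pairwise_score(c("g1", "g2", "nosuch"), fn),
               mean_pairwise_score(c("g1", "g2"), fn))
  positions <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                              start = c(0L, 100000L), end = c(10000L, 110000L))
  expect_true(is.na(mean_pairwise_score(c("g1", "g2"), fn,
                                        positions = positions,
                                        min_gap = 500000)))
})

test_that("observed curves are direct proportions and controls behave null", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c2"),
    target_genes = list(c("g1", "g2", "g3"), c("g2", "g3", "g4")))
  corpus <- toy_corpus(min_genes = 1)
  res <- cluster_score_curves(clusters, "resnik", corpus = corpus,
                              cutoffs = c(0.1, 0.5), n_controls = 0,
                              min_targets = 3)
  m1 <- mean_pairwise_score(c("g1", "g2", "g3"), resnik_metric(corpus))
  m2 <- mean_pairwise_score(c("g2", "g3", "g4"), resnik_metric(corpus))
  expect_equal(res$curves$observed, c(mean(c(m1, m2) > 0.1),
                                      mean(c(m1, m2) > 0.5)))
  expect_true(is.na(res$p_value))

  # degenerate corpus where every pair scores identically: p ~ 1
  terms <- tibble::tibble(term = c("root", "m"), name = c("r", "m"),
                          namespace = "biological_process",
                          parents = list(character(0), "root"),
                          obsolete = FALSE)
  ann <- tibble::tibble(gene_id = sprintf("g%02d", 1:12), term = "m",
                        evidence = "EXP")
  flat <- build_go_corpus(terms, ann, min_genes = 1)
  res2 <- cluster_score_curves(
    tibble::tibble(cluster_id = "c1", target_genes = list(c("g01", "g02", "g03"))),
    "resnik", corpus = flat, cutoffs = c(-1, 0.5), n_controls = 50, seed = 2)
  expect_gt(res2$p_value, 0.5)
})

test_that("coexpression curves use expression-profile correlation", {
  withr::with_seed(6, {
    latent <- rnorm(20)
    expr <- rbind(
      m1 = latent + rnorm(20, sd = 0.2),
      m2 = latent + rnorm(20, sd = 0.2),
      m3 = latent + rnorm(20, sd = 0.2),
      r1 = rnorm(20), r2 = rnorm(20), r3 = rnorm(20), r4 = rnorm(20),
      r5 = rnorm(20), r6 = rnorm(20))
    clusters <- tibble::tibble(cluster_id = "c1",
                               target_genes = list(c("m1", "m2", "m3")))
    res <- cluster_score_curves(clusters, "coexpression", expression = expr,
                                cutoffs = c(0.5), n_controls = 40, seed = 3)
    expect_equal(res$curves$observed, 1)
    expect_lt(res$curves$control_mean, 0.5)
    expect_lt(res$p_value, 0.2)
  })
})
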