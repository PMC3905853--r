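test_that("identical configs and seeds give byte-identical bundles", {
  cfg <- simulate_config(n_chromosomes = 2, chrom_length = 1.5e6, n_genes = 12,
                         n_dhs = 70, go_modules = 3, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("every emitted file parses back through the package readers", {
  cfg <- simulate_config(n_chromosomes = 2, chrom_length = 1.5e6, n_genes = 12,
                         n_dhs = 70, go_modules = 3, seed = 5)
  dir <- withr::local_tempdir()
  b <- simulate_dataset(cfg, dir = dir)
  back <- read_bundle(dir)
  expect_equal(back$genes, b$genes)
  expect_equal(back$dhs[c("chrom", "start", "end", "name")],
               b$dhs[c("chrom", "start", "end", "name")])
  expect_equal(nrow(back$blocks), nrow(b$blocks))
  expect_equal(back$contacts$pos1, b$contacts$pos1)
  expect_equal(back$truth$true_pairs, b$truth$true_pairs)
  expect_equal(unname(back$expression), unname(b$expression),
               tolerance = 1e-9)
})

test_that("planted structure follows the configuration", {
  b <- small_bundle()
  cfg <- b$config
  expect_equal(nrow(b$genes), cfg$n_genes)
  expect_equal(nrow(b$dhs), cfg$n_dhs)
  # every true pair is distal: different chromosome or gap > 500 kb
  tp <- b$truth$true_pairs
  di <- match(tp$dre_id, b$dhs$name)
  gi <- match(tp$gene_id, b$genes$gene_id)
  same <- b$dhs$chrom[di] == b$genes$chrom[gi]
  gaps <- pmax(pmax(b$genes$start[gi] - b$dhs$end[di],
                    b$dhs$start[di] - b$genes$end[gi]), 0)
  expect_true(all(!same | gaps > 5e5))

  zero <- simulate_dataset(simulate_config(
    n_chromosomes = 2, chrom_length = 1.5e6, n_genes = 12, n_dhs = 70,
    fraction_true_pairs = 0, go_modules = 3, seed = 9))
  expect_equal(nrow(zero$truth$true_pairs), 0)
})

test_that("rho_true = 1 with no jitter copies presence vectors exactly", {
  b <- simulate_dataset(simulate_config(
    n_chromosomes = 2, chrom_length = 1.5e6, n_genes = 12, n_dhs = 70,
    rho_true = 1, align_jitter = 0, go_modules = 3, seed = 31))
  run <- run_dre_pipeline(b)
  tp <- pair_pcc(b$truth$true_pairs, run$dre_profiles, run$gene_profiles)
  expect_true(all(is.na(tp$pcc) | tp$pcc > 1 - 1e-9))
})

test_that("realised presence correlation of true pairs tracks rho_true", {
  for (rho in c(0.5, 0.9)) {
    cfg <- simulate_config(n_chromosomes = 4, chrom_length = 3e6,
                           n_genes = 40, n_dhs = 400,
                           fraction_true_pairs = 0.9, rho_true = rho,
                           lambda_signal = 0, lambda_noise = 0, seed = 77)
    b <- simulate_dataset(cfg)
    cl <- classify_dhs(b$dhs, b$genes)
    bins <- build_bins(b$blocks)
    dp <- region_profiles(dre_profile_regions(dre_table(cl)), bins)
    gp <- region_profiles(gene_profile_regions(b$genes), bins)
    tp <- pair_pcc(b$truth$true_pairs, dp, gp)
    expect_gt(nrow(tp), 200)
    expect_lt(abs(mean(tp$pcc, na.rm = TRUE) - rho), 0.1)
  }
})

test_that("per-pair contact counts are Poisson with the configured mean", {
  cfg <- simulate_config(n_chromosomes = 4, chrom_length = 3e6, n_genes = 40,
                         n_dhs = 400, fraction_true_pairs = 0.9,
                         lambda_signal = 5, lambda_noise = 0, seed = 19)
  b <- simulate_dataset(cfg)
  # reconstruct per-(true pair, dataset) totals from the emitted contacts
  tp <- b$truth$true_pairs
  di <- match(tp$dre_id, b$dhs$name)
  counts <- integer(0)
  for (ds in b$roster$dataset_id) {
    cc <- b$contacts[b$contacts$dataset_id == ds, ]
    for (i in seq_len(nrow(tp))) {
      hit <- cc$chrom1 == b$dhs$chrom[di[i]] &
        cc$pos1 >= b$dhs$start[di[i]] & cc$pos1 < b$dhs$end[di[i]]
      counts <- c(counts, sum(hit))
    }
  }
  expect_gte(length(counts), 1000)
  expect_lt(abs(mean(counts) - 5), 0.25)
  # chi-square goodness of fit against Poisson(5), tail-pooled
  brk <- c(-0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, Inf)
  obs <- table(cut(counts, brk))
  p <- diff(ppois(c(-1, 1, 2, 3, 4, 5, 6, 7, 8, Inf), lambda = 5))
  chi2 <- sum((as.numeric(obs) - length(counts) * p)^2 / (length(counts) * p))
  expect_gt(pchisq(chi2, df = length(p) - 1, lower.tail = FALSE), 0.01)
})

test_that("prediction scoring implements set-overlap metrics", {
  truth <- tibble::tibble(dre_id = c("a", "b", "c", "d"),
                          gene_id = c("g1", "g2", "g3", "g4"))
  preds <- tibble::tibble(dre_id = c("a", "b", "x"),
                          gene_id = c("g1", "g2", "g9"))
  s <- score_predictions(preds, truth)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 0.5)
  perfect <- score_predictions(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- score_predictions(preds[0, ], truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
})

test_that("infeasible configurations fail before writing anything", {
  dir <- file.path(tempdir(), "never_written")
  expect_error(
    simulate_dataset(simulate_config(n_chromosomes = 1, chrom_length = 2e5,
                                     n_genes = 5, n_dhs = 40), dir = dir),
    "infeasible")
  expect_false(dir.exists(dir))
})
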