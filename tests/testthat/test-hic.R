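mk_contacts <- function(ds, chrom1, pos1, chrom2, pos2) {
  tibble::tibble(dataset_id = ds, chrom1 = chrom1, pos1 = as.integer(pos1),
                 chrom2 = chrom2, pos2 = as.integer(pos2))
}

dres1 <- tibble::tibble(dre_id = "dre1", chrom = "chr1",
                        start = 1000L, end = 1200L)
intr1 <- tibble::tibble(
  gene_id = "g1", dhs_id = c("A", "B"), chrom = "chr2",
  start = c(50000L, 80000L), end = c(50150L, 80150L),
  center = c(50075L, 80075L))

test_that("pair counts take the maximum over intragenic DHS", {
  cc <- mk_contacts("d", "chr1", c(1100, 1150, 1010, 1020),
                    "chr2", c(50075, 50900, 49300, 80090))
  out <- count_pair_reads(cc, dres1, intr1, flank = 1000)
  expect_equal(nrow(out), 1)       # max rule: one row per (dre, gene, dataset)
  expect_equal(out$count, 3L)      # DHS A caught 3 reads, B caught 1
  expect_equal(out$best_dhs, "A")

  # swapped end ordering counts the same
  swapped <- mk_contacts("d", cc$chrom2, cc$pos2, cc$chrom1, cc$pos1)
  expect_equal(count_pair_reads(swapped, dres1, intr1)$count, 3L)

  # adding a weaker DHS never changes the pair count
  intr_plus <- dplyr::bind_rows(intr1, tibble::tibble(
    gene_id = "g1", dhs_id = "C", chrom = "chr2", start = 120000L,
    end = 120150L, center = 120075L))
  cc2 <- dplyr::bind_rows(cc, mk_contacts("d", "chr1", 1005, "chr2", 120080))
  expect_equal(count_pair_reads(cc2, dres1, intr_plus)$count, 3L)
})

test_that("contacts with both ends in one DRE or genes without DHS give no pair", {
  both <- mk_contacts("d", "chr1", 1100, "chr1", 1150)
  expect_equal(nrow(count_pair_reads(both, dres1, intr1)), 0)
  no_dhs <- intr1[0, ]
  cc <- mk_contacts("d", "chr1", 1100, "chr2", 50075)
  expect_equal(nrow(count_pair_reads(cc, dres1, no_dhs)), 0)
})

test_that("counting matches the quadratic brute-force oracle", {
  withr::with_seed(31, {
    dres <- rand_intervals(8, c("chr1", "chr2"), 50000, c(100, 400))
    dres$dre_id <- sprintf("dre%02d", 1:8)
    dres <- dres[c("dre_id", "chrom", "start", "end")]
    intr <- rand_intervals(12, c("chr1", "chr2"), 50000, c(100, 200))
    intr$gene_id <- sample(sprintf("g%d", 1:5), 12, replace = TRUE)
    intr$dhs_id <- sprintf("dhs%02d", 1:12)
    intr$center <- (intr$start + intr$end) %/% 2L
    cc <- mk_contacts(sample(c("d1", "d2"), 300, replace = TRUE),
                      sample(c("chr1", "chr2"), 300, replace = TRUE),
                      sample.int(50000, 300, replace = TRUE),
                      sample(c("chr1", "chr2"), 300, replace = TRUE),
                      sample.int(50000, 300, replace = TRUE))
    got <- count_pair_reads(cc, dres, intr, flank = 1000)
    want <- oracle_pair_counts(cc, dres, intr, flank = 1000)
    expect_equal(nrow(got), nrow(want))
    got_o <- got[order(got$dre_id, got$gene_id, got$dataset_id), ]
    expect_equal(got_o$count, want$count)
    expect_equal(got_o$dre_id, want$dre_id)
    expect_equal(got_o$gene_id, want$gene_id)
  })
})

test_that("uniform read ends give a flat density ratio near 1", {
  withr::with_seed(8, {
    targets <- tibble::tibble(chrom = "chr1",
                              start = seq(50000L, 950000L, by = 45000L))
    targets$end <- targets$start + 200L
    pts <- tibble::tibble(chrom = "chr1",
                          pos = sample.int(1000000L, 200000L, replace = TRUE))
    prof <- density_profile(targets, pts, half_width = 1000, step = 100)
    expect_true(all(abs(prof$ratio - 1) < 0.25))
    expect_equal(prof$offset, -prof$offset[rev(seq_len(nrow(prof)))])
  })
})

test_that("density profile counts windows directly around a single target", {
  targets <- tibble::tibble(chrom = "chr1", start = 99900L, end = 100100L)
  # 4 reads at the center, one background read at +6 kb
  pts <- tibble::tibble(chrom = "chr1", pos = c(rep(100000L, 4), 106000L))
  prof <- density_profile(targets, pts, half_width = 100, step = 50)
  bg <- 1 / 10000
  expect_equal(prof$ratio[prof$offset == 0], (4 / 50) / bg)
  expect_equal(prof$ratio[prof$offset == 100], 0)
  expect_equal(attr(prof, "n_targets"), 1L)
})

test_that("density profile fails without background or contacts", {
  targets <- tibble::tibble(chrom = "chr1", start = 99900L, end = 100100L)
  pts <- tibble::tibble(chrom = "chr1", pos = rep(100000L, 4))
  expect_error(density_profile(targets, pts), "zero background")
  expect_error(density_profile(targets, pts[0, ]), "no contact ends")
  expect_error(density_profile(targets[0, ], pts), "no targets")
})

test_that("the max rule decouples pair counts from the number of intragenic DHS", {
  # one true looping anchor per gene with fixed signal, plus a weak background
  # at every DHS; the sum rule inflates with DHS count, the max rule must not
  withr::with_seed(77, {
    n_genes <- 500
    dres <- tibble::tibble(dre_id = sprintf("dre%03d", 1:n_genes),
                           chrom = "chr1",
                           start = seq(0L, by = 10000L, length.out = n_genes))
    dres$end <- dres$start + 200L
    intr_rows <- list(); cc_rows <- list()
    sums <- integer(n_genes)
    n_dhs_per_gene <- sample(1:8, n_genes, replace = TRUE)
    for (g in seq_len(n_genes)) {
      k <- n_dhs_per_gene[g]
      centers <- 10000000L + g * 50000L + (0:(k - 1)) * 3000L
      intr_rows[[g]] <- tibble::tibble(
        gene_id = sprintf("g%03d", g), dhs_id = sprintf("w%03d_%d", g, 1:k),
        chrom = "chr2", start = centers - 75L, end = centers + 75L,
        center = centers)
      reads_per_dhs <- rpois(k, 0.4)           # background on every DHS
      reads_per_dhs[1] <- reads_per_dhs[1] + 5L # fixed signal at the anchor
      sums[g] <- sum(reads_per_dhs)
      for (j in which(reads_per_dhs > 0)) {
        cc_rows[[length(cc_rows) + 1]] <- mk_contacts(
          "d", "chr1", rep(dres$start[g] + 100L, reads_per_dhs[j]),
          "chr2", rep(centers[j], reads_per_dhs[j]))
      }
    }
    counts <- count_pair_reads(dplyr::bind_rows(cc_rows), dres,
                               dplyr::bind_rows(intr_rows))
    per_gene <- counts$count[match(sprintf("g%03d", seq_len(n_genes)),
                                   counts$gene_id)]
    per_gene[is.na(per_gene)] <- 0L
    rho_max <- suppressWarnings(
      cor(n_dhs_per_gene, per_gene, method = "spearman"))
    rho_sum <- suppressWarnings(
      cor(n_dhs_per_gene, sums, method = "spearman"))
    expect_lt(abs(rho_max), 0.1)
    expect_gt(rho_sum, 0.5)
  })
})
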