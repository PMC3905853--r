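mk_blocks <- function(df, species) {
  df$species <- factor(df$species, levels = species)
  df[c("species", "chrom", "start", "end")]
}

test_that("bin boundaries come from block endpoints with binary indicators", {
  blocks <- mk_blocks(tibble::tibble(
    species = c("sp1", "sp2"), chrom = "chr1",
    start = c(0L, 50L), end = c(100L, 150L)), c("sp1", "sp2"))
  bins <- build_bins(blocks)
  expect_equal(bins$start, c(0L, 50L, 100L))
  expect_equal(bins$end, c(50L, 100L, 150L))
  expect_equal(bins$sp1, c(1L, 1L, 0L))
  expect_equal(bins$sp2, c(0L, 1L, 1L))

  one <- build_bins(mk_blocks(tibble::tibble(
    species = "sp1", chrom = "chr1", start = 0L, end = 100L), "sp1"))
  expect_equal(nrow(one), 1)
  expect_equal(one$sp1, 1L)

  expect_equal(nrow(build_bins(mk_blocks(
    tibble::tibble(species = character(), chrom = character(),
                   start = integer(), end = integer()), "sp1"))), 0)
})

test_that("bins are disjoint and cover exactly the union of blocks", {
  withr::with_seed(5, {
    species <- c("sp1", "sp2", "sp3")
    blocks <- rand_intervals(30, c("chrA", "chrB"), 8000, c(50, 2000))
    blocks$species <- sample(species, 30, replace = TRUE)
    blocks <- mk_blocks(blocks, species)
    bins <- build_bins(blocks)
    for (ch in c("chrA", "chrB")) {
      bb <- bins[bins$chrom == ch, ]
      # disjoint
      if (nrow(bb) > 1) {
        expect_true(all(bb$start[-1] >= bb$end[-nrow(bb)]))
      }
      # per-base coverage oracle
      cov_bins <- rep(FALSE, 10000)
      for (i in seq_len(nrow(bb))) cov_bins[(bb$start[i] + 1):bb$end[i]] <- TRUE
      bl <- blocks[blocks$chrom == ch, ]
      cov_blocks <- rep(FALSE, 10000)
      for (i in seq_len(nrow(bl))) cov_blocks[(bl$start[i] + 1):bl$end[i]] <- TRUE
      expect_equal(cov_bins, cov_blocks)
    }
  })
})

test_that("region profiles are length-weighted bin averages over the region", {
  species <- c("sp1", "sp2")
  blocks <- mk_blocks(tibble::tibble(
    species = c("sp1", "sp1", "sp2"), chrom = "chr1",
    start = c(0L, 100L, 100L), end = c(100L, 400L, 400L)), species)
  bins <- build_bins(blocks)
  r <- region_profiles(tibble::tibble(owner_id = "r1", chrom = "chr1",
                                      start = 0L, end = 400L), bins)
  expect_equal(r$sp1, 1.0)
  expect_equal(r$sp2, 0.75)   # (100*0 + 300*1) / 400

  # single-bin identity and all-zero outside the aligned territory
  r2 <- region_profiles(tibble::tibble(
    owner_id = c("in", "out"), chrom = "chr1",
    start = c(100L, 5000L), end = c(400L, 5100L)), bins)
  expect_equal(unlist(r2[1, c("sp1", "sp2")], use.names = FALSE), c(1, 1))
  expect_equal(unlist(r2[2, c("sp1", "sp2")], use.names = FALSE), c(0, 0))

  expect_error(region_profiles(tibble::tibble(
    owner_id = "bad", chrom = "chr1", start = 10L, end = 10L), bins), "invalid")
})

test_that("region profiles match the per-base coverage oracle", {
  withr::with_seed(17, {
    species <- sprintf("sp%d", 1:4)
    blocks <- rand_intervals(40, c("chr1", "chr2"), 9000, c(30, 1500))
    blocks$species <- sample(species, 40, replace = TRUE)
    blocks <- mk_blocks(blocks, species)
    bins <- build_bins(blocks)
    regions <- rand_intervals(50, c("chr1", "chr2"), 9500, c(20, 800))
    regions$owner_id <- sprintf("r%02d", seq_len(nrow(regions)))
    prof <- region_profiles(regions, bins)
    m <- profile_matrix(prof)
    for (i in seq_len(nrow(regions))) {
      want <- oracle_region_profile(regions$chrom[i], regions$start[i],
                                    regions$end[i], blocks, species)
      expect_lt(max(abs(m[regions$owner_id[i], ] - want)), 1e-12)
    }
  })
})

test_that("splitting a bin at an interior point leaves profiles unchanged", {
  species <- c("sp1", "sp2")
  blocks <- mk_blocks(tibble::tibble(
    species = c("sp1", "sp2"), chrom = "chr1",
    start = c(0L, 200L), end = c(500L, 700L)), species)
  # refine by adding a block boundary at 350 that changes no coverage
  refined <- mk_blocks(tibble::tibble(
    species = c("sp1", "sp1", "sp2", "sp2"), chrom = "chr1",
    start = c(0L, 350L, 200L, 350L), end = c(350L, 500L, 350L, 700L)), species)
  regions <- tibble::tibble(owner_id = c("a", "b"), chrom = "chr1",
                            start = c(100L, 0L), end = c(600L, 700L))
  p1 <- region_profiles(regions, build_bins(blocks))
  p2 <- region_profiles(regions, build_bins(refined))
  expect_equal(profile_matrix(p1), profile_matrix(p2), tolerance = 1e-14)
})

test_that("profile PCC follows the textbook formula and flags undefined cases", {
  expect_equal(profile_pcc(c(1, 0.5, 0, 0.25), c(0.9, 0.4, 0.1, 0.2)),
               0.987135294792748, tolerance = 1e-12)
  expect_equal(profile_pcc(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_true(is.na(profile_pcc(c(0.5, 0.5, 0.5), c(1, 0, 1))))
  expect_error(profile_pcc(c(1, 0), c(1, 0, 1)), "length")
  # symmetry and invariance to affine rescaling of one input
  withr::with_seed(3, {
    a <- runif(45); b <- runif(45)
    expect_equal(profile_pcc(a, b), profile_pcc(b, a))
    expect_equal(profile_pcc(a, b), profile_pcc(a, 0.2 + 3 * b),
                 tolerance = 1e-12)
  })
})

test_that("vectorised pair PCC matches the scalar path", {
  withr::with_seed(9, {
    dp <- tibble::tibble(owner_id = c("d1", "d2"), region_length = 100)
    gp <- tibble::tibble(owner_id = c("g1", "g2"), region_length = 100)
    for (s in sprintf("sp%d", 1:6)) {
      dp[[s]] <- runif(2); gp[[s]] <- runif(2)
    }
    gp[2, sprintf("sp%d", 1:6)] <- as.list(rep(0.4, 6))  # constant profile
    pairs <- tidyr::expand_grid(dre_id = dp$owner_id, gene_id = gp$owner_id)
    got <- pair_pcc(pairs, dp, gp)
    dm <- profile_matrix(dp); gm <- profile_matrix(gp)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$pcc[i],
                   profile_pcc(dm[got$dre_id[i], ], gm[got$gene_id[i], ]))
    }
    expect_true(all(is.na(got$pcc[got$gene_id == "g2"])))
  })
})
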