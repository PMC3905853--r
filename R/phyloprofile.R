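#' Build the genome bin partition from alignment blocks
#'
#' The start and end positions of every alignment block (all species pooled)
#' cut each chromosome into consecutive non-overlapping candidate bins. A bin
#' is emitted iff at least one species has a block covering it; its profile is
#' the binary presence indicator across the species panel. Because every block
#' boundary is a bin boundary, a block either fully contains a bin or misses
#' it, so "covered" is unambiguous.
#'
#' @param blocks Alignment-block tibble from [read_alignment_blocks()]
#'   (`species` must be a factor whose levels fix the profile order).
#' @return A tibble with columns `chrom`, `start`, `end` followed by one 0/1
#'   integer column per species, in species order.
#' @export
build_bins <- function(blocks) {
  species <- if (is.factor(blocks$species)) levels(blocks$species) else
    unique(as.character(blocks$species))
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  for (sp in species) empty[[sp]] <- integer()
  if (nrow(blocks) == 0) return(empty)
  check_intervals(blocks, "alignment block")

  bins <- map(split(blocks, blocks$chrom), function(b) {
    bnd <- sort(unique(c(b$start, b$end)))
    tibble(chrom = b$chrom[1],
           start = bnd[-length(bnd)],
           end = bnd[-1])
  })
  bins <- bind_rows(bins)

  ov <- quiet_overlaps(as_granges0(bins), as_granges0(blocks))
  ind <- matrix(0L, nrow = nrow(bins), ncol = length(species),
                dimnames = list(NULL, species))
  sp_idx <- match(as.character(blocks$species), species)
  ind[cbind(queryHits(ov), sp_idx[subjectHits(ov)])] <- 1L

  keep <- rowSums(ind) > 0
  bins <- bins[keep, , drop = FALSE]
  out <- bind_cols_matrix(bins, ind[keep, , drop = FALSE])
  arrange(out, .data$chrom, .data$start)
}

bind_cols_matrix <- function(df, m) {
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- unname(m[, j])
  df
}

bin_species <- function(bins) setdiff(names(bins), c("chrom", "start", "end"))

#' Write / read the bin partition as TSV
#'
#' @param bins Bin tibble from [build_bins()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the bin tibble (reader).
#' @export
write_bins <- function(bins, path) {
  readr::write_tsv(bins, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Length-weighted phylogenetic profiles of sequence regions
#'
#' The profile of a region is the average of the binary bin profiles it
#' overlaps, weighted by the overlap length and divided by the *full region
#' length*: bases covered by no bin (human sequence with no homolog in any
#' species) contribute 0 to every species, so profiles are comparable across
#' regions regardless of how much of them aligns. Set
#' `denominator = "aligned"` to divide by the summed overlapped bin length
#' instead.
#'
#' @param regions Tibble with `owner_id`, `chrom`, `start`, `end` (see
#'   [gene_profile_regions()] / [dre_profile_regions()]).
#' @param bins Bin tibble from [build_bins()].
#' @param denominator `"region"` (default) or `"aligned"`.
#' @return A tibble with `owner_id`, `region_length`, then one numeric column
#'   per species with values in \[0, 1\].
#' @export
region_profiles <- function(regions, bins, denominator = c("region", "aligned")) {
  denominator <- arg_match(denominator)
  check_intervals(regions, "profile region")
  species <- bin_species(bins)
  ind <- as.matrix(bins[species])
  prof <- matrix(0, nrow = nrow(regions), ncol = length(species),
                 dimnames = list(NULL, species))
  rlen <- as.numeric(regions$end - regions$start)

  if (nrow(bins) > 0 && nrow(regions) > 0) {
    gr_r <- as_granges0(regions)
    gr_b <- as_granges0(bins)
    ov <- quiet_overlaps(gr_r, gr_b)
    if (length(ov) > 0) {
      q <- queryHits(ov); s <- subjectHits(ov)
      w <- GenomicRanges::width(pintersect(gr_r[q], gr_b[s]))
      contrib <- rowsum(ind[s, , drop = FALSE] * w, group = q, reorder = TRUE)
      rows <- as.integer(rownames(contrib))
      denom <- if (denominator == "region") rlen[rows] else
        as.numeric(rowsum(w, group = q, reorder = TRUE))
      prof[rows, ] <- contrib / denom
    }
  }
  out <- tibble(owner_id = regions$owner_id, region_length = rlen)
  bind_cols_matrix(out, prof)
}

#' Extract the profile value matrix from a profile tibble
#'
#' @param profiles Output of [region_profiles()].
#' @return Numeric matrix (owners x species) with `owner_id` rownames.
#' @export
profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[setdiff(names(profiles), c("owner_id", "region_length"))])
  rownames(m) <- profiles$owner_id
  m
}

#' Pearson correlation of two phylogenetic profiles
#'
#' Returns `NA` (rather than a coerced number) when either profile has zero
#' variance: a constant profile carries no correlation evidence either way,
#' and such pairs are excluded from prediction.
#'
#' @param a,b Numeric vectors of equal length (one value per species).
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
profile_pcc <- function(a, b) {
  if (length(a) != length(b)) abort("profiles have different lengths")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Profile correlation for a table of (DRE, gene) pairs
#'
#' Vectorised Pearson correlation between the DRE profile and the gene profile
#' of each pair. Pairs whose DRE or gene has a zero-variance (or missing)
#' profile get `NA`.
#'
#' @param pairs Tibble with `dre_id` and `gene_id` columns.
#' @param dre_profiles,gene_profiles Profile tibbles from [region_profiles()].
#' @return `pairs` with an added `pcc` column.
#' @export
pair_pcc <- function(pairs, dre_profiles, gene_profiles) {
  Am <- profile_matrix(dre_profiles)
  Bm <- profile_matrix(gene_profiles)
  miss <- setdiff(c(unique(pairs$dre_id)), rownames(Am))
  miss <- c(miss, setdiff(unique(pairs$gene_id), rownames(Bm)))
  if (length(miss) > 0) {
    abort(sprintf("no profile for: %s", paste(head(miss, 3), collapse = ", ")))
  }
  A <- Am[as.character(pairs$dre_id), , drop = FALSE]
  B <- Bm[as.character(pairs$gene_id), , drop = FALSE]
  if (ncol(A) != ncol(B)) abort("profiles have different species panels")
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  num <- rowSums(Ac * Bc)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  pcc <- ifelse(den > 0, num / den, NA_real_)
  pairs$pcc <- unname(pcc)
  pairs
}
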