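#' Classify DHS into DREs, intragenic and promoter-proximal sites
#'
#' A DHS overlapping at least one gene body is *intragenic* (this takes
#' precedence). Otherwise, if its distance to the nearest transcription start
#' site is at most `tss_flank` it is *promoter_proximal*; if that distance
#' exceeds `tss_flank` (or there is no gene on the chromosome) it is a *DRE*
#' (distal regulatory element). Distance is the minimum absolute distance in bp
#' from any base of the DHS interval to the TSS point.
#'
#' @param dhs Tibble of DHS peak intervals (`chrom`, `start`, `end`, and
#'   optionally `name`; names default to `dhs_00001`, ...).
#' @param genes Gene model tibble from [read_gene_table()].
#' @param tss_flank Maximum TSS distance (bp) for the promoter-proximal class.
#' @return A tibble with columns `dhs_id`, `chrom`, `start`, `end`,
#'   `category` (one of `"DRE"`, `"intragenic"`, `"promoter_proximal"`),
#'   `tss_distance` and `host_genes` (list column of gene ids overlapping the
#'   DHS; empty unless intragenic).
#' @export
classify_dhs <- function(dhs, genes, tss_flank = 2000) {
  if (nrow(genes) == 0) abort("gene table is empty")
  check_intervals(dhs, "DHS")
  dhs_id <- if ("name" %in% names(dhs)) dhs$name else
    sprintf("dhs_%05d", seq_len(nrow(dhs)))
  if (anyDuplicated(dhs_id)) abort("duplicate DHS identifiers")

  gr_dhs <- as_granges0(dhs)
  ov <- quiet_overlaps(gr_dhs, as_granges0(genes))
  hosts <- rep(list(character()), nrow(dhs))
  if (length(ov) > 0) {
    sp <- split(genes$gene_id[subjectHits(ov)], queryHits(ov))
    hosts[as.integer(names(sp))] <- map(sp, ~ sort(unique(.x)))
  }
  intragenic <- lengths(hosts) > 0

  # nearest-TSS distance per DHS, chromosome-matched; Inf with no gene there
  tss_dist <- rep(Inf, nrow(dhs))
  for (chr in unique(dhs$chrom)) {
    gi <- which(genes$chrom == chr)
    di <- which(dhs$chrom == chr)
    if (length(gi) == 0 || length(di) == 0) next
    tvec <- sort(genes$tss[gi])
    # nearest TSS to each of start and end-1 bounds the minimum over the interval
    nearest_to <- function(p) {
      idx <- findInterval(p, tvec)
      lo <- ifelse(idx >= 1, tvec[pmax(idx, 1)], NA_integer_)
      hi <- ifelse(idx < length(tvec), tvec[pmin(idx + 1L, length(tvec))], NA_integer_)
      pmin(abs(p - lo), abs(hi - p), na.rm = TRUE)
    }
    # distance = gap between the TSS point and the half-open DHS interval
    s <- dhs$start[di]; e <- dhs$end[di]
    inside <- map_lgl(di, function(j) {
      any(tvec >= dhs$start[j] & tvec <= dhs$end[j])
    })
    d <- pmin(nearest_to(s), nearest_to(e))
    d[inside] <- 0
    tss_dist[di] <- d
  }

  category <- case_when3(intragenic, tss_dist <= tss_flank)
  tibble(
    dhs_id = dhs_id,
    chrom = dhs$chrom, start = dhs$start, end = dhs$end,
    category = category,
    tss_distance = tss_dist,
    host_genes = hosts
  )
}

case_when3 <- function(intragenic, near_tss) {
  out <- rep("DRE", length(intragenic))
  out[near_tss] <- "promoter_proximal"
  out[intragenic] <- "intragenic"
  out
}

#' Extract the DRE subset of a classified DHS table
#'
#' @param classified Output of [classify_dhs()].
#' @return Tibble with `dre_id`, `chrom`, `start`, `end`.
#' @export
dre_table <- function(classified) {
  d <- filter(classified, .data$category == "DRE")
  tibble(dre_id = d$dhs_id, chrom = d$chrom, start = d$start, end = d$end)
}

#' Intragenic DHS per gene
#'
#' Returns one row per (gene, intragenic DHS) combination: a DHS overlapping
#' two gene bodies is listed under both hosts. `center` is the floor midpoint
#' of the DHS peak, the anchor for the Hi-C capture window on the gene side.
#'
#' @param classified Output of [classify_dhs()].
#' @param genes Optional gene table; when given, only these genes are kept and
#'   rows are ordered by gene then genomic position.
#' @return Tibble with `gene_id`, `dhs_id`, `chrom`, `start`, `end`, `center`.
#' @export
intragenic_dhs <- function(classified, genes = NULL) {
  intr <- filter(classified, .data$category == "intragenic")
  out <- tidyr::unnest(
    tibble(gene_id = intr$host_genes, dhs_id = intr$dhs_id,
           chrom = intr$chrom, start = intr$start, end = intr$end),
    "gene_id"
  )
  if (!is.null(genes)) out <- filter(out, .data$gene_id %in% genes$gene_id)
  out$center <- (out$start + out$end) %/% 2L
  arrange(out, .data$gene_id, .data$chrom, .data$start, .data$end)
}

#' Profile region of a gene
#'
#' The sequence region whose phylogenetic profile represents a gene: from
#' `upstream` bp before the TSS (strand-aware) to the gene end, clipped at
#' position 0.
#'
#' @param genes Gene model tibble.
#' @param upstream Upstream extension in bp (default 1000).
#' @return Tibble with `owner_id`, `chrom`, `start`, `end`.
#' @export
gene_profile_regions <- function(genes, upstream = 1000) {
  tibble(
    owner_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(pmax(ifelse(genes$strand == "+",
                                   genes$start - upstream, genes$start), 0)),
    end = as.integer(ifelse(genes$strand == "+",
                            genes$end, genes$end + upstream))
  )
}

#' Profile region of a DRE
#'
#' For a DRE the profile region is the DHS peak interval itself.
#'
#' @param dres DRE tibble from [dre_table()].
#' @return Tibble with `owner_id`, `chrom`, `start`, `end`.
#' @export
dre_profile_regions <- function(dres) {
  tibble(owner_id = dres$dre_id, chrom = dres$chrom,
         start = dres$start, end = dres$end)
}
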