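#' Assign markers to features by peak overlap
#'
#' A feature carries a marker when its assignment interval overlaps a peak of
#' that marker by at least 1 bp. For DREs the assignment interval is the peak
#' region itself; for genes use `gene_marker_intervals()` to build
#' promoter-anchored (`TSS +/- flank`) or gene-body intervals, with the marker
#' name suffixed `@promoter` / `@gene_body` so the two assignments stay
#' distinct in the marker vocabulary.
#'
#' @param features Tibble with `id`, `chrom`, `start`, `end`.
#' @param peaks Named list of peak tibbles (`chrom`, `start`, `end`), one per
#'   marker name.
#' @return Long tibble with columns `id`, `marker`.
#' @export
assign_markers <- function(features, peaks) {
  out <- imap(peaks, function(pk, marker) {
    if (nrow(pk) == 0) return(tibble(id = character(), marker = character()))
    ov <- quiet_overlaps(as_granges0(features), as_granges0(pk))
    tibble(id = unique(features$id[queryHits(ov)]), marker = marker)
  })
  bind_rows(out)
}

#' @rdname assign_markers
#' @param genes Gene model tibble.
#' @param where `"promoter"` or `"gene_body"`.
#' @param flank Promoter half-width around the TSS in bp (default 2000).
#' @export
gene_marker_intervals <- function(genes, where = c("promoter", "gene_body"),
                                  flank = 2000) {
  where <- arg_match(where)
  if (where == "promoter") {
    tibble(id = genes$gene_id, chrom = genes$chrom,
           start = pmax(genes$tss - as.integer(flank), 0L),
           end = genes$tss + as.integer(flank))
  } else {
    tibble(id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$end)
  }
}

#' Observed/expected enrichment of a marker combination among predicted pairs
#'
#' The observed fraction is the share of predicted pairs whose DRE carries
#' `dre_marker` and whose gene carries `gene_marker`. The expected fraction
#' under independence is the product of the marginal marker frequencies,
#' computed over the unique DREs and unique genes occurring in the pair set.
#' Significance comes from a 1-df chi-square statistic
#' `sum((O - E)^2 / E)` over the four marker-combination cells, with expected
#' counts from the marginal product (no continuity correction).
#'
#' @param pairs Tibble with `dre_id`, `gene_id` (predictions, or cluster-gene
#'   pairs with cluster ids in the `dre_id` column).
#' @param dre_markers,gene_markers Long marker tibbles from
#'   [assign_markers()] (`id`, `marker`).
#' @param dre_marker,gene_marker The marker combination to test.
#' @return One-row tibble: `dre_marker`, `gene_marker`, `observed`,
#'   `expected`, `ratio`, `chi2`, `p_value`, `n_pairs`.
#' @export
marker_enrichment <- function(pairs, dre_markers, gene_markers,
                              dre_marker, gene_marker) {
  if (nrow(pairs) == 0) abort("empty pair set")
  dre_has <- unique(dre_markers$id[dre_markers$marker == dre_marker])
  gene_has <- unique(gene_markers$id[gene_markers$marker == gene_marker])
  u_dre <- unique(pairs$dre_id)
  u_gene <- unique(pairs$gene_id)
  p1 <- mean(u_dre %in% dre_has)
  p2 <- mean(u_gene %in% gene_has)

  a <- pairs$dre_id %in% dre_has
  b <- pairs$gene_id %in% gene_has
  n <- nrow(pairs)
  obs_counts <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  exp_p <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  exp_counts <- n * exp_p

  observed <- obs_counts[1] / n
  expected <- exp_p[1]
  keep <- exp_counts > 0
  chi2 <- sum((obs_counts[keep] - exp_counts[keep])^2 / exp_counts[keep])
  p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(dre_marker = dre_marker, gene_marker = gene_marker,
         observed = observed, expected = expected,
         ratio = if (expected > 0) observed / expected else NA_real_,
         chi2 = chi2, p_value = p_value, n_pairs = n)
}

#' All marker combinations at once
#'
#' @inheritParams marker_enrichment
#' @param dre_marker_set,gene_marker_set Marker vocabularies to cross;
#'   default: every marker present in the corresponding assignment table.
#' @return Tibble with one [marker_enrichment()] row per combination.
#' @export
marker_enrichment_grid <- function(pairs, dre_markers, gene_markers,
                                   dre_marker_set = sort(unique(dre_markers$marker)),
                                   gene_marker_set = sort(unique(gene_markers$marker))) {
  grid <- tidyr::expand_grid(dre_marker = dre_marker_set,
                             gene_marker = gene_marker_set)
  bind_rows(pmap(grid, function(dre_marker, gene_marker) {
    marker_enrichment(pairs, dre_markers, gene_markers, dre_marker, gene_marker)
  }))
}

#' Call differentially expressed genes from a p/fold-change table
#'
#' A gene is differentially expressed when `p < p_cutoff` and its fold change
#' is `> fc_up` or `< fc_down`.
#'
#' @param de_table Tibble with `gene_id`, `p`, `fold_change`.
#' @param p_cutoff,fc_up,fc_down Rule parameters (defaults 0.05, 1.5, 0.7).
#' @return Character vector of DE gene ids.
#' @export
classify_de_genes <- function(de_table, p_cutoff = 0.05, fc_up = 1.5,
                              fc_down = 0.7) {
  de <- de_table$p < p_cutoff &
    (de_table$fold_change > fc_up | de_table$fold_change < fc_down)
  de_table$gene_id[de]
}

#' Differential-expression enrichment among TF-bound predicted targets
#'
#' Compares the differential-expression rate among all predicted target genes
#' with the rate among the subset whose predicted DRE is bound by a given TF,
#' via a two-sided Fisher's exact test on the 2x2 table (TF-bound vs not) x
#' (DE vs not) within the target set. An optional `exclude` set (e.g. genes
#' whose promoter is bound by the knocked-out TF itself) is removed from both
#' groups first.
#'
#' @param targets_all Genes with at least one predicted DRE.
#' @param targets_tf Subset of `targets_all` whose predicted DRE overlaps a TF
#'   peak.
#' @param de_genes Differentially expressed gene set
#'   (see [classify_de_genes()]).
#' @param exclude Optional genes to drop from both groups before testing.
#' @return One-row tibble: `n_all`, `n_tf`, `frac_de_all`, `frac_de_tf`,
#'   `odds_ratio`, `p_value`.
#' @export
de_enrichment <- function(targets_all, targets_tf, de_genes, exclude = NULL) {
  targets_all <- unique(targets_all)
  targets_tf <- intersect(unique(targets_tf), targets_all)
  if (!is.null(exclude)) {
    targets_all <- setdiff(targets_all, exclude)
    targets_tf <- setdiff(targets_tf, exclude)
  }
  if (length(targets_tf) == 0) abort("no TF-bound target genes after exclusion")
  de_all <- targets_all %in% de_genes
  is_tf <- targets_all %in% targets_tf
  tab <- matrix(c(sum(is_tf & de_all), sum(is_tf & !de_all),
                  sum(!is_tf & de_all), sum(!is_tf & !de_all)),
                nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble(n_all = length(targets_all), n_tf = length(targets_tf),
         frac_de_all = mean(de_all), frac_de_tf = mean(de_all[is_tf]),
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
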