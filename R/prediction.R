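#' Distance class of DRE-gene pairs
#'
#' Pairs on different chromosomes are `inter_chr`. Otherwise the gap is the
#' minimum distance in bp between the DRE interval and the gene body (0 when
#' they overlap): gaps above `far` are `distal_intra`, gaps in `(near, far]`
#' are `within_500kb`, and gaps at most `near` are `within_50kb`. Only
#' `inter_chr` and `distal_intra` pairs enter prediction; for closer pairs the
#' profile correlation is dominated by shared local genomic context rather
#' than by a regulatory relationship.
#'
#' @param pairs Tibble with `dre_id`, `gene_id`.
#' @param dres DRE tibble ([dre_table()]).
#' @param genes Gene model tibble.
#' @param far,near Distance thresholds in bp (defaults 500000 and 50000).
#' @return `pairs` with added `distance` (bp; `NA` for inter-chromosomal) and
#'   `distance_class` columns.
#' @export
distance_classify <- function(pairs, dres, genes, far = 500000, near = 50000) {
  di <- match(pairs$dre_id, dres$dre_id)
  gi <- match(pairs$gene_id, genes$gene_id)
  if (anyNA(di)) abort("pair refers to unknown dre_id")
  if (anyNA(gi)) abort("pair refers to unknown gene_id")
  same <- dres$chrom[di] == genes$chrom[gi]
  gap <- interval_gap(dres$start[di], dres$end[di],
                      genes$start[gi], genes$end[gi])
  pairs$distance <- ifelse(same, gap, NA_real_)
  pairs$distance_class <- case_when(
    !same ~ "inter_chr",
    gap > far ~ "distal_intra",
    gap > near ~ "within_500kb",
    TRUE ~ "within_50kb"
  )
  pairs
}

#' Assemble the canonical pair-annotation table
#'
#' Joins per-dataset Hi-C counts (wide, zero-filled as `n_<dataset>`), the
#' profile correlation and the distance class into one row per candidate
#' (DRE, gene) pair. A pair is a candidate iff it has at least one supporting
#' read in some dataset.
#'
#' @param counts Long count table from [count_pair_reads()].
#' @param dre_profiles,gene_profiles Profile tibbles ([region_profiles()]).
#' @param dres,genes Feature tables ([dre_table()], [read_gene_table()]).
#' @param datasets Character vector of all dataset ids (so datasets with no
#'   supporting read still get an `n_<dataset>` column of zeros).
#' @param far,near Passed to [distance_classify()].
#' @return Tibble with `dre_id`, `gene_id`, `pcc`, `distance`,
#'   `distance_class` and one `n_<dataset>` count column per dataset.
#' @export
pair_table <- function(counts, dre_profiles, gene_profiles, dres, genes,
                       datasets = sort(unique(counts$dataset_id)),
                       far = 500000, near = 50000) {
  pairs <- distinct(counts, .data$dre_id, .data$gene_id)
  wide <- counts %>%
    mutate(dataset_id = factor(.data$dataset_id, levels = datasets)) %>%
    select("dre_id", "gene_id", "dataset_id", "count") %>%
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "count",
                       names_prefix = "n_", values_fill = 0L,
                       names_expand = TRUE)
  out <- pairs %>%
    left_join(wide, by = c("dre_id", "gene_id")) %>%
    pair_pcc(dre_profiles, gene_profiles) %>%
    distance_classify(dres, genes, far = far, near = near)
  out[c("dre_id", "gene_id", "pcc", "distance", "distance_class",
        paste0("n_", datasets))]
}

count_cols <- function(pair_tbl) {
  names(pair_tbl)[startsWith(names(pair_tbl), "n_")]
}

#' Replicate repeatability of Hi-C annotated pairs
#'
#' For the two replicates of one cell line, the reference replicate is the one
#' with the lower total read count. Among the distal pairs whose count in the
#' reference replicate is at least `read_cutoff` and whose profile correlation
#' is at least `pcc_cutoff`, repeatability is the fraction confirmed by at
#' least one read in the other replicate (no cutoff on that side). A high
#' repeatability means the cutoff pair selects interactions unlikely to be
#' replicate-specific noise.
#'
#' @param pair_tbl Pair table from [pair_table()].
#' @param datasets Length-2 character vector: the two replicate dataset ids.
#' @param totals Named vector of total reads per dataset ([dataset_totals()]).
#' @param pcc_cutoff,read_cutoff Cutoffs applied to the reference replicate.
#' @param distal_only Keep only `inter_chr`/`distal_intra` pairs (default).
#' @return A list with `repeatability` (fraction, `NA` when no pair passes the
#'   cutoffs) and `n_pairs` (size of the cutoff-passing reference set).
#' @export
repeatability <- function(pair_tbl, datasets, totals, pcc_cutoff, read_cutoff,
                          distal_only = TRUE) {
  stopifnot(length(datasets) == 2)
  if (!all(datasets %in% names(totals))) {
    abort("totals must be named with both dataset ids")
  }
  ref <- datasets[which.min(totals[datasets])]
  other <- setdiff(datasets, ref)
  tbl <- pair_tbl
  if (distal_only) {
    tbl <- filter(tbl, .data$distance_class %in% c("inter_chr", "distal_intra"))
  }
  s <- filter(tbl,
              !is.na(.data$pcc), .data$pcc >= pcc_cutoff,
              .data[[paste0("n_", ref)]] >= read_cutoff)
  if (nrow(s) == 0) return(list(repeatability = NA_real_, n_pairs = 0L))
  confirmed <- s[[paste0("n_", other)]] >= 1
  list(repeatability = mean(confirmed), n_pairs = nrow(s))
}

#' Repeatability over a grid of PCC and read-count cutoffs
#'
#' Evaluates [repeatability()] on the Cartesian grid of cutoffs used to choose
#' the operating point: profile-correlation cutoffs 0.7/0.8/0.9 crossed with
#' read-count cutoffs 1/2/3 ("3 and more").
#'
#' @inheritParams repeatability
#' @param pcc_cutoffs,read_cutoffs Grid axes.
#' @return A tibble of class `repeatability_grid` with columns `pcc_cutoff`,
#'   `read_cutoff`, `n_pairs`, `repeatability` (NA where no pair passes).
#' @export
repeatability_grid <- function(pair_tbl, datasets, totals,
                               pcc_cutoffs = c(0.7, 0.8, 0.9),
                               read_cutoffs = c(1, 2, 3),
                               distal_only = TRUE) {
  grid <- tidyr::expand_grid(pcc_cutoff = pcc_cutoffs,
                             read_cutoff = read_cutoffs)
  res <- pmap(grid, function(pcc_cutoff, read_cutoff) {
    repeatability(pair_tbl, datasets, totals, pcc_cutoff, read_cutoff,
                  distal_only = distal_only)
  })
  grid$n_pairs <- map_int(res, "n_pairs")
  grid$repeatability <- map_dbl(res, "repeatability")
  class(grid) <- c("repeatability_grid", class(grid))
  attr(grid, "datasets") <- datasets
  grid
}

#' @export
tidy.repeatability_grid <- function(x, ...) as_tibble(x)

#' @export
glance.repeatability_grid <- function(x, pcc_cutoff = 0.8, read_cutoff = 2, ...) {
  row <- filter(as_tibble(x), .data$pcc_cutoff == !!pcc_cutoff,
                .data$read_cutoff == !!read_cutoff)
  tibble(pcc_cutoff = pcc_cutoff, read_cutoff = read_cutoff,
         repeatability = if (nrow(row)) row$repeatability else NA_real_,
         n_pairs = if (nrow(row)) row$n_pairs else NA_integer_)
}

#' @export
autoplot.repeatability_grid <- function(object, ...) {
  df <- as_tibble(object)
  df$read_cutoff <- factor(df$read_cutoff)
  ggplot(df, aes(x = .data$pcc_cutoff, y = .data$repeatability,
                 colour = .data$read_cutoff, group = .data$read_cutoff)) +
    geom_line() + geom_point() +
    labs(x = "PCC cutoff", y = "repeatability", colour = "read cutoff") +
    theme_bw()
}

#' Predict DRE-target gene pairs
#'
#' Within each cell line a distal candidate pair is accepted when its profile
#' correlation exceeds `pcc_cutoff` and either (count rule) some replicate has
#' strictly more than `read_cutoff` reads, or (rescue rule) every replicate of
#' the cell line has at least one read. The final prediction set is the union
#' over cell lines; `cell_lines` records where each pair was accepted and
#' `evidence` is `"count_rule"` if the count rule fired in any accepting cell
#' line, otherwise `"rescue_rule"`. Pairs with undefined correlation are never
#' accepted.
#'
#' @param pair_tbl Pair table from [pair_table()] (all datasets present).
#' @param roster Tibble with columns `dataset_id`, `cell_line`, `replicate`.
#' @param dres DRE tibble, used to attach the DRE locus to the output.
#' @param pcc_cutoff Correlation cutoff (strict, default 0.8).
#' @param read_cutoff Read-count cutoff (strict, default 2, i.e. >= 3 reads).
#' @return A tibble of class `dre_predictions`: `dre_id`, `chrom`, `start`,
#'   `end`, `gene_id`, `pcc`, `distance_class`, the `n_<dataset>` columns,
#'   `evidence`, `cell_lines` (comma-separated, sorted).
#' @export
predict_pairs <- function(pair_tbl, roster, dres,
                          pcc_cutoff = 0.8, read_cutoff = 2) {
  need <- paste0("n_", roster$dataset_id)
  if (!all(need %in% names(pair_tbl))) {
    abort(sprintf("pair table lacks count columns: %s",
                  paste(setdiff(need, names(pair_tbl)), collapse = ", ")))
  }
  cand <- filter(pair_tbl,
                 .data$distance_class %in% c("inter_chr", "distal_intra"),
                 !is.na(.data$pcc), .data$pcc > pcc_cutoff)
  cls <- split(roster$dataset_id, roster$cell_line)
  ev <- matrix("", nrow = nrow(cand), ncol = length(cls),
               dimnames = list(NULL, names(cls)))
  for (cl in names(cls)) {
    cnts <- as.matrix(cand[paste0("n_", cls[[cl]])])
    count_rule <- apply(cnts, 1, max) > read_cutoff
    rescue <- length(cls[[cl]]) >= 2 & apply(cnts, 1, min) >= 1
    ev[count_rule, cl] <- "count_rule"
    ev[!count_rule & rescue, cl] <- "rescue_rule"
  }
  accepted <- rowSums(ev != "") > 0
  out <- cand[accepted, , drop = FALSE]
  ev <- ev[accepted, , drop = FALSE]
  if (nrow(out) == 0) {
    out$evidence <- character(0)
    out$cell_lines <- character(0)
  } else {
    out$evidence <- apply(ev, 1, function(r) {
      if (any(r == "count_rule")) "count_rule" else "rescue_rule"
    })
    out$cell_lines <- apply(ev, 1, function(r) {
      paste(sort(names(r)[r != ""]), collapse = ",")
    })
  }
  di <- match(out$dre_id, dres$dre_id)
  out$chrom <- dres$chrom[di]; out$start <- dres$start[di]
  out$end <- dres$end[di]
  out <- out[c("dre_id", "chrom", "start", "end", "gene_id", "pcc",
               "distance_class", count_cols(pair_tbl), "evidence", "cell_lines")]
  out <- arrange(out, .data$chrom, .data$start, .data$end, .data$gene_id)
  class(out) <- c("dre_predictions", class(out))
  attr(out, "params") <- list(pcc_cutoff = pcc_cutoff, read_cutoff = read_cutoff)
  out
}
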