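#' Count Hi-C reads supporting (DRE, gene) pairs
#'
#' A contact supports a (DRE, gene, DHS) triple when one end lies inside the
#' DRE peak interval and the other end lies inside the capture window
#' `[center - flank, center + flank)` of an intragenic DHS of the gene; both
#' end orderings are accepted and a single contact may support several
#' triples, but it is counted at most once per triple. The per-dataset count
#' of a (DRE, gene) pair is the **maximum** over the gene's intragenic DHS of
#' the per-DHS counts (the sum would scale with the number of intragenic DHS
#' and hence with gene length); `best_dhs` records the DHS attaining the
#' maximum (ties broken by genomic position, then id).
#'
#' @param contacts Contact tibble (rows from all datasets bound together).
#' @param dres DRE tibble from [dre_table()].
#' @param intragenic Intragenic-DHS table from [intragenic_dhs()].
#' @param flank Half-width (bp) of the capture window around each intragenic
#'   DHS center (default 1000).
#' @return A tibble with one row per (DRE, gene, dataset) having at least one
#'   supporting read: `dre_id`, `gene_id`, `dataset_id`, `count`, `best_dhs`.
#' @export
count_pair_reads <- function(contacts, dres, intragenic, flank = 1000) {
  empty <- tibble(dre_id = character(), gene_id = character(),
                  dataset_id = character(), count = integer(),
                  best_dhs = character())
  if (nrow(contacts) == 0 || nrow(dres) == 0 || nrow(intragenic) == 0) {
    return(empty)
  }
  check_intervals(dres, "DRE")
  win <- tibble(chrom = intragenic$chrom,
                start = pmax(intragenic$center - as.integer(flank), 0L),
                end = intragenic$center + as.integer(flank))

  gr_dre <- as_granges0(dres)
  gr_win <- as_granges0(win)
  p1 <- points_granges(contacts$chrom1, contacts$pos1)
  p2 <- points_granges(contacts$chrom2, contacts$pos2)

  hits <- function(pts_dre, pts_win) {
    hd <- quiet_overlaps(pts_dre, gr_dre)
    hw <- quiet_overlaps(pts_win, gr_win)
    inner_join(
      tibble(contact = queryHits(hd), dre = subjectHits(hd)),
      tibble(contact = queryHits(hw), win = subjectHits(hw)),
      by = "contact", relationship = "many-to-many"
    )
  }
  events <- bind_rows(hits(p1, p2), hits(p2, p1))
  if (nrow(events) == 0) return(empty)
  events <- distinct(events, .data$contact, .data$dre, .data$win)

  per_dhs <- events %>%
    mutate(dataset_id = contacts$dataset_id[.data$contact],
           dre_id = dres$dre_id[.data$dre],
           gene_id = intragenic$gene_id[.data$win],
           dhs_id = intragenic$dhs_id[.data$win],
           dhs_start = intragenic$start[.data$win]) %>%
    count(.data$dataset_id, .data$dre_id, .data$gene_id, .data$dhs_id,
          .data$dhs_start, name = "count")

  per_dhs %>%
    arrange(.data$dataset_id, .data$dre_id, .data$gene_id,
            dplyr::desc(.data$count), .data$dhs_start, .data$dhs_id) %>%
    group_by(.data$dataset_id, .data$dre_id, .data$gene_id) %>%
    summarise(count = as.integer(first(.data$count)),
              best_dhs = first(.data$dhs_id), .groups = "drop") %>%
    select("dre_id", "gene_id", "dataset_id", "count", "best_dhs") %>%
    arrange(.data$dre_id, .data$gene_id, .data$dataset_id)
}

#' Flatten contacts into a table of mapped end points
#'
#' @param contacts Contact tibble.
#' @return Tibble with `chrom`, `pos` (two rows per contact).
#' @export
contact_points <- function(contacts) {
  tibble(chrom = c(contacts$chrom1, contacts$chrom2),
         pos = c(contacts$pos1, contacts$pos2))
}

#' Observed/background Hi-C read-density profile around target centers
#'
#' For each target interval, the background read density is the number of
#' contact ends falling in the distant flanks
#' `[c - bg_far, c - bg_near) U [c + bg_near, c + bg_far)` of the target
#' center `c`, divided by the total flank length. The observed density at
#' offset `o` is the number of ends in the window of width `window` centred at
#' `c + o`, divided by `window`. The observed/background ratio is averaged
#' over all targets with non-zero background.
#'
#' @param targets Tibble of target intervals (`chrom`, `start`, `end`).
#' @param points Contact end points from [contact_points()].
#' @param half_width Profile half-width in bp (offsets run from `-half_width`
#'   to `+half_width`).
#' @param window Smoothing window width in bp (default 50).
#' @param bg_near,bg_far Inner/outer bounds of the background flanks (bp).
#' @param step Offset spacing in bp (default 10; 1 reproduces a per-nucleotide
#'   profile).
#' @return A tibble of class `dre_density` with columns `offset`, `ratio`, and
#'   attribute `n_targets` (targets contributing, i.e. with background > 0).
#' @export
density_profile <- function(targets, points, half_width = 2000, window = 50,
                            bg_near = 5000, bg_far = 10000, step = 10) {
  if (nrow(targets) == 0) abort("no targets given")
  if (nrow(points) == 0) abort("no contact ends given")
  offsets <- seq(-half_width, half_width, by = step)
  hw <- window / 2
  pos_by_chrom <- map(split(points$pos, points$chrom), sort)

  count_in <- function(pos, lo, hi) {   # half-open [lo, hi), integer positions
    findInterval(hi - 1L, pos) - findInterval(lo - 1L, pos)
  }

  acc <- numeric(length(offsets))
  n_used <- 0L
  for (i in seq_len(nrow(targets))) {
    pos <- pos_by_chrom[[targets$chrom[i]]]
    if (is.null(pos)) next
    c0 <- (targets$start[i] + targets$end[i]) %/% 2L
    bg <- count_in(pos, c0 - bg_far, c0 - bg_near) +
      count_in(pos, c0 + bg_near, c0 + bg_far)
    if (bg == 0) next
    bg_den <- bg / (2 * (bg_far - bg_near))
    obs <- count_in(pos, c0 + offsets - hw, c0 + offsets + hw) / window
    acc <- acc + obs / bg_den
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    abort("density profile undefined: every target has zero background reads")
  }
  out <- tibble(offset = offsets, ratio = acc / n_used)
  class(out) <- c("dre_density", class(out))
  attr(out, "n_targets") <- n_used
  out
}

#' @describeIn density_profile Plot the observed/background density ratio
#'   against the offset from the target center.
#' @param object A `dre_density` tibble.
#' @param ... Unused.
#' @export
autoplot.dre_density <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$ratio)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line(colour = "#2c7fb8") +
    labs(x = "offset from target center (bp)",
         y = "observed / background read density") +
    theme_bw()
}
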