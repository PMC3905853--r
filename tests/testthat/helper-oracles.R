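# Independent brute-force oracles. These deliberately use naive loops and
# closed forms, never the package's own code paths, so agreement is evidence
# of correctness rather than of shared bugs.

tbl_genes <- function(...) {
  g <- tibble::tribble(...)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

# classification by pairwise scan: overlap with any gene body, else min
# distance from any DHS base to any TSS point
oracle_classify <- function(dhs, genes, tss_flank = 2000) {
  sapply(seq_len(nrow(dhs)), function(i) {
    s <- dhs$start[i]; e <- dhs$end[i]; ch <- dhs$chrom[i]
    overlap <- any(genes$chrom == ch & genes$start < e & s < genes$end)
    if (overlap) return("intragenic")
    tss <- genes$tss[genes$chrom == ch]
    if (length(tss) == 0) return("DRE")
    # gap between the TSS point and the half-open interval [s, e)
    d <- min(sapply(tss, function(t) max(s - t, t - e, 0)))
    if (d <= tss_flank) "promoter_proximal" else "DRE"
  })
}

# per-base coverage profile of a region over raw blocks
oracle_region_profile <- function(chrom, start, end, blocks, species) {
  vals <- sapply(species, function(sp) {
    b <- blocks[as.character(blocks$species) == sp & blocks$chrom == chrom, ]
    if (nrow(b) == 0) return(0)
    covered <- vapply(start:(end - 1), function(pos) {
      any(b$start <= pos & pos < b$end)
    }, logical(1))
    mean(covered)
  })
  unname(vals)
}

# quadratic contact-counting oracle: every contact x every (DRE, gene, DHS)
oracle_pair_counts <- function(contacts, dres, intragenic, flank = 1000) {
  res <- list()
  for (ci in seq_len(nrow(contacts))) {
    for (di in seq_len(nrow(dres))) {
      for (wi in seq_len(nrow(intragenic))) {
        in_dre <- function(ch, p) ch == dres$chrom[di] &&
          p >= dres$start[di] && p < dres$end[di]
        c0 <- intragenic$center[wi]
        in_win <- function(ch, p) ch == intragenic$chrom[wi] &&
          p >= c0 - flank && p < c0 + flank
        hit <- (in_dre(contacts$chrom1[ci], contacts$pos1[ci]) &&
                  in_win(contacts$chrom2[ci], contacts$pos2[ci])) ||
          (in_dre(contacts$chrom2[ci], contacts$pos2[ci]) &&
             in_win(contacts$chrom1[ci], contacts$pos1[ci]))
        if (hit) {
          res[[length(res) + 1]] <- data.frame(
            dataset_id = contacts$dataset_id[ci],
            dre_id = dres$dre_id[di],
            gene_id = intragenic$gene_id[wi],
            dhs_id = intragenic$dhs_id[wi])
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(dre_id = character(), gene_id = character(),
                      dataset_id = character(), count = integer()))
  }
  agg <- stats::aggregate(
    list(count = rep(1L, length(res))),
    by = do.call(rbind, res)[c("dre_id", "gene_id", "dataset_id", "dhs_id")],
    FUN = sum)
  # max over DHS per (dre, gene, dataset)
  out <- stats::aggregate(agg$count,
                          by = agg[c("dre_id", "gene_id", "dataset_id")],
                          FUN = max)
  names(out)[4] <- "count"
  out[order(out$dre_id, out$gene_id, out$dataset_id), ]
}

# rule-by-rule evaluator over every pair row
oracle_predict <- function(pair_tbl, roster, pcc_cutoff = 0.8, read_cutoff = 2) {
  keep <- logical(nrow(pair_tbl))
  for (i in seq_len(nrow(pair_tbl))) {
    row <- pair_tbl[i, ]
    if (!row$distance_class %in% c("inter_chr", "distal_intra")) next
    if (is.na(row$pcc) || row$pcc <= pcc_cutoff) next
    for (cl in unique(roster$cell_line)) {
      ds <- roster$dataset_id[roster$cell_line == cl]
      cnts <- as.numeric(row[paste0("n_", ds)])
      if (max(cnts) > read_cutoff) keep[i] <- TRUE
      if (length(cnts) >= 2 && all(cnts >= 1)) keep[i] <- TRUE
    }
  }
  pair_tbl[keep, c("dre_id", "gene_id")]
}

# transitive closure of the pairwise gap <= gap relation
oracle_cluster <- function(dres, gap = 5000) {
  n <- nrow(dres)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (dres$chrom[i] != dres$chrom[j]) next
        g <- max(dres$start[j] - dres$end[i], dres$start[i] - dres$end[j], 0)
        if (g <= gap && comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# two-sided Fisher p by full hypergeometric enumeration of one margin
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  a_range <- max(0, k - n2):min(m, k)
  probs <- vapply(a_range, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- probs[a_range == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

chi2_closed_form <- function(obs, expected) {
  keep <- expected > 0
  sum((obs[keep] - expected[keep])^2 / expected[keep])
}

# random candidate-pair table with a 2-cell-line / 2-replicate roster
mk_pair_tbl <- function(n, seed = 1, datasets = c("cl1_r1", "cl1_r2",
                                                  "cl2_r1", "cl2_r2")) {
  withr::with_seed(seed, {
    tbl <- tibble::tibble(
      dre_id = sprintf("dre%05d", seq_len(n)),
      gene_id = sprintf("g%05d", sample.int(n, n, replace = TRUE)),
      pcc = round(runif(n, -0.2, 1), 3),
      distance = NA_real_,
      distance_class = sample(c("inter_chr", "distal_intra", "within_500kb",
                                "within_50kb"), n, replace = TRUE,
                              prob = c(0.4, 0.3, 0.2, 0.1)))
    tbl$pcc[sample.int(n, n %/% 20)] <- NA
    for (ds in datasets) tbl[[paste0("n_", ds)]] <- stats::rpois(n, 1.2)
    tbl
  })
}

roster4 <- tibble::tibble(
  dataset_id = c("cl1_r1", "cl1_r2", "cl2_r1", "cl2_r2"),
  cell_line = rep(c("cl1", "cl2"), each = 2),
  replicate = rep(c("r1", "r2"), 2))

dres_for <- function(tbl) {
  tibble::tibble(dre_id = unique(tbl$dre_id), chrom = "chr9",
                 start = seq_along(unique(tbl$dre_id)) * 1000L,
                 end = seq_along(unique(tbl$dre_id)) * 1000L + 200L)
}

rand_intervals <- function(n, chroms, max_pos, width_range = c(100, 2000)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + w)
}
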