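#' Configuration for the synthetic dataset generator
#'
#' Collects and validates every tunable of [simulate_dataset()]. The defaults
#' describe the study conditions the pipeline is exercised under: a 45-species
#' panel, two cell lines with two replicates each, strongly correlated
#' presence/absence profiles at planted true pairs (`rho_true = 0.9`), and a
#' Poisson contact model with a strong signal over a sparse background
#' (`lambda_signal = 5`, `lambda_noise = 0.05` reads per pair and replicate).
#'
#' @param n_species Number of non-human species in the profile panel.
#' @param n_chromosomes,chrom_length Genome shape (bp).
#' @param n_genes Number of protein-coding gene models.
#' @param n_dhs Total number of DHS (intragenic + promoter-proximal + DREs).
#' @param fraction_true_pairs Fraction of DREs given a planted distal target.
#' @param rho_true Target presence/absence correlation of true pairs.
#' @param lambda_signal,lambda_noise Poisson means for Hi-C contacts per
#'   (pair, dataset) at true pairs / at random DRE-DHS pairs.
#' @param n_cell_lines,n_replicates Dataset roster shape.
#' @param marker_probs Probability that a feature carries any given marker.
#' @param n_tissues Number of tissues in the expression matrix.
#' @param go_modules Number of synthetic functional modules (each gets its own
#'   GO subtree, a shared latent expression profile, and DRE clusters whose
#'   targets are drawn from it).
#' @param dre_group_size DREs per planted spatial group (gap <= 5 kb, so they
#'   cluster); grouped DREs target distinct genes of one module.
#' @param align_jitter Maximum outward jitter (bp) of alignment-block
#'   boundaries around an element.
#' @param expr_noise_sd Tissue-expression noise sd around the module latent.
#' @param seed Integer seed; the entire bundle is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
simulate_config <- function(n_species = 45, n_chromosomes = 4,
                            chrom_length = 3e6, n_genes = 60, n_dhs = 420,
                            fraction_true_pairs = 0.25, rho_true = 0.9,
                            lambda_signal = 5, lambda_noise = 0.05,
                            n_cell_lines = 2, n_replicates = 2,
                            marker_probs = 0.3, n_tissues = 79,
                            go_modules = 8, dre_group_size = 3,
                            align_jitter = 200, expr_noise_sd = 0.5,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 2, cfg$n_chromosomes >= 1, cfg$chrom_length > 1e5,
            cfg$n_genes >= 4, cfg$n_dhs > cfg$n_genes,
            cfg$fraction_true_pairs >= 0, cfg$fraction_true_pairs <= 1,
            cfg$rho_true >= 0, cfg$rho_true <= 1,
            cfg$lambda_signal >= 0, cfg$lambda_noise >= 0,
            cfg$marker_probs >= 0, cfg$marker_probs <= 1,
            cfg$n_cell_lines >= 1, cfg$n_replicates >= 1,
            cfg$n_tissues >= 2, cfg$go_modules >= 1, cfg$dre_group_size >= 1)
  structure(cfg, class = "sim_config")
}

marker_vocabulary <- function() {
  list(
    dre = c("H3K4me1", "H3K4me2", "H3K27ac"),
    promoter = c("H3K4me3", "H3K9ac", "H3K27me3"),
    gene_body = c("H3K36me3", "H4K20me1")
  )
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Emits every input the prediction pipeline consumes, with known true
#' DRE-target pairs:
#'
#' * a gene table and a DHS BED (intragenic, promoter-proximal and distal
#'   sites);
#' * per-species alignment-block BEDs. Each element (gene region or DRE) has a
#'   presence/absence vector over the species panel; species-specific
#'   retention probabilities drawn from a U-shaped Beta(0.5, 0.5) make *all*
#'   profiles positively correlated at baseline (mimicking shared phylogenetic
#'   structure), and a true pair's DRE vector is its target's vector with
#'   symmetric bit flips at rate `(1 - rho_true)/2`, so the realised
#'   correlation matches `rho_true`. Blocks cover the element with
#'   outward-jittered boundaries;
#' * BEDPE contact files per cell line x replicate: Poisson(`lambda_signal`)
#'   contacts per true pair (DRE end x a random intragenic-DHS window of the
#'   target) over a Poisson(`lambda_noise`) background on every random
#'   (DRE, intragenic DHS) combination;
#' * marker peak BEDs (independent Bernoulli assignment);
#' * a genes x tissues expression matrix where genes of one module share a
#'   latent profile;
#' * a toy GO corpus: a three-level is_a DAG with one subtree per module,
#'   EXP-evidence annotations of module genes to the module leaves, plus IEA
#'   decoys that corpus building must discard;
#' * the ground truth (true pairs, gene modules).
#'
#' @param config A `sim_config` from [simulate_config()].
#' @param dir Optional output directory; when given, the full file bundle
#'   (genes.tsv, dhs.bed, align/, hic/, markers/, expression.tsv, go.obo,
#'   go_annotations.tsv, truth.tsv, config.json) is written there.
#' @return A list bundle with the in-memory tibbles (`genes`, `dhs`, `blocks`,
#'   `contacts`, `markers`, `expression`, `go_terms`, `go_annotations`,
#'   `roster`, `species`, `truth`, `config`, and `dir` when written).
#' @export
simulate_dataset <- function(config = simulate_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  # feasibility: distal geometry must exist before anything is written
  if (config$n_chromosomes < 2 && config$chrom_length < 1.5e6) {
    abort("infeasible config: no distal (>500 kb or inter-chromosomal) geometry possible")
  }
  bundle <- withr::with_seed(config$seed, generate_bundle(config))
  if (!is.null(dir)) {
    write_bundle(bundle, dir)
    bundle$dir <- dir
  }
  bundle
}

generate_bundle <- function(cfg) {
  S <- cfg$n_species
  species <- sprintf("sp%02d", seq_len(S))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  ## --- gene models ---------------------------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  gene_rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    slot <- (cfg$chrom_length - 2e4) / k
    for (j in seq_len(k)) {
      gid <- gid + 1L
      len <- sample(5000:15000, 1)
      s <- round(1e4 + (j - 1) * slot + runif(1, 0.05, 0.25) * slot)
      gene_rows[[gid]] <- tibble(
        gene_id = sprintf("g%04d", gid), chrom = chroms[ci],
        start = as.integer(s), end = as.integer(s + len),
        strand = sample(c("+", "-"), 1)
      )
    }
  }
  genes <- bind_rows(gene_rows)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

  ## --- DHS: intragenic, promoter-proximal, DREs ---------------------------
  dhs_rows <- list()
  intr_of <- list()  # gene_id -> dhs names
  nd <- 0L
  next_dhs <- function() { nd <<- nd + 1L; sprintf("dhs_%05d", nd) }
  for (i in seq_len(nrow(genes))) {
    k <- sample(1:3, 1)
    len <- genes$end[i] - genes$start[i]
    centers <- genes$start[i] + round(seq_len(k) / (k + 1) * len) +
      sample(-200:200, k, replace = TRUE)
    centers <- pmin(pmax(centers, genes$start[i] + 200L), genes$end[i] - 200L)
    ids <- character(k)
    for (j in seq_len(k)) {
      ids[j] <- next_dhs()
      dhs_rows[[length(dhs_rows) + 1L]] <- tibble(
        chrom = genes$chrom[i], start = as.integer(centers[j] - 75L),
        end = as.integer(centers[j] + 75L), name = ids[j])
    }
    intr_of[[genes$gene_id[i]]] <- ids
  }
  n_intr <- nd
  prom_genes <- sort(sample(seq_len(nrow(genes)), round(0.15 * nrow(genes))))
  for (i in prom_genes) {
    off <- sample(400:1700, 1)          # upstream, within the promoter flank
    s <- if (genes$strand[i] == "+") genes$tss[i] - off - 150L else
      genes$tss[i] + off
    dhs_rows[[length(dhs_rows) + 1L]] <- tibble(
      chrom = genes$chrom[i], start = as.integer(s),
      end = as.integer(s + 150L), name = next_dhs())
  }
  n_dre <- cfg$n_dhs - nd
  if (n_dre < 5) abort("infeasible config: n_dhs leaves too few DREs")

  # allowed DRE territory: outside gene regions expanded by a safety buffer
  buffer <- 3000 + cfg$align_jitter
  forbid <- map(chroms, function(ch) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) return(tibble(start = numeric(0), end = numeric(0)))
    tibble(start = pmax(g$start - 1000 - buffer, 0),
           end = g$end + 1000 + buffer) %>% arrange(.data$start)
  })
  names(forbid) <- chroms
  dre_ok <- function(ch, s, e) {
    f <- forbid[[ch]]
    s >= 5000 && e <= cfg$chrom_length - 5000 &&
      !any(f$start < e & s < f$end)
  }

  n_true <- round(cfg$fraction_true_pairs * n_dre)
  gsize <- cfg$dre_group_size
  n_groups <- if (n_true > 0) ceiling(n_true / gsize) else 0L

  dre_w <- 200L
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  too_close <- function(ch, s, e, min_gap) {
    p <- placed[placed$chrom == ch, ]
    nrow(p) > 0 && any(p$start - min_gap < e & s < p$end + min_gap)
  }
  place_one <- function(min_gap, span = dre_w) {
    for (try in 1:2000) {
      ch <- sample(chroms, 1)
      s <- sample.int(cfg$chrom_length - 10000L, 1) + 5000L
      e <- s + span
      if (dre_ok(ch, s, e) && !too_close(ch, s, e, min_gap)) {
        return(list(chrom = ch, start = as.integer(s)))
      }
    }
    abort("infeasible config: could not place DREs outside gene territory")
  }

  dre_tbl <- list()
  dre_group <- integer(0)
  di <- 0L
  for (grp in seq_len(n_groups)) {
    members <- min(gsize, n_true - (grp - 1L) * gsize)
    span <- members * dre_w + (members - 1L) * 4000L
    base <- place_one(min_gap = 8000L, span = span)
    for (m in seq_len(members)) {
      di <- di + 1L
      s <- base$start + (m - 1L) * (dre_w + sample(2000:3800, 1))
      dre_tbl[[di]] <- tibble(chrom = base$chrom, start = as.integer(s),
                              end = as.integer(s + dre_w), name = next_dhs())
      dre_group[di] <- grp
      placed <- bind_rows(placed, dre_tbl[[di]][c("chrom", "start", "end")])
    }
  }
  for (j in seq_len(n_dre - n_true)) {
    di <- di + 1L
    loc <- place_one(min_gap = 8000L)
    dre_tbl[[di]] <- tibble(chrom = loc$chrom, start = loc$start,
                            end = loc$start + dre_w, name = next_dhs())
    dre_group[di] <- NA_integer_
    placed <- bind_rows(placed, dre_tbl[[di]][c("chrom", "start", "end")])
  }
  dres <- bind_rows(dre_tbl)
  dhs <- bind_rows(bind_rows(dhs_rows), dres) %>%
    arrange(.data$chrom, .data$start, .data$end)

  ## --- modules and true-pair targets --------------------------------------
  gpm <- max(3L, floor(cfg$n_genes * 0.8 / cfg$go_modules))
  shuffled <- sample(genes$gene_id)
  module_of <- setNames(rep(NA_integer_, cfg$n_genes), genes$gene_id)
  take <- min(cfg$go_modules * gpm, cfg$n_genes)
  module_of[shuffled[seq_len(take)]] <- rep(seq_len(cfg$go_modules),
                                            each = gpm)[seq_len(take)]

  # margin over the 500 kb rule so every member of a spatial group stays distal
  is_distal <- function(dre_row, gi) {
    genes$chrom[gi] != dre_row$chrom |
      interval_gap(dre_row$start, dre_row$end,
                   genes$start[gi], genes$end[gi]) > 5e5 + 5e4
  }
  truth_rows <- list()
  target_of <- rep(NA_character_, nrow(dres))
  if (n_true > 0) {
    grp_module <- rep_len(seq_len(cfg$go_modules), n_groups)
    for (grp in seq_len(n_groups)) {
      mem <- which(dre_group == grp)
      mod_genes <- which(module_of[genes$gene_id] == grp_module[grp])
      cand <- mod_genes[is_distal(dres[mem[1], ], mod_genes)]
      if (length(cand) < length(mem)) {
        extra <- setdiff(which(is_distal(dres[mem[1], ], seq_len(nrow(genes)))),
                         cand)
        cand <- c(cand, sample(extra, length(mem) - length(cand)))
      }
      tgt <- sample(cand, length(mem))
      for (m in seq_along(mem)) {
        target_of[mem[m]] <- genes$gene_id[tgt[m]]
        truth_rows[[length(truth_rows) + 1L]] <-
          tibble(dre_id = dres$name[mem[m]], gene_id = genes$gene_id[tgt[m]])
      }
    }
  }
  true_pairs <- if (length(truth_rows)) bind_rows(truth_rows) else
    tibble(dre_id = character(), gene_id = character())

  ## --- presence/absence profiles and alignment blocks ---------------------
  # U-shaped species retention rates give all independent profiles a positive
  # baseline correlation (shared phylogenetic structure); symmetric bit flips
  # at rate (1 - rho)/2 make a true pair's realised correlation equal rho_true
  # (the flips replace, not add to, the baseline structure).
  q <- pmin(pmax(rbeta(S, 0.5, 0.5), 0.03), 0.97)
  eps <- (1 - cfg$rho_true) / 2

  draw_presence <- function() {
    x <- rbinom(S, 1L, q)
    if (sum(x) == 0) x[which.max(q)] <- 1L
    x
  }
  gene_pres <- t(vapply(seq_len(nrow(genes)), function(i) draw_presence(),
                        integer(S)))
  dimnames(gene_pres) <- list(genes$gene_id, species)
  dre_pres <- matrix(0L, nrow = nrow(dres), ncol = S,
                     dimnames = list(dres$name, species))
  for (i in seq_len(nrow(dres))) {
    if (!is.na(target_of[i])) {
      flips <- rbinom(S, 1L, eps)
      x <- as.integer(xor(gene_pres[target_of[i], ], flips))
      if (sum(x) == 0) x[which.max(q)] <- 1L
      dre_pres[i, ] <- x
    } else {
      dre_pres[i, ] <- draw_presence()
    }
  }

  elem <- bind_rows(
    gene_profile_regions(genes) %>% mutate(kind = "gene"),
    tibble(owner_id = dres$name, chrom = dres$chrom, start = dres$start,
           end = dres$end, kind = "dre")
  )
  pres <- rbind(gene_pres, dre_pres)[elem$owner_id, , drop = FALSE]
  block_rows <- list()
  for (i in seq_len(nrow(elem))) {
    sp_in <- which(pres[i, ] == 1L)
    if (length(sp_in) == 0) next
    j1 <- sample(0:cfg$align_jitter, length(sp_in), replace = TRUE)
    j2 <- sample(0:cfg$align_jitter, length(sp_in), replace = TRUE)
    block_rows[[i]] <- tibble(
      species = species[sp_in], chrom = elem$chrom[i],
      start = as.integer(pmax(elem$start[i] - j1, 0L)),
      end = as.integer(elem$end[i] + j2))
  }
  blocks <- bind_rows(block_rows)
  blocks$species <- factor(blocks$species, levels = species)
  blocks <- arrange(blocks, .data$species, .data$chrom, .data$start, .data$end)

  ## --- Hi-C contacts -------------------------------------------------------
  cell_lines <- sprintf("cl%d", seq_len(cfg$n_cell_lines))
  reps <- sprintf("r%d", seq_len(cfg$n_replicates))
  roster <- tidyr::expand_grid(cell_line = cell_lines, replicate = reps) %>%
    mutate(dataset_id = paste(.data$cell_line, .data$replicate, sep = "_")) %>%
    select("dataset_id", "cell_line", "replicate")

  intr_long <- tibble(
    gene_id = rep(genes$gene_id, lengths(intr_of[genes$gene_id])),
    dhs_id = unlist(intr_of[genes$gene_id], use.names = FALSE)
  ) %>%
    left_join(dhs, by = c("dhs_id" = "name")) %>%
    mutate(center = (.data$start + .data$end) %/% 2L)

  rand_in <- function(lo, hi, n) lo + (sample.int(hi - lo, n, replace = TRUE) - 1L)
  contact_rows <- list()
  for (ds in roster$dataset_id) {
    # planted signal
    if (nrow(true_pairs) > 0 && cfg$lambda_signal > 0) {
      k <- rpois(nrow(true_pairs), cfg$lambda_signal)
      for (i in which(k > 0)) {
        dre_i <- match(true_pairs$dre_id[i], dres$name)
        cand_dhs <- intr_long[intr_long$gene_id == true_pairs$gene_id[i], ]
        pick <- sample.int(nrow(cand_dhs), k[i], replace = TRUE)
        p1 <- rand_in(dres$start[dre_i], dres$end[dre_i], k[i])
        p2 <- cand_dhs$center[pick] + (sample.int(2000L, k[i], replace = TRUE) - 1001L)
        contact_rows[[length(contact_rows) + 1L]] <- tibble(
          dataset_id = ds, chrom1 = dres$chrom[dre_i], pos1 = p1,
          chrom2 = cand_dhs$chrom[pick], pos2 = p2)
      }
    }
    # background: independent Poisson on every (DRE, intragenic DHS) pair
    if (cfg$lambda_noise > 0) {
      nb <- rpois(nrow(dres) * nrow(intr_long), cfg$lambda_noise)
      hit <- which(nb > 0)
      if (length(hit) > 0) {
        dre_i <- ((hit - 1L) %% nrow(dres)) + 1L
        win_i <- ((hit - 1L) %/% nrow(dres)) + 1L
        reps_n <- nb[hit]
        dre_i <- rep(dre_i, reps_n); win_i <- rep(win_i, reps_n)
        p1 <- rand_in(0L, dre_w, length(dre_i)) + dres$start[dre_i]
        p2 <- intr_long$center[win_i] +
          (sample.int(2000L, length(win_i), replace = TRUE) - 1001L)
        contact_rows[[length(contact_rows) + 1L]] <- tibble(
          dataset_id = ds, chrom1 = dres$chrom[dre_i], pos1 = p1,
          chrom2 = intr_long$chrom[win_i], pos2 = p2)
      }
    }
  }
  contacts <- if (length(contact_rows)) bind_rows(contact_rows) else
    tibble(dataset_id = character(), chrom1 = character(), pos1 = integer(),
           chrom2 = character(), pos2 = integer())
  contacts <- arrange(contacts, .data$dataset_id, .data$chrom1, .data$pos1,
                      .data$chrom2, .data$pos2)

  ## --- markers -------------------------------------------------------------
  voc <- marker_vocabulary()
  markers <- list()
  for (mk in voc$dre) {
    sel <- runif(nrow(dres)) < cfg$marker_probs
    markers[[mk]] <- dres[sel, c("chrom", "start", "end")]
  }
  prom <- gene_marker_intervals(genes, "promoter")
  for (mk in voc$promoter) {
    sel <- runif(nrow(genes)) < cfg$marker_probs
    markers[[paste0(mk, "@promoter")]] <- prom[sel, c("chrom", "start", "end")]
  }
  for (mk in voc$gene_body) {
    sel <- runif(nrow(genes)) < cfg$marker_probs
    markers[[paste0(mk, "@gene_body")]] <- genes[sel, c("chrom", "start", "end")]
  }

  ## --- expression ----------------------------------------------------------
  latent <- matrix(rnorm(cfg$go_modules * cfg$n_tissues), nrow = cfg$go_modules)
  expression <- matrix(NA_real_, nrow = nrow(genes), ncol = cfg$n_tissues,
                       dimnames = list(genes$gene_id,
                                       sprintf("t%02d", seq_len(cfg$n_tissues))))
  for (i in seq_len(nrow(genes))) {
    m <- module_of[genes$gene_id[i]]
    expression[i, ] <- if (is.na(m)) rnorm(cfg$n_tissues) else
      latent[m, ] + rnorm(cfg$n_tissues, sd = cfg$expr_noise_sd)
  }
  expression <- round(expression, 6)

  ## --- GO corpus -----------------------------------------------------------
  root <- "GO:ROOT0001"; generic <- "GO:GENER001"
  term_rows <- list(
    tibble(term = root, name = "biological_process",
           namespace = "biological_process", parents = list(character(0)),
           obsolete = FALSE),
    tibble(term = generic, name = "generic cellular process",
           namespace = "biological_process", parents = list(root),
           obsolete = FALSE)
  )
  leaf_of_module <- list()
  for (m in seq_len(cfg$go_modules)) {
    mid <- sprintf("GO:M%03d0", m)
    la <- sprintf("GO:M%03dA", m); lb <- sprintf("GO:M%03dB", m)
    term_rows <- c(term_rows, list(
      tibble(term = mid, name = sprintf("module %d process", m),
             namespace = "biological_process", parents = list(root),
             obsolete = FALSE),
      tibble(term = la, name = sprintf("module %d subprocess A", m),
             namespace = "biological_process", parents = list(mid),
             obsolete = FALSE),
      tibble(term = lb, name = sprintf("module %d subprocess B", m),
             namespace = "biological_process", parents = list(mid),
             obsolete = FALSE)))
    leaf_of_module[[m]] <- c(la, lb)
  }
  go_terms <- bind_rows(term_rows)

  ann_rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]; m <- module_of[g]
    term <- if (is.na(m)) generic else
      leaf_of_module[[m]][1L + (i %% 2L)]
    ann_rows[[length(ann_rows) + 1L]] <-
      tibble(gene_id = g, term = term, evidence = "EXP")
    if (i %% 5L == 0L) {   # IEA decoys that corpus building must drop
      ann_rows[[length(ann_rows) + 1L]] <-
        tibble(gene_id = g,
               term = leaf_of_module[[1L + (i %% cfg$go_modules)]][1],
               evidence = "IEA")
    }
  }
  go_annotations <- bind_rows(ann_rows)

  list(
    config = cfg, species = species, roster = roster,
    genes = genes[c("gene_id", "chrom", "start", "end", "strand", "tss")],
    dhs = dhs, blocks = blocks, contacts = contacts, markers = markers,
    expression = expression, go_terms = go_terms,
    go_annotations = go_annotations,
    truth = list(true_pairs = true_pairs,
                 gene_modules = tibble(gene_id = genes$gene_id,
                                       module = unname(module_of[genes$gene_id])))
  )
}

write_obo <- function(terms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(terms))) {
    lines <- c("[Term]",
               paste0("id: ", terms$term[i]),
               paste0("name: ", terms$name[i]),
               paste0("namespace: ", terms$namespace[i]),
               sprintf("is_a: %s", terms$parents[[i]]))
    if (terms$obsolete[i]) lines <- c(lines, "is_obsolete: true")
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("align", "hic", "markers")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  readr::write_tsv(bundle$genes[c("gene_id", "chrom", "start", "end", "strand")],
                   file.path(dir, "genes.tsv"), progress = FALSE)
  write_bed(bundle$dhs, file.path(dir, "dhs.bed"))
  for (sp in bundle$species) {
    b <- bundle$blocks[as.character(bundle$blocks$species) == sp, ]
    write_bed(b, file.path(dir, "align", paste0(sp, ".bed")))
  }
  for (ds in bundle$roster$dataset_id) {
    cc <- bundle$contacts[bundle$contacts$dataset_id == ds, ]
    bedpe <- tibble(chrom1 = cc$chrom1, start1 = cc$pos1 - 25L,
                    end1 = cc$pos1 + 25L, chrom2 = cc$chrom2,
                    start2 = cc$pos2 - 25L, end2 = cc$pos2 + 25L)
    readr::write_tsv(bedpe, file.path(dir, "hic", paste0(ds, ".bedpe")),
                     col_names = FALSE, progress = FALSE)
  }
  for (mk in names(bundle$markers)) {
    safe <- gsub("@", "_at_", mk)
    write_bed(bundle$markers[[mk]], file.path(dir, "markers", paste0(safe, ".bed")))
  }
  expr <- as_tibble(bundle$expression, rownames = "gene_id")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"), progress = FALSE)
  write_obo(bundle$go_terms, file.path(dir, "go.obo"))
  readr::write_tsv(bundle$go_annotations, file.path(dir, "go_annotations.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$truth$true_pairs, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$truth$gene_modules, file.path(dir, "gene_modules.tsv"),
                   progress = FALSE)
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a previously written simulation bundle
#'
#' @param dir Directory written by [simulate_dataset()].
#' @return A bundle list equivalent to the in-memory one.
#' @export
read_bundle <- function(dir) {
  cfg_l <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(simulate_config, cfg_l)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  cell_lines <- sprintf("cl%d", seq_len(config$n_cell_lines))
  reps <- sprintf("r%d", seq_len(config$n_replicates))
  roster <- tidyr::expand_grid(cell_line = cell_lines, replicate = reps) %>%
    mutate(dataset_id = paste(.data$cell_line, .data$replicate, sep = "_")) %>%
    select("dataset_id", "cell_line", "replicate")
  contacts <- bind_rows(map(roster$dataset_id, function(ds) {
    read_bedpe_contacts(file.path(dir, "hic", paste0(ds, ".bedpe")), ds)
  }))
  marker_files <- list.files(file.path(dir, "markers"), pattern = "\\.bed$")
  markers <- map(marker_files, ~ read_bed(file.path(dir, "markers", .x)))
  names(markers) <- gsub("_at_", "@", sub("\\.bed$", "", marker_files))
  truth_path <- file.path(dir, "truth.tsv")
  gm_path <- file.path(dir, "gene_modules.tsv")
  list(
    config = config, species = species, roster = roster,
    genes = read_gene_table(file.path(dir, "genes.tsv")),
    dhs = read_bed(file.path(dir, "dhs.bed"), id_prefix = "dhs"),
    blocks = read_alignment_blocks(file.path(dir, "align"), species),
    contacts = contacts, markers = markers,
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    go_terms = read_obo(file.path(dir, "go.obo")),
    go_annotations = read_go_annotations(file.path(dir, "go_annotations.tsv")),
    truth = list(
      true_pairs = readr::read_tsv(truth_path, show_col_types = FALSE,
                                   progress = FALSE),
      gene_modules = readr::read_tsv(gm_path, show_col_types = FALSE,
                                     progress = FALSE)
    ),
    dir = dir
  )
}

#' Score predictions against planted ground truth
#'
#' Standard set-overlap metrics over distal pairs. Precision is `NA` when
#' there are no predictions; recall is `NA` when there are no true pairs.
#'
#' @param predictions Prediction tibble (needs `dre_id`, `gene_id`).
#' @param truth Ground-truth list from the bundle, or a tibble of true pairs.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_predictions <- function(predictions, truth) {
  tp_tbl <- if (is.data.frame(truth)) truth else truth$true_pairs
  pred_keys <- unique(paste(predictions$dre_id, predictions$gene_id, sep = "\r"))
  true_keys <- unique(paste(tp_tbl$dre_id, tp_tbl$gene_id, sep = "\r"))
  tp <- length(intersect(pred_keys, true_keys))
  fp <- length(pred_keys) - tp
  fn <- length(true_keys) - tp
  precision <- if (length(pred_keys) > 0) tp / length(pred_keys) else NA_real_
  recall <- if (length(true_keys) > 0) tp / length(true_keys) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}
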