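#' Default pipeline parameters
#'
#' One place for every numeric threshold of the pipeline, at its standard
#' value: TSS flank 2000 bp for DRE classification, 1000 bp upstream extension
#' of gene regions, 1000 bp capture half-window around intragenic DHS,
#' distance classes at 500 kb / 50 kb, profile-correlation cutoff 0.8,
#' read-count cutoff 2 (strictly greater, i.e. >= 3 reads), 5 kb cluster gap,
#' the 3x3 repeatability cutoff grid, and 100 control resamples for the
#' functional-coherence curves.
#'
#' @return Named list of parameters.
#' @export
default_run_params <- function() {
  list(
    tss_flank = 2000, upstream = 1000, dhs_flank = 1000,
    far = 500000, near = 50000,
    pcc_cutoff = 0.8, read_cutoff = 2,
    pcc_cutoffs = c(0.7, 0.8, 0.9), read_cutoffs = c(1, 2, 3),
    cluster_gap = 5000, n_controls = 100, min_targets = 3,
    density_half_width = 2000, density_window = 50,
    density_bg_near = 5000, density_bg_far = 10000, density_step = 10,
    seed = 1
  )
}

merge_params <- function(params = list()) {
  p <- default_run_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  p[names(params)] <- params
  p
}

#' Run the full prediction pipeline in memory
#'
#' Chains classification, profiling, Hi-C counting, and prediction on a
#' simulation bundle (or any list with the same components), and scores the
#' result against the bundle's ground truth when present.
#'
#' @param bundle A bundle from [simulate_dataset()] / [read_bundle()].
#' @param params Named list overriding [default_run_params()].
#' @return List with `classified`, `dres`, `intragenic`, `bins`,
#'   `dre_profiles`, `gene_profiles`, `pair_tbl`, `predictions`, and `score`
#'   (when ground truth is available).
#' @export
run_dre_pipeline <- function(bundle, params = list()) {
  p <- merge_params(params)
  classified <- classify_dhs(bundle$dhs, bundle$genes, tss_flank = p$tss_flank)
  dres <- dre_table(classified)
  intr <- intragenic_dhs(classified, bundle$genes)
  bins <- build_bins(bundle$blocks)
  dre_prof <- region_profiles(dre_profile_regions(dres), bins)
  gene_prof <- region_profiles(gene_profile_regions(bundle$genes,
                                                    upstream = p$upstream), bins)
  counts <- count_pair_reads(bundle$contacts, dres, intr, flank = p$dhs_flank)
  ptbl <- pair_table(counts, dre_prof, gene_prof, dres, bundle$genes,
                     datasets = bundle$roster$dataset_id,
                     far = p$far, near = p$near)
  preds <- predict_pairs(ptbl, bundle$roster, dres,
                         pcc_cutoff = p$pcc_cutoff, read_cutoff = p$read_cutoff)
  out <- list(classified = classified, dres = dres, intragenic = intr,
              bins = bins, dre_profiles = dre_prof, gene_profiles = gene_prof,
              pair_tbl = ptbl, predictions = preds, params = p)
  if (!is.null(bundle$truth)) {
    out$score <- score_predictions(preds, bundle$truth)
  }
  out
}

stage_outputs <- list(
  simulate = "config.json",
  annotate = "classified_dhs.tsv",
  profiles = c("bins.tsv", "dre_profiles.tsv", "gene_profiles.tsv"),
  `hic-count` = "pair_counts.tsv",
  density = "density.tsv",
  repeatability = "repeatability.tsv",
  predict = "predictions.tsv",
  cluster = c("clusters.tsv", "cluster_summary.tsv"),
  enrich = "marker_enrichment.tsv",
  funcsim = c("cluster_curves.tsv", "funcsim_summary.tsv"),
  score = "score.tsv"
)

stage_prereqs <- list(
  simulate = character(0),
  annotate = "simulate",
  profiles = c("simulate", "annotate"),
  `hic-count` = c("simulate", "annotate"),
  density = c("simulate", "annotate"),
  repeatability = c("simulate", "annotate", "profiles", "hic-count"),
  predict = c("simulate", "annotate", "profiles", "hic-count"),
  cluster = c("simulate", "annotate", "predict"),
  enrich = c("simulate", "annotate", "predict"),
  funcsim = c("simulate", "annotate", "predict", "cluster"),
  score = c("simulate", "predict")
)

check_prereqs <- function(stage, dir) {
  for (pre in stage_prereqs[[stage]]) {
    missing <- !file.exists(file.path(dir, stage_outputs[[pre]]))
    if (any(missing)) {
      abort(sprintf(
        "stage '%s' needs %s; run the '%s' stage first",
        stage, stage_outputs[[pre]][missing][1], pre))
    }
  }
}

read_classified <- function(dir) {
  cl <- readr::read_tsv(file.path(dir, "classified_dhs.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  cl$host_genes <- map(strsplit(ifelse(is.na(cl$host_genes), "",
                                       cl$host_genes), ","), ~ .x[nzchar(.x)])
  cl
}

load_profiles <- function(dir) {
  list(dre = readr::read_tsv(file.path(dir, "dre_profiles.tsv"),
                             show_col_types = FALSE, progress = FALSE),
       gene = readr::read_tsv(file.path(dir, "gene_profiles.tsv"),
                              show_col_types = FALSE, progress = FALSE))
}

#' Run one pipeline stage against a run directory
#'
#' File-based counterpart of [run_dre_pipeline()]: every stage reads the
#' plain-text outputs of its predecessors from `dir`, writes its own outputs
#' there, and stores its resolved parameters (with the package version and
#' input checksums) next to them as `<stage>.params.json`. Stages are
#' idempotent given fixed inputs and seed. Missing upstream artifacts raise an
#' error naming the stage that produces them.
#'
#' @param stage One of `"simulate"`, `"annotate"`, `"profiles"`,
#'   `"hic-count"`, `"density"`, `"repeatability"`, `"predict"`, `"cluster"`,
#'   `"enrich"`, `"funcsim"`, `"score"`.
#' @param dir Run directory.
#' @param params Named list overriding [default_run_params()]; for
#'   `"simulate"`, entries matching [simulate_config()] arguments override the
#'   generator configuration instead.
#' @return The stage's main result, invisibly.
#' @export
pipeline_stage <- function(stage, dir, params = list()) {
  stage <- arg_match(stage, names(stage_outputs))
  if (stage == "simulate") {
    ok <- names(params) %in% names(formals(simulate_config))
    cfg <- do.call(simulate_config, params[ok])
    res <- simulate_dataset(cfg, dir = dir)
    log_stage(stage, dir, unclass(cfg), character(0))
    return(invisible(res))
  }
  check_prereqs(stage, dir)
  p <- merge_params(params)
  bundle <- read_bundle(dir)
  inputs <- character(0)

  res <- switch(
    stage,
    annotate = {
      cl <- classify_dhs(bundle$dhs, bundle$genes, tss_flank = p$tss_flank)
      out <- mutate(cl, host_genes = map_chr(.data$host_genes, paste,
                                             collapse = ","))
      readr::write_tsv(out, file.path(dir, "classified_dhs.tsv"),
                       progress = FALSE)
      inputs <- c("genes.tsv", "dhs.bed")
      cl
    },
    profiles = {
      cl <- read_classified(dir)
      bins <- build_bins(bundle$blocks)
      write_bins(bins, file.path(dir, "bins.tsv"))
      dres <- dre_table(cl)
      dp <- region_profiles(dre_profile_regions(dres), bins)
      gp <- region_profiles(gene_profile_regions(bundle$genes, p$upstream), bins)
      readr::write_tsv(dp, file.path(dir, "dre_profiles.tsv"), progress = FALSE)
      readr::write_tsv(gp, file.path(dir, "gene_profiles.tsv"), progress = FALSE)
      inputs <- "classified_dhs.tsv"
      list(bins = bins, dre_profiles = dp, gene_profiles = gp)
    },
    `hic-count` = {
      cl <- read_classified(dir)
      counts <- count_pair_reads(bundle$contacts, dre_table(cl),
                                 intragenic_dhs(cl, bundle$genes),
                                 flank = p$dhs_flank)
      readr::write_tsv(counts, file.path(dir, "pair_counts.tsv"),
                       progress = FALSE)
      inputs <- "classified_dhs.tsv"
      counts
    },
    density = {
      cl <- read_classified(dir)
      dres <- dre_table(cl)
      prof <- density_profile(dres, contact_points(bundle$contacts),
                              half_width = p$density_half_width,
                              window = p$density_window,
                              bg_near = p$density_bg_near,
                              bg_far = p$density_bg_far,
                              step = p$density_step)
      readr::write_tsv(as_tibble(prof), file.path(dir, "density.tsv"),
                       progress = FALSE)
      inputs <- "classified_dhs.tsv"
      prof
    },
    repeatability = {
      ptbl <- stage_pair_table(dir, bundle, p)
      totals <- dataset_totals(bundle$contacts)
      grids <- map(split(bundle$roster, bundle$roster$cell_line), function(r) {
        if (nrow(r) < 2) return(NULL)
        g <- repeatability_grid(ptbl, r$dataset_id[1:2], totals,
                                pcc_cutoffs = p$pcc_cutoffs,
                                read_cutoffs = p$read_cutoffs)
        mutate(as_tibble(g), cell_line = r$cell_line[1], .before = 1)
      })
      out <- bind_rows(grids)
      readr::write_tsv(out, file.path(dir, "repeatability.tsv"), progress = FALSE)
      inputs <- c("pair_counts.tsv", "dre_profiles.tsv", "gene_profiles.tsv")
      out
    },
    predict = {
      ptbl <- stage_pair_table(dir, bundle, p)
      cl <- read_classified(dir)
      preds <- predict_pairs(ptbl, bundle$roster, dre_table(cl),
                             pcc_cutoff = p$pcc_cutoff,
                             read_cutoff = p$read_cutoff)
      write_predictions(preds, file.path(dir, "predictions.tsv"))
      inputs <- c("pair_counts.tsv", "dre_profiles.tsv", "gene_profiles.tsv")
      preds
    },
    cluster = {
      cl <- read_classified(dir)
      preds <- read_predictions(file.path(dir, "predictions.tsv"))
      clustered <- cluster_dres(dre_table(cl), gap = p$cluster_gap)
      summ <- cluster_summary(clustered, preds)
      readr::write_tsv(clustered, file.path(dir, "clusters.tsv"), progress = FALSE)
      out <- summ %>%
        mutate(members = map_chr(.data$members, paste, collapse = ","),
               target_genes = map_chr(.data$target_genes, paste, collapse = ","))
      readr::write_tsv(out, file.path(dir, "cluster_summary.tsv"),
                       progress = FALSE)
      inputs <- "predictions.tsv"
      summ
    },
    enrich = {
      cl <- read_classified(dir)
      preds <- read_predictions(file.path(dir, "predictions.tsv"))
      dres <- dre_table(cl)
      dm <- assign_markers(rename(dres, id = "dre_id"),
                           bundle$markers[!grepl("@", names(bundle$markers))])
      gm_peaks <- bundle$markers[grepl("@", names(bundle$markers))]
      gm <- bind_rows(imap(gm_peaks, function(pk, mk) {
        where <- if (endsWith(mk, "@promoter")) "promoter" else "gene_body"
        iv <- gene_marker_intervals(bundle$genes, where, flank = p$tss_flank)
        out <- assign_markers(iv, setNames(list(pk), mk))
        out
      }))
      res <- marker_enrichment_grid(preds, dm, gm)
      readr::write_tsv(res, file.path(dir, "marker_enrichment.tsv"),
                       progress = FALSE)
      inputs <- "predictions.tsv"
      res
    },
    funcsim = {
      preds <- read_predictions(file.path(dir, "predictions.tsv"))
      clustered <- readr::read_tsv(file.path(dir, "clusters.tsv"),
                                   show_col_types = FALSE, progress = FALSE)
      summ <- cluster_summary(clustered, preds)
      corpus <- build_go_corpus(bundle$go_terms, bundle$go_annotations)
      res_r <- cluster_score_curves(summ, "resnik", corpus = corpus,
                                    n_controls = p$n_controls,
                                    min_targets = p$min_targets,
                                    seed = p$seed)
      res_c <- cluster_score_curves(summ, "coexpression",
                                    expression = bundle$expression,
                                    n_controls = p$n_controls,
                                    min_targets = p$min_targets,
                                    seed = p$seed + 1)
      curves <- bind_rows(mutate(res_r$curves, metric = "resnik", .before = 1),
                          mutate(res_c$curves, metric = "coexpression",
                                 .before = 1))
      readr::write_tsv(curves, file.path(dir, "cluster_curves.tsv"),
                       progress = FALSE)
      summary <- bind_rows(glance(res_r), glance(res_c))
      readr::write_tsv(summary, file.path(dir, "funcsim_summary.tsv"),
                       progress = FALSE)
      inputs <- c("predictions.tsv", "clusters.tsv")
      list(resnik = res_r, coexpression = res_c)
    },
    score = {
      preds <- read_predictions(file.path(dir, "predictions.tsv"))
      sc <- score_predictions(preds, bundle$truth)
      readr::write_tsv(sc, file.path(dir, "score.tsv"), progress = FALSE)
      inputs <- "predictions.tsv"
      sc
    }
  )
  log_stage(stage, dir, p, inputs)
  invisible(res)
}

stage_pair_table <- function(dir, bundle, p) {
  counts <- readr::read_tsv(file.path(dir, "pair_counts.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  prof <- load_profiles(dir)
  cl <- read_classified(dir)
  pair_table(counts, prof$dre, prof$gene, dre_table(cl), bundle$genes,
             datasets = bundle$roster$dataset_id, far = p$far, near = p$near)
}

log_stage <- function(stage, dir, params, inputs) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(file.path(dir, inputs)))
  } else list()
  info <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("dretarget")),
    params = params,
    input_md5 = checksums,
    outputs = stage_outputs[[stage]]
  )
  jsonlite::write_json(info, file.path(dir, paste0(stage, ".params.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inform(sprintf("[%s] done (outputs: %s)", stage,
                 paste(stage_outputs[[stage]], collapse = ", ")))
}
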