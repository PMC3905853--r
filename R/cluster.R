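#' Single-linkage clustering of DREs by genomic gap
#'
#' DREs are sorted per chromosome and chained: a DRE joins the open cluster
#' when the gap between its start and the cluster's running span end is at
#' most `gap` bp. Chaining is transitive, so a run of DREs each within 5 kb of
#' the next forms one cluster regardless of its total span; clusters never
#' cross chromosomes.
#'
#' @param dres DRE tibble ([dre_table()]).
#' @param gap Maximum inter-DRE gap in bp (default 5000).
#' @return `dres` with an added `cluster_id` column (`dcl_00001`, ... in
#'   genomic order).
#' @export
cluster_dres <- function(dres, gap = 5000) {
  if (nrow(dres) == 0) return(mutate(dres, cluster_id = character(0)))
  check_intervals(dres, "DRE")
  ord <- order(dres$chrom, dres$start, dres$end)
  d <- dres[ord, ]
  run_end <- cummax_by_chrom(d$chrom, d$end)
  new_cluster <- c(TRUE, (d$chrom[-1] != d$chrom[-nrow(d)]) |
                     (d$start[-1] - run_end[-nrow(d)] > gap))
  d$cluster_id <- sprintf("dcl_%05d", cumsum(new_cluster))
  d
}

cummax_by_chrom <- function(chrom, end) {
  out <- numeric(length(end))
  for (idx in split(seq_along(end), chrom)) out[idx] <- cummax(end[idx])
  out
}

#' Summarise DRE clusters and their target-gene sets
#'
#' @param clustered Output of [cluster_dres()].
#' @param predictions Optional prediction tibble; when given, each cluster is
#'   linked to the union of its members' predicted target genes.
#' @return Tibble with `cluster_id`, `chrom`, `start`, `end` (span),
#'   `n_members`, `members` (list of dre_ids) and, with predictions,
#'   `target_genes` (list) and `n_targets`.
#' @export
cluster_summary <- function(clustered, predictions = NULL) {
  out <- clustered %>%
    group_by(.data$cluster_id) %>%
    summarise(chrom = first(.data$chrom),
              start = min(.data$start), end = max(.data$end),
              n_members = dplyr::n(),
              members = list(sort(.data$dre_id)), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  if (!is.null(predictions)) {
    tg <- clustered %>%
      select("cluster_id", "dre_id") %>%
      inner_join(select(as_tibble(predictions), "dre_id", "gene_id"),
                 by = "dre_id", relationship = "many-to-many") %>%
      distinct(.data$cluster_id, .data$gene_id) %>%
      group_by(.data$cluster_id) %>%
      summarise(target_genes = list(sort(.data$gene_id)), .groups = "drop")
    out <- left_join(out, tg, by = "cluster_id")
    no_t <- map_lgl(out$target_genes, is.null)
    out$target_genes[no_t] <- list(character(0))
    out$n_targets <- lengths(out$target_genes)
  }
  out
}

#' Build a GO corpus with information content
#'
#' Restricts the DAG to one namespace (biological process by default),
#' discards obsolete terms, drops IEA-evidence annotations, and computes for
#' every term its information content `IC = -ln p`, where `p` is the fraction
#' of annotated genes annotated to the term or any of its descendants.
#' Direct annotations to terms with fewer than `min_genes` annotated genes are
#' discarded as too unreliable for similarity scoring.
#'
#' @param terms Term tibble from [read_obo()].
#' @param annotations Annotation tibble from [read_go_annotations()].
#' @param namespace GO namespace to keep.
#' @param min_genes Minimum number of annotated genes for a term to be used.
#' @param drop_iea Drop annotations with evidence code `"IEA"`.
#' @return An object of class `go_corpus`: list with `ic` (named numeric),
#'   `ancestors` (term -> ancestor ids incl. self), `gene_terms`,
#'   `gene_closure` (gene -> all ancestor terms of its annotations),
#'   `universe` (annotated genes), `namespace`.
#' @export
build_go_corpus <- function(terms, annotations, namespace = "biological_process",
                            min_genes = 3, drop_iea = TRUE) {
  t <- filter(terms, !.data$obsolete,
              is.na(.data$namespace) | .data$namespace == !!namespace)
  parents <- setNames(t$parents, t$term)
  parents <- map(parents, ~ intersect(.x, t$term))

  anc_env <- new.env(parent = emptyenv())
  ancestors_of <- function(id, stack = character()) {
    if (id %in% stack) abort(sprintf("cycle in GO DAG at %s", id))
    got <- anc_env[[id]]
    if (!is.null(got)) return(got)
    res <- id
    for (p in parents[[id]]) res <- union(res, ancestors_of(p, c(stack, id)))
    anc_env[[id]] <- res
    res
  }
  anc <- setNames(map(t$term, ancestors_of), t$term)

  ann <- annotations
  if (drop_iea && "evidence" %in% names(ann)) {
    ann <- filter(ann, is.na(.data$evidence) | .data$evidence != "IEA")
  }
  ann <- filter(distinct(ann, .data$gene_id, .data$term),
                .data$term %in% t$term)
  if (nrow(ann) == 0) abort("no usable annotations in this namespace")

  gene_terms <- map(split(ann$term, ann$gene_id), unique)
  gene_closure <- map(gene_terms, ~ unique(unlist(anc[.x], use.names = FALSE)))
  n_universe <- length(gene_closure)
  counts <- table(unlist(gene_closure, use.names = FALSE))
  n_below <- setNames(rep(0L, nrow(t)), t$term)
  n_below[names(counts)] <- as.integer(counts)
  ic <- -log(ifelse(n_below > 0, n_below / n_universe, NA_real_))

  # drop direct annotations to under-supported terms; ancestors keep their IC
  ok_terms <- names(n_below)[n_below >= min_genes]
  gene_terms <- map(gene_terms, ~ intersect(.x, ok_terms))
  keep <- lengths(gene_terms) > 0
  gene_terms <- gene_terms[keep]
  gene_closure <- map(gene_terms, ~ unique(unlist(anc[.x], use.names = FALSE)))

  structure(list(ic = ic, ancestors = anc, gene_terms = gene_terms,
                 gene_closure = gene_closure,
                 universe = names(gene_terms), n_genes = n_below,
                 namespace = namespace),
            class = "go_corpus")
}

#' @export
print.go_corpus <- function(x, ...) {
  cat(sprintf("<go_corpus> %s: %d terms, %d annotated genes\n",
              x$namespace, length(x$ic), length(x$universe)))
  invisible(x)
}

#' @export
tidy.go_corpus <- function(x, ...) {
  tibble(term = names(x$ic), ic = unname(x$ic),
         n_genes = unname(x$n_genes[names(x$ic)]))
}

#' Resnik semantic similarity between two genes
#'
#' The score is the maximum, over all pairs of terms annotated to the two
#' genes, of the information content of the most informative common ancestor.
#' Equivalently: the highest-IC term in the intersection of the two genes'
#' ancestor closures. Genes sharing only the root score `-ln(1) = 0`; an
#' unannotated gene gives `NA` (the pair is skipped downstream).
#'
#' @param corpus A `go_corpus` from [build_go_corpus()].
#' @param g1,g2 Gene ids.
#' @return Non-negative score, or `NA` if either gene is unannotated.
#' @export
resnik_similarity <- function(corpus, g1, g2) {
  c1 <- corpus$gene_closure[[g1]]
  c2 <- corpus$gene_closure[[g2]]
  if (is.null(c1) || is.null(c2)) return(NA_real_)
  common <- intersect(c1, c2)
  if (length(common) == 0) return(0)
  max(corpus$ic[common], na.rm = TRUE)
}

#' Mean pairwise score of a gene set
#'
#' Averages a pair metric over all unordered gene pairs of a set, skipping
#' pairs where the metric is undefined and, when `positions` and `min_gap` are
#' given, pairs of genes on the same chromosome closer than `min_gap` bp
#' (used to remove the contribution of genomic neighbours).
#'
#' @param genes Character vector of gene ids (>= 2).
#' @param score_fn Function `(g1, g2) -> number or NA`.
#' @param positions Optional gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param min_gap Optional minimum gap in bp for same-chromosome pairs.
#' @return Mean score, or `NA` when no pair has a defined score.
#' @export
mean_pairwise_score <- function(genes, score_fn, positions = NULL,
                                min_gap = NULL) {
  genes <- unique(genes)
  if (length(genes) < 2) return(NA_real_)
  pr <- combn(genes, 2)
  if (!is.null(min_gap) && !is.null(positions)) {
    i1 <- match(pr[1, ], positions$gene_id)
    i2 <- match(pr[2, ], positions$gene_id)
    same <- !is.na(i1) & !is.na(i2) &
      positions$chrom[i1] == positions$chrom[i2]
    g <- interval_gap(positions$start[i1], positions$end[i1],
                      positions$start[i2], positions$end[i2])
    keep <- !(same & g < min_gap)
    pr <- pr[, keep, drop = FALSE]
  }
  if (ncol(pr) == 0) return(NA_real_)
  vals <- map_dbl(seq_len(ncol(pr)), ~ score_fn(pr[1, .x], pr[2, .x]))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Pair metric factories
#'
#' `resnik_metric()` wraps a GO corpus; `coexpression_metric()` wraps an
#' expression matrix (genes x tissues) and returns the Pearson correlation of
#' the two genes' expression profiles (`NA` when a gene is missing or has a
#' constant profile).
#'
#' @param corpus A `go_corpus`.
#' @param expression Numeric matrix, genes as rownames.
#' @return A function `(g1, g2) -> numeric`.
#' @export
resnik_metric <- function(corpus) {
  function(g1, g2) resnik_similarity(corpus, g1, g2)
}

#' @rdname resnik_metric
#' @export
coexpression_metric <- function(expression) {
  function(g1, g2) {
    if (!(g1 %in% rownames(expression)) || !(g2 %in% rownames(expression))) {
      return(NA_real_)
    }
    profile_pcc(expression[g1, ], expression[g2, ])
  }
}

#' Cluster functional-coherence curves with random-gene controls
#'
#' For every DRE cluster with at least `min_targets` target genes the mean
#' pairwise score of its target set is computed (Resnik similarity or
#' co-expression correlation). Control replicates redraw, for each cluster, an
#' equal-sized random gene set from the universe where the metric is defined.
#' The curves report the proportion of clusters whose mean score exceeds each
#' cutoff, observed versus control; the p-value is the resampling probability
#' that a control replicate's curve lies as high (averaged over cutoffs) as
#' the observed one.
#'
#' @param cluster_targets Tibble from [cluster_summary()] with `cluster_id`
#'   and `target_genes` list column.
#' @param metric `"resnik"` or `"coexpression"`.
#' @param corpus `go_corpus`, required for the Resnik metric.
#' @param expression Genes x tissues matrix, required for co-expression.
#' @param cutoffs Numeric cutoff grid; defaults to 8 equally spaced values
#'   over the observed score range.
#' @param n_controls Number of control resamples (0 = observed curve only).
#' @param min_targets Minimum target-set size (default 3).
#' @param positions,min_gap Optional same-chromosome gene-pair distance filter
#'   (see [mean_pairwise_score()]), applied to observed and control sets alike.
#' @param seed Optional integer seed for the control resampling.
#' @return An object of class `cluster_curves`: list with `curves` tibble
#'   (`cutoff`, `observed`, `control_mean`, `control_sd`), `scores` per
#'   cluster, `p_value`, `metric`, `n_controls`.
#' @export
cluster_score_curves <- function(cluster_targets, metric = c("resnik", "coexpression"),
                                 corpus = NULL, expression = NULL,
                                 cutoffs = NULL, n_controls = 100,
                                 min_targets = 3, positions = NULL,
                                 min_gap = NULL, seed = NULL) {
  metric <- arg_match(metric)
  if (metric == "resnik") {
    if (is.null(corpus)) abort("the resnik metric needs a go_corpus")
    score_fn <- resnik_metric(corpus)
    universe <- corpus$universe
  } else {
    if (is.null(expression)) abort("the coexpression metric needs an expression matrix")
    score_fn <- coexpression_metric(expression)
    universe <- rownames(expression)
  }
  cl <- filter(cluster_targets, lengths(.data$target_genes) >= min_targets)
  if (nrow(cl) == 0) abort("no cluster has enough target genes")

  obs <- map_dbl(cl$target_genes, mean_pairwise_score, score_fn = score_fn,
                 positions = positions, min_gap = min_gap)
  dropped <- is.na(obs)
  if (any(dropped)) {
    inform(sprintf("dropping %d cluster(s) with no scorable gene pair",
                   sum(dropped)))
  }
  cl <- cl[!dropped, , drop = FALSE]
  obs <- obs[!dropped]
  if (length(obs) == 0) abort("no cluster has a scorable gene pair")

  if (is.null(cutoffs)) {
    cutoffs <- seq(min(obs), max(obs), length.out = 8)
  }
  observed_curve <- map_dbl(cutoffs, ~ mean(obs > .x))

  control_mat <- NULL
  p_value <- NA_real_
  if (n_controls > 0) {
    sizes <- lengths(cl$target_genes)
    draw <- function() {
      map_dbl(sizes, function(k) {
        mean_pairwise_score(sample(universe, k), score_fn,
                            positions = positions, min_gap = min_gap)
      })
    }
    run_controls <- function() {
      m <- matrix(NA_real_, nrow = n_controls, ncol = length(cutoffs))
      for (r in seq_len(n_controls)) {
        sc <- draw()
        sc <- sc[!is.na(sc)]
        m[r, ] <- if (length(sc)) map_dbl(cutoffs, ~ mean(sc > .x)) else 0
      }
      m
    }
    control_mat <- if (is.null(seed)) run_controls() else
      withr::with_seed(seed, run_controls())
    stat_obs <- mean(observed_curve)
    stat_ctl <- rowMeans(control_mat)
    p_value <- (1 + sum(stat_ctl >= stat_obs)) / (n_controls + 1)
  }

  curves <- tibble(
    cutoff = cutoffs,
    observed = observed_curve,
    control_mean = if (is.null(control_mat)) NA_real_ else colMeans(control_mat),
    control_sd = if (is.null(control_mat)) NA_real_ else
      apply(control_mat, 2, stats::sd)
  )
  structure(list(curves = curves,
                 scores = tibble(cluster_id = cl$cluster_id, mean_score = obs),
                 p_value = p_value, metric = metric, n_controls = n_controls),
            class = "cluster_curves")
}

#' @export
print.cluster_curves <- function(x, ...) {
  cat(sprintf("<cluster_curves> metric=%s, %d clusters, %d controls, p=%s\n",
              x$metric, nrow(x$scores), x$n_controls,
              format(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
tidy.cluster_curves <- function(x, ...) x$curves

#' @export
glance.cluster_curves <- function(x, ...) {
  tibble(metric = x$metric, n_clusters = nrow(x$scores),
         n_controls = x$n_controls, p_value = x$p_value,
         mean_observed = mean(x$scores$mean_score))
}

#' @export
autoplot.cluster_curves <- function(object, ...) {
  df <- object$curves
  p <- ggplot(df, aes(x = .data$cutoff))
  if (!all(is.na(df$control_mean))) {
    p <- p +
      geom_ribbon(aes(ymin = pmax(.data$control_mean - .data$control_sd, 0),
                      ymax = pmin(.data$control_mean + .data$control_sd, 1)),
                  fill = "grey80") +
      geom_line(aes(y = .data$control_mean), colour = "grey40",
                linetype = "dashed")
  }
  p + geom_line(aes(y = .data$observed), colour = "#d95f02") +
    labs(x = sprintf("mean %s cutoff", object$metric),
         y = "proportion of clusters above cutoff") +
    theme_bw()
}
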