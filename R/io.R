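#' Read genomic intervals from a BED file
#'
#' Parses a BED3+ file into a tibble of 0-based half-open intervals. The
#' optional 4th and 5th BED columns are kept as `name` and `score`; input order
#' is preserved. When no name column is present, stable identifiers
#' (`<prefix>_00001`, ...) are generated so downstream tables can refer to
#' individual features.
#'
#' @param path Path to a tab-separated BED file (at least 3 columns).
#' @param id_prefix Prefix used to synthesise `name` when the file has none.
#' @return A tibble with columns `chrom`, `start`, `end`, `name` and, when
#'   present in the file, `score`.
#' @export
read_bed <- function(path, id_prefix = "feat") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                  which(nf < 3)[1], path))
  }
  chrom <- map_chr(fields, 1)
  start <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                  which(is.na(start) | is.na(end))[1], path))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  out$name <- if (all(nf >= 4)) map_chr(fields, 4) else
    sprintf("%s_%05d", id_prefix, seq_along(chrom))
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(map_chr(fields, 5)))
  }
  check_intervals(out, what = sprintf("BED record in %s", path))
  out
}

#' Write a tibble of intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' Loads gene models from either a 5-column TSV (`gene_id`, `chrom`, `start`,
#' `end`, `strand`; 0-based half-open) or a GTF file (one `gene` feature per
#' gene, parsed through rtracklayer). The transcription start site is derived
#' from the strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param path Path to the gene table.
#' @param format `"tsv"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gene_table <- function(path, format = c("tsv", "gtf")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(genes))) {
      abort(sprintf("gene TSV must have columns %s", paste(need, collapse = ", ")))
    }
    genes <- genes[need]
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0) abort(sprintf("no gene features in GTF %s", path))
    genes <- tibble(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand symbol '%s' for gene %s",
                  genes$strand[!genes$strand %in% c("+", "-")][1],
                  genes$gene_id[!genes$strand %in% c("+", "-")][1]))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) abort(sprintf("duplicate gene_id: %s", dup[1]))
  check_intervals(genes, what = "gene record")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  as_tibble(genes)
}

#' Read per-species alignment blocks
#'
#' Loads one BED file of human-coordinate alignment blocks per species from a
#' directory. The species order given in `species` is preserved pipeline-wide
#' (it fixes the position of each species in every phylogenetic profile).
#' Overlapping blocks within a species are retained as-is: downstream code
#' treats coverage as binary, so multiple homologous blocks simply mean
#' "present".
#'
#' @param dir Directory containing `<species>.bed` files.
#' @param species Character vector of species names fixing the profile order.
#' @return A tibble with columns `species` (factor with levels in the given
#'   order), `chrom`, `start`, `end`.
#' @export
read_alignment_blocks <- function(dir, species) {
  if (!dir.exists(dir)) abort(sprintf("directory not found: %s", dir))
  files <- list.files(dir, pattern = "\\.bed$")
  found <- sub("\\.bed$", "", files)
  extra <- setdiff(found, species)
  if (length(extra) > 0) {
    warn(sprintf("skipping species not in the configured list: %s",
                 paste(extra, collapse = ", ")))
  }
  missing <- setdiff(species, found)
  if (length(missing) > 0) {
    abort(sprintf("no alignment file for listed species: %s",
                  paste(missing, collapse = ", ")))
  }
  blocks <- map(species, function(sp) {
    b <- read_bed(file.path(dir, paste0(sp, ".bed")))
    b$species <- sp
    b
  })
  out <- bind_rows(blocks)
  out$species <- factor(out$species, levels = species)
  out[c("species", "chrom", "start", "end")]
}

#' Read Hi-C contacts from a BEDPE file
#'
#' Each BEDPE record becomes one contact; the mapped position of each end is
#' the floor midpoint of its interval. Records are tagged with `dataset_id`
#' (cell line x replicate label).
#'
#' @param path Path to a BEDPE file (at least 6 tab-separated columns).
#' @param dataset_id Label for the cell line x replicate this file comes from.
#' @return A tibble with columns `dataset_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`.
#' @export
read_bedpe_contacts <- function(path, dataset_id) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(dataset_id = character(), chrom1 = character(),
                  pos1 = integer(), chrom2 = character(), pos2 = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("malformed BEDPE line %d in %s: fewer than 6 columns",
                  which(nf < 6)[1], path))
  }
  s1 <- as.integer(map_chr(fields, 2)); e1 <- as.integer(map_chr(fields, 3))
  s2 <- as.integer(map_chr(fields, 5)); e2 <- as.integer(map_chr(fields, 6))
  bad <- which(e1 <= s1 | e2 <= s2 | s1 < 0 | s2 < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid BEDPE line %d in %s: zero-length or negative end interval",
                  bad[1], path))
  }
  tibble(
    dataset_id = dataset_id,
    chrom1 = map_chr(fields, 1),
    pos1 = (s1 + e1) %/% 2L,
    chrom2 = map_chr(fields, 4),
    pos2 = (s2 + e2) %/% 2L
  )
}

#' Total contact count per dataset
#'
#' Used to pick the lower-coverage replicate when computing repeatability.
#'
#' @param contacts Contact tibble from [read_bedpe_contacts()] (rows from
#'   several datasets may be bound together).
#' @return Named integer vector of contact counts keyed by `dataset_id`.
#' @export
dataset_totals <- function(contacts) {
  tab <- table(contacts$dataset_id)
  setNames(as.integer(tab), names(tab))
}

#' Write predictions to a TSV file
#'
#' Output is deterministically ordered by DRE locus (`chrom`, `start`, `end`)
#' and then `gene_id`, so identical prediction sets always produce
#' byte-identical files.
#'
#' @param predictions Prediction tibble from [predict_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(is.data.frame(predictions))
  out <- arrange(predictions, .data$chrom, .data$start, .data$end, .data$gene_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return A prediction tibble.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a genes-by-tissues expression matrix
#'
#' @param path TSV with a `gene_id` column followed by one column per tissue.
#' @return A numeric matrix with genes as rownames and tissues as columns.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") abort("expression TSV must start with gene_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read gene-to-GO-term annotations
#'
#' @param path TSV with columns `gene_id`, `term` and optionally `evidence`.
#' @return A tibble with those columns (`evidence` filled with `NA` if absent).
#' @export
read_go_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "term") %in% names(df))) {
    abort("annotation TSV must have columns gene_id, term")
  }
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  as_tibble(df[c("gene_id", "term", "evidence")])
}
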