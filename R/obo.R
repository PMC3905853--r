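#' Read a GO DAG from an OBO file
#'
#' A minimal OBO 1.2 parser covering what the semantic-similarity analysis
#' needs: `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete`. Only `is_a` edges are read; `relationship:` edges (part_of
#' etc.) are deliberately ignored.
#'
#' @param path Path to an OBO file.
#' @return A tibble with columns `term`, `name`, `namespace`, `parents`
#'   (list column of parent term ids) and `obsolete`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) abort(sprintf("no [Term] stanzas in %s", path))
  bounds <- c(starts, length(lines) + 1L)
  terms <- map(seq_along(starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    get1 <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ": "))]
      if (length(v) == 0) return(NA_character_)
      sub(paste0("^", key, ": "), "", v[1])
    }
    isa <- chunk[startsWith(chunk, "is_a: ")]
    parents <- trimws(sub("!.*$", "", sub("^is_a: ", "", isa)))
    tibble(
      term = get1("id"),
      name = get1("name"),
      namespace = get1("namespace"),
      parents = list(parents),
      obsolete = identical(get1("is_obsolete"), "true")
    )
  })
  out <- bind_rows(terms)
  if (anyNA(out$term)) abort(sprintf("[Term] stanza without id in %s", path))
  out
}
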