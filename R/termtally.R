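#' Read a gene-to-GO-term map
#'
#' Accepts either GAF 2.x (tab-separated, `!` comment lines; columns 2, 5
#' and 9 give the gene id, GO id and aspect) or a headered two-plus-column
#' TSV (`gene_id`, `term_id`, optional `ontology`, optional `term_name`).
#' Malformed lines (wrong column count or a term id not matching
#' `GO:NNNNNNN`) are skipped with a message naming their position. The map
#' is assumed pre-slimmed; no DAG propagation is done.
#'
#' @param path file path.
#' @return data.frame: gene_id, term_id, ontology (`BP`/`MF`/`CC` or `NA`),
#'   term_name (`NA` when unavailable), one row per annotation instance.
#' @export
read_term_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop2("empty term-map file: ", path)
  first_body <- lines[which(!startsWith(lines, "!") & nzchar(lines))[1]]
  is_gaf <- grepl("^!gaf-version", lines[1]) ||
    (!is.na(first_body) && length(strsplit(first_body, "\t")[[1]]) >= 15)
  if (is_gaf) {
    body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
    rows <- list()
    for (i in body_idx) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 15 || !grepl("^GO:[0-9]{7}$", f[5])) {
        message("skipping malformed GAF line ", i)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = f[2], term_id = f[5],
                   ontology = c(P = "BP", F = "MF", C = "CC")[f[9]],
                   term_name = NA_character_, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) stop2("no valid GAF annotation lines in ", path)
    map <- do.call(rbind, rows)
  } else {
    map <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "term_id") %in% names(map)))
      stop2("term-map TSV needs columns gene_id, term_id")
    if (!"ontology" %in% names(map)) map$ontology <- NA_character_
    if (!"term_name" %in% names(map)) map$term_name <- NA_character_
    bad <- !grepl("^GO:[0-9]{7}$", map$term_id)
    if (any(bad)) {
      message("skipping ", sum(bad), " row(s) with malformed term ids")
      map <- map[!bad, , drop = FALSE]
    }
    map <- map[, c("gene_id", "term_id", "ontology", "term_name")]
  }
  rownames(map) <- NULL
  map
}

#' Tally GO-slim terms over enriched gene lists
#'
#' For each condition's gene list, a term's instance count is the number of
#' (gene, term) annotation pairs among that list's genes — a gene annotated
#' to the same term twice contributes twice, matching an instance tally of
#' retrieved annotations (set `unique_genes = TRUE` to count distinct genes
#' instead). A term is marked for display when its count at any condition
#' reaches `min_instances` (`>=` by default; `strict = TRUE` demands `>`).
#' Genes absent from the map are reported per condition, not dropped
#' silently.
#'
#' @param de_genes named list of character vectors, one per condition
#'   (e.g. `list(D6 = ..., D21 = ...)`).
#' @param map annotation map from [read_term_map()] (or an equivalent
#'   data.frame).
#' @param min_instances display threshold (default 10).
#' @param strict require strictly more than `min_instances` instead of at
#'   least.
#' @param unique_genes count distinct annotated genes rather than
#'   annotation instances.
#' @return data.frame of class `term_tally`: term_id, ontology, term_name,
#'   one `count_<condition>` column per condition, and `display`; genes
#'   missing from the map are in `attr(, "unmapped")` (named list).
#' @export
tally_terms <- function(de_genes, map, min_instances = 10,
                        strict = FALSE, unique_genes = FALSE) {
  if (is.null(names(de_genes)) || any(!nzchar(names(de_genes))))
    stop2("de_genes must be a named list of conditions")
  if (!all(c("gene_id", "term_id") %in% names(map)))
    stop2("map needs columns gene_id, term_id")
  if (!"ontology" %in% names(map)) map$ontology <- NA_character_
  if (!"term_name" %in% names(map)) map$term_name <- NA_character_
  terms <- unique(map[, c("term_id", "ontology", "term_name"), drop = FALSE])
  terms <- terms[!duplicated(terms$term_id), , drop = FALSE]
  terms <- terms[order(terms$term_id), , drop = FALSE]
  unmapped <- list()
  for (cond in names(de_genes)) {
    genes <- de_genes[[cond]]
    unmapped[[cond]] <- sort(setdiff(genes, map$gene_id))
    hits <- map[map$gene_id %in% genes, , drop = FALSE]
    if (unique_genes)
      hits <- hits[!duplicated(hits[, c("gene_id", "term_id")]), ,
                   drop = FALSE]
    cnt <- table(factor(hits$term_id, levels = terms$term_id))
    terms[[paste0("count_", cond)]] <- as.integer(cnt)
  }
  count_cols <- paste0("count_", names(de_genes))
  mx <- do.call(pmax, terms[count_cols])
  terms$display <- if (strict) mx > min_instances else mx >= min_instances
  rownames(terms) <- NULL
  structure(terms, unmapped = unmapped,
            class = c("term_tally", "data.frame"))
}
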