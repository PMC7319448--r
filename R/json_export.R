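#' Export a pipeline result as JSON
#'
#' Deterministic JSON for downstream analysis: keys sorted, versioned
#' `schema` field, and a `parameters` block recording every applied
#' parameter including defaulted ones (the default operon gap is observable
#' here). Gene coordinates are exported 1-based inclusive.
#'
#' @param result a `domains_result` or `neighborhoods_result`.
#' @param path optional output file.
#' @return JSON text (single string).
#' @export
export_json <- function(result, path = NULL) {
  UseMethod("export_json")
}

#' @export
export_json.domains_result <- function(result, path = NULL) {
  feats <- result$architectures
  doc <- list(
    schema = "phylotracks-domains/1",
    parameters = result$metadata,
    tree = write_newick(result$tree),
    leaves = as.list(order_leaves(result$tree)),
    alignment = purrr::map2(result$alignment$id, result$alignment$residues,
                            function(i, r) list(id = i, residues = r)),
    features = if (nrow(feats) == 0L) list() else
      unname(purrr::map(split(feats, feats$protein_id)[
        unique(feats$protein_id)], function(f)
          list(protein_id = f$protein_id[1],
               features = purrr::pmap(
                 f[c("kind", "source", "accession", "name", "start", "end",
                     "bit_score", "evalue")], list))))
  )
  finish_json(doc, "domains", path)
}

#' @export
export_json.neighborhoods_result <- function(result, path = NULL) {
  nb <- result$neighborhoods
  ann <- dplyr::select(result$genes, "gene_id", "cluster_id", "operon_id",
                       "domain_accessions")
  queries <- unique(nb$leaf_name)
  doc <- list(
    schema = "phylotracks-neighborhoods/1",
    parameters = result$metadata$parameters,
    tree_source = result$metadata$tree_source,
    tree = write_newick(result$tree),
    queries = purrr::map(queries, function(leaf) {
      genes <- nb[nb$leaf_name == leaf, ]
      genes <- dplyr::left_join(genes, ann, by = "gene_id")
      list(
        leaf = leaf,
        query_gene_id = genes$query_gene_id[1],
        truncated_left = genes$truncated_left[1],
        truncated_right = genes$truncated_right[1],
        wrapped = genes$wrapped[1],
        genes = purrr::pmap(
          list(genes$gene_id, genes$locus_tag, genes$protein_id,
               genes$replicon_id, genes$start, genes$end, genes$strand,
               genes$product, genes$is_query, genes$cluster_id,
               genes$operon_id, genes$domain_accessions),
          function(gid, lt, pid, rep, s, e, st, prod, isq, cid, oid, doms) {
            list(gene_id = gid, locus_tag = lt, protein_id = pid,
                 replicon_id = rep,
                 start = s + 1L, end = e,      # 1-based inclusive on export
                 strand = st, product = prod, is_query = isq,
                 cluster_id = cid, operon_id = oid,
                 domain_accessions = as.list(doms))
          })
      )
    }),
    clusters = purrr::pmap(
      list(result$clusters$gene_id, result$clusters$cluster_id),
      function(g, c) list(gene_id = g, cluster_id = c)),
    operons = purrr::pmap(
      dplyr::select(result$operons, "operon_id", "replicon_id", "strand",
                    "gene_id", "position"), list)
  )
  finish_json(doc, "neighborhoods", path)
}

finish_json <- function(doc, kind, path) {
  doc <- sort_keys_recursive(doc)
  schema <- jsonlite::read_json(
    system.file("extdata", "schema", paste0(kind, ".schema.json"),
                package = "phylotracks"))
  ok <- validate_against_schema(doc, schema)
  if (!isTRUE(ok)) stop("internal error: JSON fails shipped schema: ", ok,
                        call. = FALSE)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                          na = "null", digits = NA, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

sort_keys_recursive <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    x[] <- lapply(x, sort_keys_recursive)
  }
  x
}

#' Validate a document against a shipped JSON schema
#'
#' Minimal structural validator covering the subset of JSON Schema used by
#' the shipped schemas: `type`, `required`, `properties`, `items`, `enum`.
#'
#' @param doc an R list representing the JSON document.
#' @param schema an R list representing the schema.
#' @param where JSON-path prefix used in violation messages.
#' @return `TRUE`, or a character description of the first violation.
#' @export
validate_against_schema <- function(doc, schema, where = "$") {
  is_na_scalar <- function(x) length(x) == 1L && !is.list(x) && is.na(x)
  type_of <- function(x) {
    if (is.null(x) || is_na_scalar(x)) "null"
    else if (is.list(x)) {
      if (!is.null(names(x)) && length(x) > 0L && all(nzchar(names(x))))
        "object" else "array"
    }
    else if (is.character(x)) "string"
    else if (is.logical(x)) "boolean"
    else if (is.numeric(x)) {
      if (all(x == floor(x))) "integer" else "number"
    }
    else "unknown"
  }
  t <- type_of(doc)
  if (!is.null(schema$type)) {
    ok_types <- unlist(schema$type)
    ok <- t %in% ok_types ||
      (t == "integer" && "number" %in% ok_types) ||
      (length(doc) == 0L && t %in% c("array", "object") &&
         any(c("array", "object") %in% ok_types))
    if (!ok) {
      return(paste0(where, ": expected type ",
                    paste(ok_types, collapse = "|"), ", got ", t))
    }
    if (t == "null") return(TRUE)
  }
  if (!is.null(schema$enum)) {
    if (!doc %in% unlist(schema$enum)) {
      return(paste0(where, ": value not in enum"))
    }
  }
  if (!is.null(schema$required)) {
    miss <- setdiff(unlist(schema$required), names(doc))
    if (length(miss) > 0L) {
      return(paste0(where, ": missing required key(s) ",
                    paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(schema$properties) && is.list(doc)) {
    for (k in intersect(names(schema$properties), names(doc))) {
      r <- validate_against_schema(doc[[k]], schema$properties[[k]],
                                   paste0(where, ".", k))
      if (!isTRUE(r)) return(r)
    }
  }
  if (!is.null(schema$items) && is.list(doc) &&
      (is.null(names(doc)) || !all(nzchar(names(doc))))) {
    for (i in seq_along(doc)) {
      r <- validate_against_schema(doc[[i]], schema$items,
                                   paste0(where, "[", i, "]"))
      if (!isTRUE(r)) return(r)
    }
  }
  TRUE
}
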