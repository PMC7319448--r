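#' Run the neighborhoods pipeline
#'
#' Full gene-neighborhood analysis: the input (sequences, MSA, Newick tree or
#' identifier list — auto-detected) defines the query proteins and the tree;
#' each query's neighborhood is extracted from the genome annotation; all
#' neighborhood genes are clustered by shared domain content; operons are
#' called per replicon by intergenic distance, restricted to the genomic
#' spans the neighborhoods cover.
#'
#' @param input query input: FASTA/Newick/id-list text, a records tibble, or
#'   a `phylo` tree.
#' @param annotation a [genome_annotation()] or list of them (merged).
#' @param hits tibble of feature hits used to attach domain content.
#' @param config a [neighborhoods_config()].
#' @param sequences optional sequence store (records tibble) used to build a
#'   tree when the input is an identifier list.
#' @param domains_cfg a [domains_config()] controlling hit filtering and the
#'   builtin tree backend.
#' @return a `neighborhoods_result`: list with `tree`, `neighborhoods`
#'   (one row per gene per query), `genes` (clustered union), `clusters`,
#'   `operons`, `metadata`.
#' @export
run_neighborhoods_pipeline <- function(input, annotation, hits = empty_hits(),
                                       config = neighborhoods_config(),
                                       sequences = NULL,
                                       domains_cfg = domains_config()) {
  if (is.list(annotation) && !inherits(annotation, "genome_annotation")) {
    annotation <- merge_annotations(annotation)
  }
  stopifnot(inherits(annotation, "genome_annotation"))

  tree_source <- NULL
  if (inherits(input, "phylo")) {
    tree <- input
    tree_source <- "user"
  } else if (is.data.frame(input)) {
    tree <- build_query_tree(input, domains_cfg)
    tree_source <- if (is_alignment(input)) "built_from_alignment"
                   else "built_from_sequences"
  } else {
    type <- detect_input_type(input)
    if (type == "newick") {
      tree <- read_newick(input)
      tree_source <- "user"
    } else if (type %in% c("sequences", "alignment")) {
      recs <- read_fasta(input)
      tree <- build_query_tree(recs, domains_cfg)
      tree_source <- paste0("built_from_", type)
    } else {                                   # id_list
      ids <- trimws(strsplit(paste(as_text_lines(input), collapse = "\n"),
                             "\n", fixed = TRUE)[[1]])
      ids <- ids[nzchar(ids)]
      if (is.null(sequences)) {
        stop("id_list input requires a sequence store to build the tree",
             call. = FALSE)
      }
      missing <- setdiff(ids, sequences$id)
      if (length(missing) > 0L) {
        stop("ids not in sequence store: ",
             paste(sQuote(missing), collapse = ", "), call. = FALSE)
      }
      recs <- sequences[match(ids, sequences$id), ]
      tree <- build_query_tree(recs, domains_cfg)
      tree_source <- "built_from_id_list"
    }
  }

  leaf_order <- order_leaves(tree)
  query_ids <- parse_leaf_id(leaf_order)

  g <- annotation$genes
  resolvable <- query_ids %in% g$gene_id |
    query_ids %in% stats::na.omit(g$locus_tag) |
    query_ids %in% stats::na.omit(g$protein_id)
  if (any(!resolvable)) {
    stop("query protein(s) with no gene in the annotation: ",
         paste(sQuote(query_ids[!resolvable]), collapse = ", "),
         call. = FALSE)
  }

  architectures <- build_architectures(hits, domains_cfg)

  nbhd <- purrr::map2_dfr(query_ids, leaf_order, function(qid, leaf) {
    nb <- extract_neighborhood(annotation, qid, config$window)
    nb$leaf_name <- leaf
    nb$truncated_left <- attr(nb, "truncated_left")
    nb$truncated_right <- attr(nb, "truncated_right")
    nb$wrapped <- attr(nb, "wrapped")
    nb
  })

  # union of neighborhood genes, ordered by first appearance scanning the
  # tree top-to-bottom and each neighborhood left-to-right: this order
  # defines cluster ids (and later, colors)
  union_genes <- dplyr::distinct(nbhd, .data$gene_id, .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(names(annotation$genes)))
  clusters <- cluster_genes(union_genes, architectures, config$nonshared_max)

  # operons per replicon, over maximal annotation-contiguous runs of the
  # union genes (neighborhoods are contiguous, so their union is a set of
  # contiguous blocks; blocks are never bridged)
  with_idx <- union_genes |>
    dplyr::mutate(.ann_idx = match(.data$gene_id,
                                   annotation$genes$gene_id)) |>
    dplyr::arrange(.data$.ann_idx)
  blocks <- split(seq_len(nrow(with_idx)),
                  paste(with_idx$replicon_id,
                        cumsum(c(1L, diff(with_idx$.ann_idx) != 1L))))
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  operons <- purrr::map_dfr(blocks, function(idx) {
    detect_operons(with_idx[idx, setdiff(names(with_idx), ".ann_idx")],
                   config)
  })
  if (nrow(operons) > 0L) {
    # renumber sequentially in genomic scan order; ids are unique run-wide
    key <- cumsum(c(TRUE, operons$position[-1L] == 1L))
    operons$operon_id <- key
  }

  genes_out <- union_genes |>
    dplyr::left_join(dplyr::select(clusters, "gene_id", "cluster_id"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::select(operons, "gene_id", "operon_id"),
                     by = "gene_id") |>
    dplyr::mutate(domain_accessions = lapply(.data$protein_id,
                                             gene_domain_set, architectures))

  meta <- list(
    parameters = list(window = config$window,
                      nonshared_max = config$nonshared_max,
                      operon_gap_max = config$operon_gap_max,
                      require_same_strand = config$require_same_strand,
                      evalue_max = domains_cfg$evalue_max,
                      overlap_fraction_max = domains_cfg$overlap_fraction_max),
    tree_source = tree_source,
    n_queries = length(query_ids),
    wrapped_queries = unique(nbhd$query_gene_id[nbhd$wrapped])
  )

  structure(list(tree = tree, neighborhoods = nbhd, genes = genes_out,
                 clusters = clusters, operons = operons,
                 architectures = architectures, metadata = meta),
            class = "neighborhoods_result")
}

#' @export
print.neighborhoods_result <- function(x, ...) {
  cat("<neighborhoods_result> ", x$metadata$n_queries, " queries, ",
      nrow(x$genes), " genes, ",
      length(unique(stats::na.omit(x$genes$cluster_id))), " clusters, ",
      length(unique(x$operons$operon_id)), " operons\n", sep = "")
  invisible(x)
}

build_query_tree <- function(records, domains_cfg) {
  if (nrow(records) < 3L) {
    stop("need at least 3 sequences to build a tree", call. = FALSE)
  }
  dm <- kmer_distance_matrix(degap(records), k = domains_cfg$kmer_size)
  nj_tree(dm)
}

merge_annotations <- function(annotations) {
  stopifnot(all(vapply(annotations, inherits, logical(1),
                       "genome_annotation")))
  genome_annotation(
    genes = dplyr::bind_rows(lapply(annotations, `[[`, "genes")),
    replicons = dplyr::bind_rows(lapply(annotations, `[[`, "replicons"))
  )
}
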