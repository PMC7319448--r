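#' Run the domains pipeline
#'
#' End-to-end analysis for protein families: optional redundancy reduction,
#' feature filtering and overlap resolution into domain architectures, tree
#' construction (built-in k-mer + neighbor joining, or an external command),
#' MSA sorting by tree leaf order and optional enumeration.
#'
#' Input may be unaligned sequences, a pre-aligned FASTA (the aligner is then
#' skipped), or — in partial mode — a user tree that is used verbatim while
#' only the non-tree steps run. In two-area mode (`input2`) the tree is built
#' from sequence fragments while architectures are computed on the
#' full-length sequences, joined by shared ids.
#'
#' @param input sequence records (tibble from [read_fasta()]) or FASTA text.
#' @param config a [domains_config()].
#' @param hits tibble of feature hits (from [read_domtblout()] or
#'   [read_hits_tsv()]); `NULL` with `skip_features = TRUE` for tree-only use.
#' @param tree user tree (`phylo` or Newick text), required in partial mode.
#' @param input2 optional fragment records for two-area mode: the tree is
#'   built from these, features from `input`.
#' @return a `domains_result`: list with `tree`, `architectures`,
#'   `alignment`, `metadata`.
#' @export
run_domains_pipeline <- function(input, config = domains_config(),
                                 hits = NULL, tree = NULL, input2 = NULL) {
  records <- if (is.data.frame(input)) input else read_fasta(input)
  if (!is.null(input2) && !is.data.frame(input2)) input2 <- read_fasta(input2)
  if (!is.null(tree) && !inherits(tree, "phylo")) tree <- read_newick(tree)
  if (config$mode == "partial" && is.null(tree)) {
    stop("partial mode requires a tree", call. = FALSE)
  }
  if (config$skip_features && config$mode == "partial") {
    stop("nothing to do: features skipped and tree supplied", call. = FALSE)
  }
  meta <- list(
    mode = config$mode,
    evalue_max = config$evalue_max,
    overlap_fraction_max = config$overlap_fraction_max,
    identity_threshold = config$identity_threshold,
    enumerate_leaves = config$enumerate_leaves,
    skip_features = config$skip_features,
    tree_backend = if (config$mode == "partial") "user"
                   else config$tree_backend,
    aligner_backend = config$aligner_backend,
    kmer_size = config$kmer_size,
    two_area = !is.null(input2)
  )

  membership <- NULL
  if (!is.null(config$identity_threshold)) {
    if (is_alignment(records)) {
      stop("reduce before aligning: redundancy reduction needs ungapped input",
           call. = FALSE)
    }
    red <- reduce_redundancy(records, config$identity_threshold)
    records <- red$representatives
    membership <- red$membership
  }

  architectures <- empty_hits()
  if (!config$skip_features) {
    if (is.null(hits)) hits <- empty_hits()
    keep <- hits$protein_id %in% records$id
    architectures <- build_architectures(hits[keep, ], config)
  }

  tree_input <- records
  if (!is.null(input2)) {
    if (!setequal(records$id, input2$id)) {
      stop("two-area mode requires identical id sets; differing: ",
           paste(sQuote(c(setdiff(records$id, input2$id),
                          setdiff(input2$id, records$id))), collapse = ", "),
           call. = FALSE)
    }
    tree_input <- input2   # fragments drive the tree in two-area mode
  }

  aligned <- is_alignment(tree_input)
  alignment <- tree_input
  if (!aligned && config$aligner_backend == "external") {
    alignment <- run_external_aligner(tree_input, config$aligner_cmd)
    aligned <- TRUE
  }
  meta$alignment_skipped <- aligned && config$aligner_backend != "external"

  if (config$mode == "partial") {
    out_tree <- tree
  } else if (config$tree_backend == "external") {
    out_tree <- run_external_treebuilder(alignment, config$treebuilder_cmd)
  } else {
    dm <- kmer_distance_matrix(degap(alignment), k = config$kmer_size)
    out_tree <- nj_tree(dm)
  }

  sorted <- sort_alignment_by_tree(alignment, out_tree)
  if (config$enumerate_leaves) {
    en <- enumerate_leaves(out_tree, sorted)
    out_tree <- en$tree
    sorted <- en$alignment
  }

  structure(list(tree = out_tree,
                 architectures = architectures,
                 alignment = sorted,
                 membership = membership,
                 metadata = meta),
            class = "domains_result")
}

#' @export
print.domains_result <- function(x, ...) {
  cat("<domains_result> ", length(x$tree$tip.label), " leaves, ",
      nrow(x$architectures), " resolved features (",
      length(unique(x$architectures$protein_id)), " proteins)\n", sep = "")
  invisible(x)
}

run_external_aligner <- function(records, cmd_template) {
  if (is.null(cmd_template)) {
    stop("external aligner requested but no aligner_cmd given", call. = FALSE)
  }
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta(records, path = fin)
  run_template(cmd_template, fin, fout)
  read_fasta(fout)
}

run_external_treebuilder <- function(records, cmd_template) {
  if (is.null(cmd_template)) {
    stop("external tree builder requested but no treebuilder_cmd given",
         call. = FALSE)
  }
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(fin, fout)))
  write_fasta(records, path = fin)
  run_template(cmd_template, fin, fout)
  read_newick(fout)
}

# substitute {input}/{output} and run through the shell; the template owns
# redirection (e.g. "mafft {input} > {output}")
run_template <- function(template, input, output) {
  cmd <- gsub("{input}", shQuote(input),
              gsub("{output}", shQuote(output), template, fixed = TRUE),
              fixed = TRUE)
  # the template owns stdout (usually "... > {output}"); only mute stderr
  status <- system(cmd, ignore.stdout = FALSE, ignore.stderr = TRUE)
  if (status != 0L || !file.exists(output)) {
    stop("external command failed (exit ", status, "): ", cmd, call. = FALSE)
  }
  invisible(output)
}
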