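#' Specification for the synthetic-data generator
#'
#' Defines a small prokaryote-like test genome with planted, separable
#' structure: operons are runs of co-oriented genes with small intra-operon
#' gaps, singleton genes are separated by large gaps, and gene families share
#' a planted domain-accession set. Defaults emulate typical bacterial gene
#' density (~1 gene/kb, genes 300-1500 bp) with gap classes chosen well
#' apart (50 bp inside operons, 500 bp between transcription units) so that
#' a 200 bp threshold separates them.
#'
#' @param seed mandatory integer seed; the single source of randomness.
#' @param n_replicons number of replicons (default 2).
#' @param genes_per_replicon genes on each replicon (default 12).
#' @param operon_sizes gene counts of the operons planted on each replicon
#'   (default `c(3, 2)`).
#' @param intra_gap intergenic gap inside planted operons, bp (default 50).
#' @param inter_gap gap between transcription units, bp (default 500).
#' @param domain_families list of character vectors: the domain-accession
#'   sets of the planted gene families.
#' @param p_domainless fraction of genes left without any domain hit
#'   (default 0.15).
#' @param n_queries number of query genes drawn per genome (default 4).
#' @param tree_leaves leaves of the synthetic tree (default 6).
#' @param sub_rate per-site substitution rate per unit branch length for
#'   sequence evolution (default 0.5).
#' @param circular mark replicons circular (default `FALSE`).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_replicons = 2L, genes_per_replicon = 12L,
                         operon_sizes = c(3L, 2L), intra_gap = 50L,
                         inter_gap = 500L,
                         domain_families = list(c("PF00015", "PF00512"),
                                                c("PF00072"),
                                                c("PF00989", "PF08447"),
                                                c("PF00126")),
                         p_domainless = 0.15, n_queries = 4L,
                         tree_leaves = 6L, sub_rate = 0.5,
                         circular = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (intra_gap >= inter_gap) {
    stop("intra_gap must be < inter_gap (planted operons must be separable)",
         call. = FALSE)
  }
  stopifnot(sum(operon_sizes) <= genes_per_replicon, all(operon_sizes >= 2L),
            tree_leaves >= 3L, sub_rate >= 0)
  structure(list(seed = as.integer(seed), n_replicons = as.integer(n_replicons),
                 genes_per_replicon = as.integer(genes_per_replicon),
                 operon_sizes = as.integer(operon_sizes),
                 intra_gap = as.integer(intra_gap),
                 inter_gap = as.integer(inter_gap),
                 domain_families = domain_families,
                 p_domainless = p_domainless,
                 n_queries = as.integer(n_queries),
                 tree_leaves = as.integer(tree_leaves),
                 sub_rate = sub_rate, circular = isTRUE(circular)),
            class = "fixture_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic annotated genome with known ground truth
#'
#' Lays out genes with the planted gap structure and strands, assigns each
#' gene a domain family (or none), and emits the GFF3 annotation, the protein
#' FASTA, a feature-hit TSV (E-values far below the default cutoff) and a
#' truth record listing the planted operons, the family partition and the
#' query genes. Deterministic given the seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `gff3`, `fasta`, `hits_tsv` (text), `annotation`,
#'   `proteins`, `hits` (parsed objects) and `truth`.
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    genes <- list(); truth_operons <- list(); fam_of <- character(0)
    for (r in seq_len(spec$n_replicons)) {
      rid <- sprintf("rep%02d", r)
      n <- spec$genes_per_replicon
      # operon block sizes followed by singletons
      sizes <- c(spec$operon_sizes,
                 rep(1L, n - sum(spec$operon_sizes)))
      pos <- 1000L
      gi <- 0L
      for (b in seq_along(sizes)) {
        strand <- sample(c("+", "-"), 1L)
        block_ids <- character(0)
        for (s in seq_len(sizes[b])) {
          gi <- gi + 1L
          len <- 3L * sample(100L:500L, 1L)
          gid <- sprintf("%s_g%02d", rid, gi)
          pid <- sprintf("WP_%09d.1", r * 1000L + gi)
          fam <- if (stats::runif(1) < spec$p_domainless) NA_integer_
                 else sample(seq_along(spec$domain_families), 1L)
          genes[[length(genes) + 1L]] <- tibble::tibble(
            gene_id = gid, locus_tag = toupper(gid),
            protein_id = pid,
            replicon_id = rid, start = pos, end = pos + len,
            strand = strand,
            product = if (is.na(fam)) "hypothetical protein"
                      else sprintf("family %d protein", fam))
          fam_of[gid] <- fam
          block_ids <- c(block_ids, gid)
          pos <- pos + len +
            if (s < sizes[b]) spec$intra_gap else spec$inter_gap
        }
        if (sizes[b] >= 2L) {
          truth_operons[[length(truth_operons) + 1L]] <-
            list(replicon_id = rid, strand = strand, gene_ids = block_ids)
        }
      }
    }
    genes <- dplyr::bind_rows(genes)
    repl_len <- genes |>
      dplyr::group_by(.data$replicon_id) |>
      dplyr::summarise(length = max(.data$end) + 1000L)
    annotation <- genome_annotation(
      genes,
      tibble::tibble(replicon_id = repl_len$replicon_id,
                     length = repl_len$length,
                     circular = spec$circular))

    proteins <- tibble::tibble(
      id = genes$protein_id,
      description = genes$product,
      residues = vapply(
        (genes$end - genes$start) %/% 3L - 1L,
        function(l) paste(sample(AA20, l, replace = TRUE), collapse = ""),
        character(1)))

    fam_idx <- fam_of[genes$gene_id]
    hit_rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      f <- suppressWarnings(as.integer(fam_idx[i]))
      if (is.na(f)) return(empty_hits())
      accs <- spec$domain_families[[f]]
      plen <- nchar(proteins$residues[i])
      width <- max(20L, plen %/% (length(accs) + 1L))
      tibble::tibble(
        protein_id = genes$protein_id[i], kind = "domain", source = "pfam",
        accession = accs, name = accs,
        start = pmin(plen - width, 1L + (seq_along(accs) - 1L) * (width + 5L)),
        end = pmin(plen, 1L + (seq_along(accs) - 1L) * (width + 5L) + width - 1L),
        bit_score = round(stats::runif(length(accs), 50, 300), 1),
        evalue = 10^(-stats::runif(length(accs), 15, 40)))
    })

    families <- split(genes$gene_id[!is.na(fam_idx)],
                      fam_idx[!is.na(fam_idx)])
    queries <- sort(sample(genes$gene_id, spec$n_queries))
    truth <- list(operons = truth_operons,
                  families = unname(families),
                  family_of = fam_idx,
                  queries = queries)

    list(gff3 = write_gff3(annotation),
         fasta = write_fasta(proteins),
         hits_tsv = format_hits_tsv(hit_rows),
         annotation = annotation, proteins = proteins, hits = hit_rows,
         truth = truth)
  })
}

format_hits_tsv <- function(hits) {
  header <- paste(names(empty_hits()), collapse = "\t")
  if (nrow(hits) == 0L) return(paste0(header, "\n"))
  rows <- sprintf("%s\t%s\t%s\t%s\t%s\t%d\t%d\t%.1f\t%.3e",
                  hits$protein_id, hits$kind, hits$source, hits$accession,
                  hits$name, hits$start, hits$end, hits$bit_score,
                  hits$evalue)
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Generate a random tree with evolved sequences and its additive matrix
#'
#' Random topology by sequential leaf attachment: starting from a two-leaf
#' tree, each new leaf is attached to a uniformly chosen branch. Branch
#' lengths are uniform on (0.05, 0.5). Sequences evolve from a random root
#' sequence by per-site substitutions (Poisson counts proportional to branch
#' length, uniform replacement). The patristic (path-length) distance matrix
#' is returned alongside — it is additive on the emitted tree by
#' construction, which is what makes it an exact oracle for
#' neighbor joining.
#'
#' @param spec a [fixture_spec()] (uses `seed`, `tree_leaves`, `sub_rate`).
#' @param seq_length root sequence length (default 120).
#' @return list with `tree` (phylo), `records` (tibble), `fasta` (text),
#'   `dist` (additive matrix with leaf dimnames).
#' @export
synth_tree_and_sequences <- function(spec, seq_length = 120L) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 1L, {
    n <- spec$tree_leaves
    labels <- sprintf("T%02d", seq_len(n))
    # sequential attachment on the edge list of a rooted binary tree
    tree <- ape::read.tree(text = sprintf("(%s:%.6f,%s:%.6f);",
                                          labels[1], stats::runif(1, .05, .5),
                                          labels[2], stats::runif(1, .05, .5)))
    for (i in 3:n) {
      edge <- sample(nrow(tree$edge), 1L)
      tree <- ape::bind.tree(
        tree,
        read_newick(sprintf("%s:%.6f;", labels[i],
                            stats::runif(1, .05, .5))),
        where = tree$edge[edge, 2],
        position = tree$edge.length[edge] * stats::runif(1, 0.2, 0.8))
    }
    tree$node.label <- NULL
    tree <- ape::reorder.phylo(tree, "cladewise")   # preorder edge list
    d <- ape::cophenetic.phylo(tree)[labels, labels]

    root_seq <- sample(AA20, seq_length, replace = TRUE)
    evolve <- function(seq, len) {
      k <- stats::rpois(1, spec$sub_rate * len * length(seq))
      if (k > 0) {
        sites <- sample(length(seq), min(k, length(seq)))
        seq[sites] <- vapply(seq[sites], function(a)
          sample(setdiff(AA20, a), 1L), character(1))
      }
      seq
    }
    ntip <- length(tree$tip.label)
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root_seq
    # cladewise edges are in preorder: parents are filled before children
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      seqs[[child]] <- evolve(seqs[[parent]], tree$edge.length[e])
    }
    records <- tibble::tibble(
      id = tree$tip.label,
      description = "",
      residues = vapply(seqs[seq_len(ntip)], paste, character(1),
                        collapse = ""))
    records <- records[match(labels, records$id), ]
    list(tree = tree, records = records, fasta = write_fasta(records),
         dist = d)
  })
}
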