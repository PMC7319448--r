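#' Configuration for the neighborhoods pipeline
#'
#' @param window genes kept on each side of the query (default 5).
#' @param nonshared_max permitted number of non-shared domains (cardinality
#'   of the symmetric difference of domain sets) for two genes to be
#'   clustered together (default 0: identical sets).
#' @param operon_gap_max maximum intergenic distance, in base pairs, for two
#'   adjacent genes to be linked into an operon (default 200 bp, inclusive).
#' @param require_same_strand operons must be co-oriented (default `TRUE`);
#'   set `FALSE` for the distance-only rule.
#' @return a `neighborhoods_config` list.
#' @export
neighborhoods_config <- function(window = 5L, nonshared_max = 0L,
                                 operon_gap_max = 200L,
                                 require_same_strand = TRUE) {
  stopifnot(window >= 1L, nonshared_max >= 0L, operon_gap_max >= 0L)
  structure(list(window = as.integer(window),
                 nonshared_max = as.integer(nonshared_max),
                 operon_gap_max = as.integer(operon_gap_max),
                 require_same_strand = isTRUE(require_same_strand)),
            class = "neighborhoods_config")
}

#' Extract the gene neighborhood around a query gene
#'
#' Up to `window` genes on each side of the query, in genomic order on the
#' query's replicon. On linear replicons the window truncates at the ends
#' (`truncated_left`/`truncated_right` attributes); on circular replicons it
#' wraps around the origin (`wrapped` attribute) and genes keep their
#' original, unwrapped coordinates.
#'
#' @param annotation a [genome_annotation()].
#' @param query_gene_id gene id, locus tag or protein id of the query.
#' @param window genes per side.
#' @return tibble of genes in neighborhood order with columns of the gene
#'   table plus `query_gene_id`, `is_query`, `offset` (query = 0); attributes
#'   `truncated_left`, `truncated_right`, `wrapped`.
#' @export
extract_neighborhood <- function(annotation, query_gene_id, window = 5L) {
  stopifnot(inherits(annotation, "genome_annotation"), window >= 1L)
  g <- annotation$genes
  hit <- which(g$gene_id == query_gene_id |
                 (!is.na(g$locus_tag) & g$locus_tag == query_gene_id) |
                 (!is.na(g$protein_id) & g$protein_id == query_gene_id))
  if (length(hit) == 0L) {
    stop("unknown query gene: ", sQuote(query_gene_id), call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop("ambiguous query id ", sQuote(query_gene_id), " matches ",
         length(hit), " genes", call. = FALSE)
  }
  repl <- g$replicon_id[hit]
  ridx <- which(g$replicon_id == repl)        # genes already sorted by start
  pos <- match(hit, ridx)
  n <- length(ridx)
  circular <- isTRUE(annotation$replicons$circular[
    match(repl, annotation$replicons$replicon_id)])
  if (circular && n > 1L) {
    offsets <- (-window):window
    take <- ((pos - 1L + offsets) %% n) + 1L
    # if the window covers the whole circle, keep the copy nearest the query
    nearest <- order(abs(offsets))
    keep_idx <- sort(nearest[!duplicated(take[nearest])])
    offsets <- offsets[keep_idx]; take <- take[keep_idx]
    out <- g[ridx[take], ]
    out$offset <- offsets
    wrapped <- any(pos + offsets < 1L) || any(pos + offsets > n)
    tl <- FALSE; tr <- FALSE
  } else {
    lo <- max(1L, pos - window)
    hi <- min(n, pos + window)
    out <- g[ridx[lo:hi], ]
    out$offset <- (lo:hi) - pos
    tl <- (pos - window) < 1L
    tr <- (pos + window) > n
    wrapped <- FALSE
  }
  out$query_gene_id <- g$gene_id[hit]
  out$is_query <- out$offset == 0L
  attr(out, "truncated_left") <- tl
  attr(out, "truncated_right") <- tr
  attr(out, "wrapped") <- wrapped
  out
}

#' Are two domain sets compatible for clustering?
#'
#' Two genes may share a cluster when the symmetric difference of their
#' domain-accession sets has at most `k` elements. Two empty sets are never
#' compatible: genes without domains have no "shared domains" and are never
#' clustered.
#'
#' @param set_a,set_b character vectors of domain accessions.
#' @param k permitted number of non-shared domains.
#' @return logical scalar.
#' @export
compatible <- function(set_a, set_b, k = 0L) {
  stopifnot(k >= 0L)
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) return(FALSE)
  length(setdiff(a, b)) + length(setdiff(b, a)) <= k
}

#' Cluster genes by shared domain content
#'
#' Builds the compatibility graph over genes (edges where [compatible()])
#' and takes its connected components (single linkage) as clusters. With
#' `k = 0` this reduces to grouping by identical non-empty domain sets.
#' Domain-less genes remain unclustered (`NA` cluster id). Cluster ids are
#' contiguous from 1, numbered by first occurrence in the input row order.
#'
#' @param genes tibble of genes (needs `gene_id`, `protein_id`).
#' @param architectures tibble of resolved feature hits.
#' @param k permitted number of non-shared domains.
#' @return tibble `gene_id`, `cluster_id` (NA = unclustered),
#'   `domain_signature` (list column: the domain set of the first member).
#' @export
cluster_genes <- function(genes, architectures, k = 0L) {
  genes <- dplyr::distinct(genes, .data$gene_id, .keep_all = TRUE)
  sets <- lapply(genes$protein_id, gene_domain_set, architectures)
  n <- nrow(genes)
  clusterable <- which(lengths(sets) > 0L)
  comp <- rep(NA_integer_, n)
  if (length(clusterable) > 0L) {
    # identical sets are always compatible (k >= 0): group first, then
    # connect groups whose signatures differ by at most k
    sig <- vapply(sets, function(s) paste(s, collapse = "\r"), character(1))
    usig <- unique(sig[clusterable])
    usets <- lapply(strsplit(usig, "\r", fixed = TRUE), unique)
    m <- length(usig)
    edges <- integer(0)
    if (m > 1L && k > 0L) {
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          if (compatible(usets[[i]], usets[[j]], k)) edges <- c(edges, i, j)
        }
      }
    }
    gr <- igraph::make_empty_graph(n = m, directed = FALSE)
    if (length(edges) > 0L) gr <- igraph::add_edges(gr, edges)
    memb <- igraph::components(gr)$membership
    comp[clusterable] <- memb[match(sig[clusterable], usig)]
    # renumber by first occurrence in row order
    first_seen <- unique(comp[clusterable])
    comp <- match(comp, first_seen)
  }
  signature <- vector("list", n)
  for (cid in unique(stats::na.omit(comp))) {
    members <- which(comp == cid)
    signature[members] <- list(sets[[members[1]]])
  }
  tibble::tibble(gene_id = genes$gene_id, cluster_id = comp,
                 domain_signature = signature)
}

#' Detect operons by intergenic distance
#'
#' Scans adjacent gene pairs along a replicon: a pair is linked when the
#' intergenic gap `start(next) - end(prev)` (bases strictly between the
#' genes; negative when they overlap) is at most `operon_gap_max`, inclusive,
#' and — unless `require_same_strand = FALSE` — both genes are co-oriented.
#' Operons are the maximal linked runs of at least two genes.
#'
#' @param genes tibble of genes of one replicon, sorted by `start`.
#' @param config a [neighborhoods_config()].
#' @return tibble `operon_id`, `replicon_id`, `strand`, `gene_id`,
#'   `position` (1-based within the operon); zero rows when none found.
#' @export
detect_operons <- function(genes, config = neighborhoods_config()) {
  if (length(unique(genes$replicon_id)) > 1L) {
    stop("detect_operons expects genes of a single replicon", call. = FALSE)
  }
  if (is.unsorted(genes$start)) {
    stop("genes must be sorted by start", call. = FALSE)
  }
  n <- nrow(genes)
  empty <- tibble::tibble(operon_id = integer(), replicon_id = character(),
                          strand = character(), gene_id = character(),
                          position = integer())
  if (n < 2L) return(empty)
  gap <- genes$start[-1L] - genes$end[-n]
  linked <- gap <= config$operon_gap_max
  if (config$require_same_strand) {
    linked <- linked & genes$strand[-1L] == genes$strand[-n]
  }
  run_id <- cumsum(c(1L, !linked))          # genes in one run share an id
  runs <- split(seq_len(n), run_id)
  runs <- runs[lengths(runs) >= 2L]
  if (length(runs) == 0L) return(empty)
  purrr::imap_dfr(unname(runs), function(idx, oid) {
    tibble::tibble(operon_id = oid,
                   replicon_id = genes$replicon_id[idx],
                   strand = genes$strand[idx],
                   gene_id = genes$gene_id[idx],
                   position = seq_along(idx))
  })
}
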