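#' Configuration for the domains pipeline
#'
#' @param evalue_max maximum per-domain independent E-value for a domain hit
#'   to be retained (default 0.01). Transmembrane and low-complexity features
#'   are not E-value filtered.
#' @param overlap_fraction_max maximum tolerated overlap between two accepted
#'   domain hits, as a fraction of the shorter hit (default 0.2).
#' @param identity_threshold optional identity in (0, 1] enabling redundancy
#'   reduction before analysis; `NULL` disables it.
#' @param enumerate_leaves prefix leaves and alignment rows with display
#'   indices.
#' @param skip_features skip feature identification (tree-only use).
#' @param mode `"full"` or `"partial"` (user tree used verbatim).
#' @param tree_backend `"builtin_nj"` or `"external"` (command template).
#' @param aligner_backend `"builtin_identity_passthrough"` or `"external"`.
#' @param kmer_size k-mer length for the builtin distance (default 3).
#' @param aligner_cmd,treebuilder_cmd command templates for external backends;
#'   `{input}` and `{output}` placeholders are substituted.
#' @return a `domains_config` list.
#' @export
domains_config <- function(evalue_max = 0.01, overlap_fraction_max = 0.2,
                           identity_threshold = NULL,
                           enumerate_leaves = FALSE, skip_features = FALSE,
                           mode = c("full", "partial"),
                           tree_backend = c("builtin_nj", "external"),
                           aligner_backend = c("builtin_identity_passthrough",
                                               "external"),
                           kmer_size = 3L,
                           aligner_cmd = NULL, treebuilder_cmd = NULL) {
  stopifnot(evalue_max > 0,
            overlap_fraction_max >= 0, overlap_fraction_max <= 1,
            is.null(identity_threshold) ||
              (identity_threshold > 0 && identity_threshold <= 1),
            kmer_size >= 1)
  structure(list(evalue_max = evalue_max,
                 overlap_fraction_max = overlap_fraction_max,
                 identity_threshold = identity_threshold,
                 enumerate_leaves = isTRUE(enumerate_leaves),
                 skip_features = isTRUE(skip_features),
                 mode = match.arg(mode),
                 tree_backend = match.arg(tree_backend),
                 aligner_backend = match.arg(aligner_backend),
                 kmer_size = as.integer(kmer_size),
                 aligner_cmd = aligner_cmd,
                 treebuilder_cmd = treebuilder_cmd),
            class = "domains_config")
}

#' Filter feature hits by E-value
#'
#' Domain hits must satisfy `evalue <= evalue_max`; transmembrane and
#' low-complexity features bypass the filter (their sources do not report
#' comparable E-values).
#'
#' @param hits tibble of feature hits.
#' @param config a [domains_config()].
#' @return filtered tibble.
#' @export
filter_hits <- function(hits, config = domains_config()) {
  if (nrow(hits) == 0L) return(hits)
  dplyr::filter(hits, .data$kind != "domain" |
                  (!is.na(.data$evalue) & .data$evalue <= config$evalue_max))
}

#' Resolve overlapping hits into a domain architecture
#'
#' Greedy selection by descending bit score (ties: smaller E-value, then
#' smaller start): a hit is accepted iff its overlap with every already
#' accepted domain hit is at most `overlap_fraction_max` of the shorter of
#' the pair. Non-domain features (TM, low-complexity) are always kept and do
#' not block domains. The result is sorted by start (ties by end).
#'
#' @param hits filtered hits for one protein.
#' @param config a [domains_config()].
#' @return tibble: the ordered, non-overlapping architecture.
#' @export
resolve_overlaps <- function(hits, config = domains_config()) {
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein_id)) > 1L) {
    stop("resolve_overlaps expects hits for a single protein", call. = FALSE)
  }
  dom <- dplyr::filter(hits, .data$kind == "domain")
  other <- dplyr::filter(hits, .data$kind != "domain")
  if (nrow(dom) > 0L) {
    ord <- order(-dom$bit_score, dom$evalue, dom$start)
    dom <- dom[ord, ]
    keep <- logical(nrow(dom))
    for (i in seq_len(nrow(dom))) {
      ok <- TRUE
      for (j in which(keep)) {
        ov <- min(dom$end[i], dom$end[j]) - max(dom$start[i], dom$start[j]) + 1L
        shorter <- min(dom$end[i] - dom$start[i], dom$end[j] - dom$start[j]) + 1L
        if (ov > config$overlap_fraction_max * shorter) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    dom <- dom[keep, ]
  }
  out <- dplyr::bind_rows(dom, other)
  out[order(out$start, out$end), ]
}

#' Build domain architectures for many proteins
#'
#' Applies [filter_hits()] then [resolve_overlaps()] per protein.
#'
#' @param hits tibble of feature hits for any number of proteins.
#' @param config a [domains_config()].
#' @return tibble of resolved hits for all proteins.
#' @export
build_architectures <- function(hits, config = domains_config()) {
  if (nrow(hits) == 0L) return(hits)
  filter_hits(hits, config) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(~ resolve_overlaps(.x |>
      dplyr::mutate(protein_id = .y$protein_id), config) |>
      dplyr::select(-"protein_id")) |>
    dplyr::ungroup()
}

#' The domain-accession set encoded by a gene's protein
#'
#' Collapses an architecture to the set (not multiset) of domain accessions;
#' transmembrane and low-complexity features are excluded. A protein without
#' an architecture yields the empty set.
#'
#' @param protein_id protein identifier (scalar).
#' @param architectures tibble of resolved hits (any number of proteins).
#' @return character vector (sorted, unique domain accessions).
#' @export
gene_domain_set <- function(protein_id, architectures) {
  if (is.na(protein_id) || nrow(architectures) == 0L) return(character())
  rows <- architectures$protein_id == protein_id &
    architectures$kind == "domain"
  sort(unique(architectures$accession[rows]))
}
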