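#' Reorder alignment rows to the tree's leaf order
#'
#' Rows are permuted to the tree's depth-first leaf order (children visited
#' in stored order) so that phylogenetically related sequences sit next to
#' each other in the MSA. Leaf names are matched to record ids through
#' [parse_leaf_id()]; the match must be a bijection.
#'
#' @param alignment tibble of sequence records (aligned or not).
#' @param tree an `ape::phylo` tree.
#' @return the alignment tibble with rows permuted; attribute `leaf_name`
#'   holds the matching leaf for each row.
#' @export
sort_alignment_by_tree <- function(alignment, tree) {
  leaves <- order_leaves(tree)
  leaf_ids <- parse_leaf_id(leaves)
  missing_rec <- setdiff(leaf_ids, alignment$id)
  missing_leaf <- setdiff(alignment$id, leaf_ids)
  if (length(missing_rec) || length(missing_leaf)) {
    stop("tree/alignment mismatch",
         if (length(missing_rec))
           paste0("; leaves without record: ",
                  paste(sQuote(missing_rec), collapse = ", ")),
         if (length(missing_leaf))
           paste0("; records without leaf: ",
                  paste(sQuote(missing_leaf), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(leaf_ids)) {
    stop("leaf ids are not unique after parsing", call. = FALSE)
  }
  out <- alignment[match(leaf_ids, alignment$id), ]
  attr(out, "leaf_name") <- leaves
  out
}

#' Enumerate tree leaves and alignment rows
#'
#' Prefixes leaf `i` of the displayed order and MSA row `i` with the same
#' index `"i. "`, so positions in the picture and in the alignment can be
#' cross-referenced. Requires an alignment already sorted by
#' [sort_alignment_by_tree()]; re-enumeration is refused.
#'
#' @param tree an `ape::phylo` tree.
#' @param alignment sorted alignment tibble.
#' @return list with `tree` and `alignment`, both relabeled.
#' @export
enumerate_leaves <- function(tree, alignment) {
  leaves <- order_leaves(tree)
  expected <- attr(alignment, "leaf_name")
  if (is.null(expected) || !identical(expected, leaves)) {
    stop("alignment must be sorted by the tree before enumeration",
         call. = FALSE)
  }
  if (any(grepl("^[0-9]+\\. ", c(leaves, alignment$id)))) {
    stop("already enumerated", call. = FALSE)
  }
  idx <- seq_along(leaves)
  new_names <- paste0(idx, ". ", leaves)
  tree$tip.label[match(leaves, tree$tip.label)] <- new_names
  alignment$id <- paste0(idx, ". ", alignment$id)
  attr(alignment, "leaf_name") <- new_names
  list(tree = tree, alignment = alignment)
}
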