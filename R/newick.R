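#' Parse a Newick tree
#'
#' Wraps [ape::read.tree()] with the validation this package relies on:
#' exactly one statement, unique leaf names, child order as written, internal
#' node labels kept as support values.
#'
#' @param text Newick text (single statement ending in `;`) or a file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  txt <- paste(as_text_lines(text), collapse = "")
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("empty Newick input", call. = FALSE)
  if (!endsWith(txt, ";")) {
    stop("Newick parse error: missing terminating ';' (offset ",
         nchar(txt), ")", call. = FALSE)
  }
  depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                    (strsplit(txt, "")[[1]] == ")"))
  if (utils::tail(depth, 1) != 0L || any(depth < 0L)) {
    off <- which(depth < 0L)
    off <- if (length(off)) off[1] else nchar(txt)
    stop("Newick parse error: unbalanced parentheses (offset ", off, ")",
         call. = FALSE)
  }
  if (grepl("^[^();,]+;$", txt)) {
    # single-leaf statement like "A;" — valid Newick that ape cannot hold
    lab <- sub(";$", "", txt)
    len <- NA_real_
    if (grepl(":", lab, fixed = TRUE)) {
      len <- as.numeric(sub("^.*:", "", lab))
      lab <- sub(":.*$", "", lab)
    }
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           tip.label = lab, Nnode = 1L),
                      class = "phylo", order = "cladewise")
    if (!is.na(len)) tree$edge.length <- len
    return(tree)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    stop("Newick parse error in ", sQuote(substr(txt, 1, 40)), call. = FALSE)
  }
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single Newick statement, got ", length(tree),
         call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf name", if (length(dup) > 1L) "s" else "", ": ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  tree
}

#' Serialize a tree to Newick text
#'
#' Deterministic writer: child order is preserved, branch lengths are printed
#' with a fixed number of significant decimal digits, internal node labels
#' (support values) are emitted when present.
#'
#' @param tree an `ape::phylo` tree.
#' @param precision digits after the decimal point for branch lengths
#'   (default 6).
#' @param path optional output file.
#' @return Newick string ending in `;`.
#' @export
write_newick <- function(tree, precision = 6L, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  node_lab <- tree$node.label
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # keep child order as stored (edge matrix row order within each parent)
  fmt_len <- function(x) {
    s <- formatC(round(x, precision), format = "f", digits = precision)
    s <- sub("0+$", "", s)
    sub("\\.$", "", s)
  }
  edge_suffix <- function(edge_row) {
    if (has_len && edge_row > 0L) paste0(":", fmt_len(tree$edge.length[edge_row]))
    else ""
  }
  recurse <- function(node, edge_row) {
    if (node <= ntip) {
      return(paste0(tree$tip.label[node], edge_suffix(edge_row)))
    }
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, function(e)
      recurse(tree$edge[e, 2], e), character(1)), collapse = ",")
    lab <- if (!is.null(node_lab)) {
      l <- node_lab[node - ntip]
      if (is.na(l) || !nzchar(l)) "" else l
    } else ""
    paste0("(", inner, ")", lab, edge_suffix(edge_row))
  }
  out <- if (ntip == 1L) {
    paste0(tree$tip.label[1],
           if (has_len) paste0(":", fmt_len(tree$edge.length[1])) else "",
           ";")
  } else {
    paste0(recurse(ntip + 1L, 0L), ";")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
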