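#' Leaf display order of a tree
#'
#' Depth-first traversal with children in stored order; with
#' `ladderize = TRUE` children are first sorted by subtree leaf count
#' (ascending, ties by the lexicographically smallest leaf name in the
#' subtree), giving the tidy staircase layout.
#'
#' @param tree an `ape::phylo` tree.
#' @param ladderize sort children by subtree size before traversal.
#' @return character vector of leaf names, top to bottom.
#' @export
order_leaves <- function(tree, ladderize = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  recurse <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    sub <- lapply(kids, recurse)
    if (ladderize) {
      ord <- order(lengths(sub),
                   vapply(sub, function(s) sort(s)[1], character(1)))
      sub <- sub[ord]
    }
    unlist(sub)
  }
  recurse(ntip + 1L)
}

# fixed 20-color qualitative palette; cycles with a hatch flag afterwards
TRACK_PALETTE <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
  "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
  "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
  "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5"
)
NEUTRAL_COLOR <- "#d9d9d9"   # reserved for domain-less genes

#' Assign display colors to clusters and operons
#'
#' Ids are ranked by first occurrence scanning leaves top-to-bottom and each
#' leaf's genes left-to-right, then mapped onto a fixed 20-color cyclic
#' palette in that order. After palette exhaustion colors repeat with a
#' `hatch` flag so co-colored ids remain distinguishable. Domain-less genes
#' use a reserved neutral color. Fully deterministic.
#'
#' @param result a `neighborhoods_result`.
#' @param leaf_order leaf names top to bottom (default: the result's tree
#'   order).
#' @return list with tibbles `clusters` (`cluster_id`, `color`, `hatch`) and
#'   `operons` (`operon_id`, `color`, `hatch`), plus `neutral`.
#' @export
assign_colors <- function(result, leaf_order = order_leaves(result$tree)) {
  nb <- result$neighborhoods
  nb <- nb[order(match(nb$leaf_name, leaf_order), nb$offset), ]
  ann <- dplyr::left_join(
    nb[, c("gene_id", "leaf_name", "offset")],
    dplyr::select(result$genes, "gene_id", "cluster_id", "operon_id"),
    by = "gene_id")
  palette_for <- function(ids) {
    ids <- ids[!is.na(ids)]
    first <- unique(ids)
    rank <- seq_along(first)
    tibble::tibble(
      id = first,
      color = TRACK_PALETTE[(rank - 1L) %% length(TRACK_PALETTE) + 1L],
      hatch = rank > length(TRACK_PALETTE)
    )
  }
  cl <- palette_for(ann$cluster_id)
  op <- palette_for(ann$operon_id)
  names(cl)[1] <- "cluster_id"
  names(op)[1] <- "operon_id"
  list(clusters = cl, operons = op, neutral = NEUTRAL_COLOR)
}

#' Assemble the render model for a pipeline result
#'
#' Combines the tree with one per-leaf track: architecture glyph rows
#' (protein ruler plus feature boxes) for a `domains_result`, gene-arrow
#' rows (fill = cluster color, border = operon color, thick border = query)
#' for a `neighborhoods_result`. Leaves without data get an explicit empty
#' track and a warning entry in the model metadata.
#'
#' @param result a `domains_result` or `neighborhoods_result`.
#' @param ladderize ladderize the leaf order (default `FALSE`).
#' @param scale pixels per residue (domains) or per kb (neighborhoods).
#' @return a `render_model` list.
#' @export
assemble_render_model <- function(result, ladderize = FALSE, scale = NULL) {
  UseMethod("assemble_render_model")
}

#' @export
assemble_render_model.domains_result <- function(result, ladderize = FALSE,
                                                 scale = NULL) {
  if (is.null(scale)) scale <- 1.0       # px per residue
  leaves <- order_leaves(result$tree, ladderize)
  ids <- parse_leaf_id(sub("^[0-9]+\\. ", "", leaves))
  warn <- character(0)
  tracks <- purrr::map2(leaves, ids, function(leaf, pid) {
    arch <- result$architectures[result$architectures$protein_id == pid, ]
    len <- nchar(gsub("-", "", result$alignment$residues[
      match(pid, sub("^[0-9]+\\. ", "", result$alignment$id))], fixed = TRUE))
    if (nrow(arch) == 0L) warn <<- c(warn, leaf)
    list(leaf = leaf, protein_id = pid, protein_length = len,
         features = arch)
  })
  structure(list(tree = result$tree, leaf_order = leaves, tracks = tracks,
                 palette = NULL, scale = scale, kind = "domains",
                 warnings = if (length(warn))
                   paste0("no features for leaf ", sQuote(warn))
                 else character(0)),
            class = "render_model")
}

#' @export
assemble_render_model.neighborhoods_result <- function(result,
                                                       ladderize = FALSE,
                                                       scale = NULL) {
  if (is.null(scale)) scale <- 20.0      # px per kb
  leaves <- order_leaves(result$tree, ladderize)
  palette <- assign_colors(result, leaves)
  warn <- character(0)
  genes_ann <- dplyr::select(result$genes, "gene_id", "cluster_id",
                             "operon_id", "domain_accessions")
  tracks <- purrr::map(leaves, function(leaf) {
    nb <- result$neighborhoods[result$neighborhoods$leaf_name == leaf, ]
    nb <- dplyr::left_join(nb, genes_ann, by = "gene_id")
    if (nrow(nb) == 0L) warn <<- c(warn, leaf)
    list(leaf = leaf, genes = nb)
  })
  structure(list(tree = result$tree, leaf_order = leaves, tracks = tracks,
                 palette = palette, scale = scale, kind = "neighborhoods",
                 warnings = if (length(warn))
                   paste0("no neighborhood for leaf ", sQuote(warn))
                 else character(0)),
            class = "render_model")
}

#' Render a model to SVG text
#'
#' Deterministic, standalone SVG: one `<g>` per leaf row with a stable `id`
#' attribute; every feature box / gene arrow carries a `<title>` element with
#' accession, name and coordinates (the static analogue of an interactive
#' tooltip). Byte-identical across runs on identical input.
#'
#' @param model a `render_model` from [assemble_render_model()].
#' @param path optional output file.
#' @return SVG text (single string).
#' @export
render_svg <- function(model, path = NULL) {
  stopifnot(inherits(model, "render_model"))
  row_h <- 28; pad <- 10; label_w <- 180; tree_w <- 120
  n <- length(model$leaf_order)
  rows <- character(0)
  max_track_px <- 0
  for (i in seq_len(n)) {
    tr <- model$tracks[[i]]
    y <- pad + (i - 1) * row_h
    body <- if (model$kind == "domains") {
      svg_architecture_row(tr, model$scale, row_h)
    } else {
      svg_neighborhood_row(tr, model$palette, model$scale, row_h)
    }
    max_track_px <- max(max_track_px, body$width)
    rows <- c(rows, sprintf(
      '<g id="leaf-%d" transform="translate(%g,%g)"><text x="0" y="%g" font-size="11" font-family="monospace">%s</text><g transform="translate(%g,0)">%s</g></g>',
      i, tree_w + pad, y, row_h / 2 + 4, xml_escape(tr$leaf %||% model$leaf_order[i]),
      label_w, body$svg))
  }
  width <- tree_w + pad * 3 + label_w + max_track_px
  height <- pad * 2 + n * row_h
  tree_svg <- svg_tree(model$tree, model$leaf_order, tree_w, row_h, pad)
  out <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
            width, height, width, height),
    tree_svg, paste(rows, collapse = ""), "</svg>")
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

svg_architecture_row <- function(track, scale, row_h) {
  len <- track$protein_length
  if (is.na(len) || length(len) == 0L) len <- 0
  ruler <- sprintf('<line x1="0" y1="%g" x2="%g" y2="%g" stroke="#555" stroke-width="1"/>',
                   row_h / 2, len * scale, row_h / 2)
  feats <- track$features
  boxes <- character(0)
  if (!is.null(feats) && nrow(feats) > 0L) {
    fill <- ifelse(feats$kind == "domain",
                   TRACK_PALETTE[(match(feats$accession,
                                        unique(feats$accession)) - 1L) %%
                                   length(TRACK_PALETTE) + 1L],
                   ifelse(feats$kind == "transmembrane", "#444444",
                          "#bbbbbb"))
    boxes <- sprintf(
      '<rect x="%g" y="%g" width="%g" height="%g" fill="%s" stroke="#222" stroke-width="0.5"><title>%s</title></rect>',
      (feats$start - 1) * scale, row_h * 0.2,
      (feats$end - feats$start + 1) * scale, row_h * 0.6, fill,
      xml_escape(sprintf("%s %s [%d-%d]", feats$accession, feats$name,
                         feats$start, feats$end)))
  }
  list(svg = paste0(ruler, paste(boxes, collapse = "")),
       width = len * scale)
}

svg_neighborhood_row <- function(track, palette, scale, row_h) {
  g <- track$genes
  if (is.null(g) || nrow(g) == 0L) return(list(svg = "", width = 0))
  px_per_bp <- scale / 1000
  origin <- min(g$start)
  x0 <- (g$start - origin) * px_per_bp
  x1 <- (g$end - origin) * px_per_bp
  fill <- palette$clusters$color[match(g$cluster_id,
                                       palette$clusters$cluster_id)]
  fill[is.na(fill)] <- palette$neutral
  border <- palette$operons$color[match(g$operon_id,
                                        palette$operons$operon_id)]
  border[is.na(border)] <- "#333333"
  bw <- ifelse(g$is_query, 3, 1)
  y0 <- row_h * 0.15; y1 <- row_h * 0.85; ym <- row_h * 0.5
  head <- pmin(6, (x1 - x0) * 0.4)
  pts <- ifelse(
    g$strand == "+",
    sprintf("%g,%g %g,%g %g,%g %g,%g %g,%g",
            x0, y0, x1 - head, y0, x1, ym, x1 - head, y1, x0, y1),
    sprintf("%g,%g %g,%g %g,%g %g,%g %g,%g",
            x1, y0, x0 + head, y0, x0, ym, x0 + head, y1, x1, y1))
  title <- xml_escape(sprintf(
    "%s | %s | %d-%d (%s) | domains: %s | cluster: %s | operon: %s",
    g$gene_id, ifelse(is.na(g$product), "", g$product),
    g$start + 1L, g$end, g$strand,
    vapply(g$domain_accessions,
           function(d) if (length(d)) paste(d, collapse = ",") else "-",
           character(1)),
    ifelse(is.na(g$cluster_id), "-", as.character(g$cluster_id)),
    ifelse(is.na(g$operon_id), "-", as.character(g$operon_id))))
  polys <- sprintf(
    '<polygon points="%s" fill="%s" stroke="%s" stroke-width="%g"><title>%s</title></polygon>',
    pts, fill, border, bw, title)
  list(svg = paste(polys, collapse = ""), width = max(x1))
}

# simple rectangular cladogram in the left margin
svg_tree <- function(tree, leaf_order, tree_w, row_h, pad) {
  ntip <- length(tree$tip.label)
  y_leaf <- stats::setNames(pad + (seq_along(leaf_order) - 0.5) * row_h,
                            leaf_order)
  if (ntip == 1L) {
    return(sprintf('<g id="tree"><line x1="0" y1="%g" x2="%g" y2="%g" stroke="#000"/></g>',
                   y_leaf[1], tree_w, y_leaf[1]))
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  depth <- function(node) {
    if (node <= ntip) return(0L)
    1L + max(vapply(children[[as.character(node)]], depth, integer(1)))
  }
  total_depth <- depth(ntip + 1L)
  xs <- tree_w * (1 - (0:total_depth) / max(1L, total_depth))
  segs <- character(0)
  recurse <- function(node, d) {
    if (node <= ntip) {
      y <- y_leaf[[tree$tip.label[node]]]
      segs <<- c(segs, sprintf(
        '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#000" stroke-width="1"/>',
        xs[d + 1L], y, tree_w, y))
      return(y)
    }
    kids <- children[[as.character(node)]]
    ys <- vapply(kids, recurse, numeric(1), d = d + 1L)
    y <- mean(range(ys))
    segs <<- c(segs, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#000" stroke-width="1"/>',
      xs[d + 1L], min(ys), xs[d + 1L], max(ys)))
    segs <<- c(segs, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="#000" stroke-width="1"/>',
      xs[d + 2L], y, xs[d + 1L], y))
    y
  }
  recurse(ntip + 1L, 0L)
  paste0('<g id="tree">', paste(segs, collapse = ""), "</g>")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
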