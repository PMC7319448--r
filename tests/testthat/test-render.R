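test_that("leaf order follows depth-first traversal; ladderize sorts kids", {
  t <- read_newick("((A,B),C);")
  expect_equal(order_leaves(t), c("A", "B", "C"))
  expect_equal(order_leaves(t, ladderize = TRUE), c("C", "A", "B"))
  expect_equal(order_leaves(read_newick("A;")), "A")
})

fxr <- synth_genome(fixture_spec(seed = 77))
qpid <- fxr$annotation$genes$protein_id[
  match(fxr$truth$queries, fxr$annotation$genes$gene_id)]
resn <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                   fxr$annotation, hits = fxr$hits,
                                   sequences = fxr$proteins)

test_that("colors are assigned by first occurrence, deterministically", {
  pal <- assign_colors(resn)
  ranks <- seq_len(nrow(pal$clusters))
  expect_equal(pal$clusters$color,
               phylotracks:::TRACK_PALETTE[(ranks - 1) %% 20 + 1])
  expect_identical(assign_colors(resn), pal)
  expect_false(any(duplicated(pal$clusters$color[!pal$clusters$hatch])))
  expect_false(phylotracks:::NEUTRAL_COLOR %in% pal$clusters$color)
})

test_that("palette cycles with a hatch flag after 20 ids", {
  fake <- resn
  nb <- fake$neighborhoods[rep(1, 25), ]
  nb$gene_id <- sprintf("fk%02d", 1:25)
  nb$offset <- 1:25
  fake$neighborhoods <- nb
  fake$genes <- tibble::tibble(gene_id = nb$gene_id, cluster_id = 1:25,
                               operon_id = NA_integer_)
  pal <- assign_colors(fake)
  expect_equal(pal$clusters$color[21], pal$clusters$color[1])
  expect_true(pal$clusters$hatch[21])
  expect_false(pal$clusters$hatch[1])
})

test_that("color ranks are stable when new leaves append at the bottom", {
  pal_full <- assign_colors(resn)
  lo <- order_leaves(resn$tree)
  # restrict to the first three leaves: shared ids keep their rank prefix
  res3 <- resn
  res3$neighborhoods <- resn$neighborhoods[
    resn$neighborhoods$leaf_name %in% lo[1:3], ]
  pal3 <- assign_colors(res3, lo[1:3])
  shared <- intersect(pal3$clusters$cluster_id, pal_full$clusters$cluster_id)
  expect_equal(
    pal3$clusters$color[match(shared, pal3$clusters$cluster_id)],
    pal_full$clusters$color[match(shared, pal_full$clusters$cluster_id)])
})

test_that("the neighborhoods SVG is valid XML with one group per leaf", {
  m <- assemble_render_model(resn)
  svg <- render_svg(m)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  rows <- xml2::xml_find_all(doc, "//d1:g[starts-with(@id, 'leaf-')]", ns)
  expect_equal(length(rows), length(order_leaves(resn$tree)))
  polys <- xml2::xml_find_all(doc, "//d1:polygon", ns)
  expect_equal(length(polys), nrow(resn$neighborhoods))
  titles <- xml2::xml_find_all(doc, "//d1:title", ns)
  expect_equal(length(titles), length(polys))
  # query genes get the thick border
  widths <- as.numeric(xml2::xml_attr(polys, "stroke-width"))
  expect_equal(sum(widths == 3), sum(resn$neighborhoods$is_query))
  expect_identical(render_svg(m), svg)   # byte-identical
})

test_that("arrow orientation matches the strand of each gene", {
  m <- assemble_render_model(resn)
  svg <- render_svg(m)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  polys <- xml2::xml_find_all(doc, "//d1:polygon", ns)
  # polygons appear leaf-by-leaf in neighborhood order
  ordered <- resn$neighborhoods[
    order(match(resn$neighborhoods$leaf_name, m$leaf_order),
          resn$neighborhoods$offset), ]
  pts <- xml2::xml_attr(polys, "points")
  tip_right <- vapply(strsplit(pts, " "), function(p) {
    xs <- as.numeric(sub(",.*", "", p))
    which.max(xs) == 3  # arrow apex is the third vertex
  }, logical(1))
  expect_equal(tip_right, ordered$strand == "+")
})

test_that("the domains SVG draws a ruler row per leaf with feature boxes", {
  resd <- run_domains_pipeline(fxr$proteins[1:5, ], hits = fxr$hits)
  m <- assemble_render_model(resd)
  svg <- render_svg(m)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(
    doc, "//d1:g[starts-with(@id, 'leaf-')]", ns)), 5L)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:rect", ns)),
               nrow(resd$architectures))
  expect_identical(render_svg(m), svg)
})

test_that("an empty model still renders minimal valid SVG", {
  t1 <- read_newick("A;")
  res <- list(tree = t1,
              architectures = phylotracks:::empty_hits(),
              alignment = tibble::tibble(id = "A", description = "",
                                         residues = "MKTLV"),
              metadata = list())
  class(res) <- "domains_result"
  m <- assemble_render_model(res)
  expect_match(m$warnings, "'A'")
  svg <- render_svg(m)
  expect_no_error(xml2::read_xml(svg))
})
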