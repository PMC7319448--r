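fxn <- synth_genome(fixture_spec(seed = 57))
qpid <- fxn$annotation$genes$protein_id[
  match(fxn$truth$queries, fxn$annotation$genes$gene_id)]

test_that("id-list input builds a tree and one neighborhood per query", {
  res <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                    fxn$annotation, hits = fxn$hits,
                                    sequences = fxn$proteins)
  expect_s3_class(res, "neighborhoods_result")
  expect_equal(length(res$tree$tip.label), length(qpid))
  expect_equal(res$metadata$tree_source, "built_from_id_list")
  expect_equal(length(unique(res$neighborhoods$query_gene_id)),
               length(qpid))
  # every neighborhood contains its query once and respects the window
  for (q in unique(res$neighborhoods$query_gene_id)) {
    nb <- res$neighborhoods[res$neighborhoods$query_gene_id == q, ]
    expect_equal(sum(nb$is_query), 1L)
    expect_lte(nrow(nb), 2 * res$metadata$parameters$window + 1)
    expect_equal(length(unique(nb$replicon_id)), 1L)
  }
})

test_that("newick input is used verbatim with no tree building", {
  nwk <- sprintf("(%s:1,(%s:1,(%s:1,%s:1):1):1);",
                 qpid[1], qpid[2], qpid[3], qpid[4])
  res <- run_neighborhoods_pipeline(nwk, fxn$annotation, hits = fxn$hits)
  expect_equal(res$metadata$tree_source, "user")
  expect_equal(write_newick(res$tree), write_newick(read_newick(nwk)))
})

test_that("missing query genes are reported by id", {
  expect_error(
    run_neighborhoods_pipeline("(WP_999999999.1:1,WP_888888888.1:1);",
                               fxn$annotation),
    "WP_999999999.1")
})

test_that("cluster membership is stable across runs and input order", {
  a <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                  fxn$annotation, hits = fxn$hits,
                                  sequences = fxn$proteins)
  b <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                  fxn$annotation, hits = fxn$hits,
                                  sequences = fxn$proteins)
  expect_identical(a$clusters, b$clusters)
  expect_identical(export_json(a), export_json(b))
  # membership (not ids) is invariant under permuted query order
  perm <- run_neighborhoods_pipeline(paste(rev(qpid), collapse = "\n"),
                                     fxn$annotation, hits = fxn$hits,
                                     sequences = fxn$proteins)
  part <- function(r) {
    cl <- r$clusters[!is.na(r$clusters$cluster_id), ]
    unname(sort(vapply(split(cl$gene_id, cl$cluster_id),
                       function(g) paste(sort(g), collapse = ","),
                       character(1))))
  }
  expect_equal(part(perm), part(a))
})

test_that("operons inside neighborhoods match direct detection", {
  res <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                    fxn$annotation, hits = fxn$hits,
                                    sequences = fxn$proteins)
  full <- dplyr::bind_rows(lapply(split(fxn$annotation$genes,
                                        fxn$annotation$genes$replicon_id),
                                  detect_operons))
  in_scope <- res$genes$gene_id
  full_pairs <- character(0)
  for (key in unique(paste(full$replicon_id, full$operon_id))) {
    m <- full$gene_id[paste(full$replicon_id, full$operon_id) == key]
    full_pairs <- c(full_pairs, paste(m[-length(m)], m[-1], sep = ">"))
  }
  got_pairs <- character(0)
  for (oid in unique(res$operons$operon_id)) {
    m <- res$operons$gene_id[res$operons$operon_id == oid]
    got_pairs <- c(got_pairs, paste(m[-length(m)], m[-1], sep = ">"))
  }
  # pipeline operon links are exactly the genome-wide links whose two
  # genes both fall inside the neighborhood scope
  both_in <- vapply(strsplit(full_pairs, ">", fixed = TRUE),
                    function(p) all(p %in% in_scope), logical(1))
  expect_setequal(got_pairs, full_pairs[both_in])
})

test_that("domain-less genes render neutral and never cluster", {
  res <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                    fxn$annotation, hits = fxn$hits,
                                    sequences = fxn$proteins)
  empty <- lengths(res$genes$domain_accessions) == 0
  expect_true(all(is.na(res$genes$cluster_id[empty])))
  expect_true(all(!is.na(res$genes$cluster_id[!empty])))
})
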