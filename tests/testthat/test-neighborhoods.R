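linear_ann <- function(n = 9L, gap = 300L, len = 600L, strand = "+",
                       circular = FALSE) {
  starts <- seq(0L, by = len + gap, length.out = n)
  genome_annotation(
    tibble::tibble(gene_id = sprintf("g%d", 1:n),
                   locus_tag = NA_character_,
                   protein_id = sprintf("P%d", 1:n),
                   replicon_id = "chr", start = starts,
                   end = starts + len,
                   strand = rep_len(strand, n), product = NA_character_),
    tibble::tibble(replicon_id = "chr",
                   length = max(starts) + len + 1000L,
                   circular = circular))
}

test_that("window takes up to `window` genes each side of the query", {
  nb <- extract_neighborhood(linear_ann(), "g5", window = 3)
  expect_equal(nb$gene_id, sprintf("g%d", 2:8))
  expect_false(attr(nb, "truncated_left"))
  expect_false(attr(nb, "truncated_right"))
  expect_equal(nb$gene_id[nb$is_query], "g5")
  expect_lte(nrow(nb), 2 * 3 + 1)
})

test_that("windows truncate at linear replicon ends and flag it", {
  nb <- extract_neighborhood(linear_ann(), "g2", window = 3)
  expect_equal(nb$gene_id, sprintf("g%d", 1:5))
  expect_true(attr(nb, "truncated_left"))
  expect_false(attr(nb, "truncated_right"))
})

test_that("circular replicons wrap the window across the origin", {
  nb <- extract_neighborhood(linear_ann(n = 6L, circular = TRUE), "g1",
                             window = 2)
  expect_equal(nb$gene_id, c("g5", "g6", "g1", "g2", "g3"))
  expect_true(attr(nb, "wrapped"))
  expect_false(attr(nb, "truncated_left"))
})

test_that("unknown and ambiguous query ids are rejected", {
  expect_error(extract_neighborhood(linear_ann(), "nope", 2), "unknown")
  ann <- linear_ann()
  ann$genes$locus_tag[2] <- "g7"   # collides with gene_id g7
  expect_error(extract_neighborhood(ann, "g7", 2), "ambiguous")
})

test_that("domain-set compatibility counts the symmetric difference", {
  expect_true(compatible(c("X", "Y"), c("X", "Y"), 0))
  expect_false(compatible(c("X", "Y"), c("X", "Y", "Z"), 0))
  expect_true(compatible(c("X", "Y"), c("X", "Y", "Z"), 1))
  expect_false(compatible(character(0), character(0), 5))
})

mk_arch <- function(sets) {
  purrr::imap_dfr(sets, function(accs, pid) {
    if (length(accs) == 0) return(phylotracks:::empty_hits())
    tibble::tibble(protein_id = pid, kind = "domain", source = "pfam",
                   accession = accs, name = accs,
                   start = seq(1, by = 100, length.out = length(accs)),
                   end = seq(50, by = 100, length.out = length(accs)),
                   bit_score = 100, evalue = 1e-30)
  })
}

gene_tbl <- function(pids) {
  tibble::tibble(gene_id = paste0("g_", pids), protein_id = pids)
}

test_that("k = 0 groups identical non-empty sets; empty sets stay out", {
  arch <- mk_arch(list(P1 = c("X", "Y"), P2 = c("X", "Y"), P3 = "W",
                       P4 = character(0)))
  cl <- cluster_genes(gene_tbl(c("P1", "P2", "P3", "P4")), arch, k = 0)
  expect_equal(cl$cluster_id, c(1L, 1L, 2L, NA))
})

test_that("k = 1 chains via single linkage across the compatibility graph", {
  arch <- mk_arch(list(P1 = "X", P2 = c("X", "Y"), P3 = c("X", "Y", "Z")))
  cl <- cluster_genes(gene_tbl(c("P1", "P2", "P3")), arch, k = 1)
  expect_equal(cl$cluster_id, c(1L, 1L, 1L))
  cl0 <- cluster_genes(gene_tbl(c("P1", "P2", "P3")), arch, k = 0)
  expect_equal(cl0$cluster_id, 1:3)
})

test_that("k = 0 clustering equals hash-grouping by frozen domain set", {
  withr::with_seed(99, {
    pool <- c("PF1", "PF2", "PF3", "PF4", "PF5")
    sets <- replicate(20, sort(sample(pool, sample(0:3, 1))),
                      simplify = FALSE)
    names(sets) <- sprintf("P%02d", 1:20)
    arch <- mk_arch(sets)
    cl <- cluster_genes(gene_tbl(names(sets)), arch, k = 0)
    keys <- vapply(sets, paste, character(1), collapse = "|")
    oracle <- ifelse(keys == "", NA_character_, keys)
    split_mine <- split(cl$gene_id[!is.na(cl$cluster_id)],
                        cl$cluster_id[!is.na(cl$cluster_id)])
    split_oracle <- split(paste0("g_", names(sets))[!is.na(oracle)],
                          oracle[!is.na(oracle)])
    expect_setequal(
      unname(vapply(split_mine, function(g) paste(sort(g), collapse = ","),
                    character(1))),
      unname(vapply(split_oracle, function(g) paste(sort(g), collapse = ","),
                    character(1))))
    expect_true(all(is.na(cl$cluster_id[keys == ""])))
  })
})

test_that("partition at k+1 coarsens the partition at k", {
  for (s in 1:10) {
    fx <- synth_genome(fixture_spec(seed = 400 + s))
    arch <- build_architectures(fx$hits)
    for (k in 0:2) {
      a <- cluster_genes(fx$annotation$genes, arch, k)
      b <- cluster_genes(fx$annotation$genes, arch, k + 1)
      for (cid in unique(stats::na.omit(a$cluster_id))) {
        members <- a$gene_id[!is.na(a$cluster_id) & a$cluster_id == cid]
        super <- b$cluster_id[match(members, b$gene_id)]
        expect_equal(length(unique(super)), 1L)
      }
    }
  }
})

op_ann <- function(gaps, strands) {
  n <- length(gaps) + 1L
  len <- 500L
  starts <- integer(n); starts[1] <- 0L
  for (i in seq_along(gaps)) starts[i + 1] <- starts[i] + len + gaps[i]
  genome_annotation(
    tibble::tibble(gene_id = sprintf("g%d", 1:n), locus_tag = NA_character_,
                   protein_id = sprintf("P%d", 1:n), replicon_id = "chr",
                   start = starts, end = starts + len,
                   strand = rep_len(strands, n), product = NA_character_),
    tibble::tibble(replicon_id = "chr", length = max(starts) + len + 100L,
                   circular = FALSE))$genes
}

test_that("operons are maximal runs under the gap threshold", {
  ops <- detect_operons(op_ann(c(50L, 300L, 100L), "+"))
  expect_equal(unname(split(ops$gene_id, ops$operon_id)),
               list(c("g1", "g2"), c("g3", "g4")))
})

test_that("strand changes break operons when required", {
  g <- op_ann(c(50L, 100L), c("+", "-", "+"))
  expect_equal(nrow(detect_operons(g)), 0L)
  relaxed <- detect_operons(g, neighborhoods_config(require_same_strand =
                                                      FALSE))
  expect_equal(sort(unique(relaxed$gene_id)), c("g1", "g2", "g3"))
})

test_that("the gap threshold is inclusive and overlaps always link", {
  exactly200 <- detect_operons(op_ann(200L, "+"))
  expect_equal(nrow(exactly200), 2L)
  over <- detect_operons(op_ann(201L, "+"))
  expect_equal(nrow(over), 0L)
  overlap <- detect_operons(op_ann(-30L, "+"))
  expect_equal(nrow(overlap), 2L)
})

test_that("unsorted input is rejected; operons need two genes", {
  g <- op_ann(c(50L, 50L), "+")
  expect_error(detect_operons(g[c(2, 1, 3), ]), "sorted")
  expect_equal(nrow(detect_operons(g[1, ])), 0L)
})

test_that("linked-pair set is monotone in the gap threshold", {
  withr::with_seed(7, {
    gaps <- as.integer(sample(0:600, 15))
    g <- op_ann(gaps, "+")
    linked_at <- function(t) {
      ops <- detect_operons(g, neighborhoods_config(operon_gap_max = t))
      pairs <- character(0)
      for (oid in unique(ops$operon_id)) {
        m <- ops$gene_id[ops$operon_id == oid]
        pairs <- c(pairs, paste(m[-length(m)], m[-1], sep = "-"))
      }
      pairs
    }
    for (t in c(0L, 100L, 200L, 400L)) {
      expect_true(all(linked_at(t) %in% linked_at(t + 100L)))
    }
  })
})
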