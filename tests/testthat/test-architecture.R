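mk_hit <- function(protein_id = "P", kind = "domain", accession = "X",
                   start = 1L, end = 100L, bit_score = 50, evalue = 1e-10) {
  tibble::tibble(protein_id = protein_id, kind = kind, source = "pfam",
                 accession = accession, name = accession,
                 start = as.integer(start), end = as.integer(end),
                 bit_score = bit_score, evalue = evalue)
}

test_that("E-value filter keeps domains below threshold, TM always passes", {
  h <- dplyr::bind_rows(mk_hit(evalue = 1e-20),
                        mk_hit(accession = "Y", evalue = 0.1))
  kept <- filter_hits(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$accession, "X")
  expect_equal(nrow(filter_hits(h[0, ])), 0L)
  tm <- mk_hit(kind = "transmembrane", evalue = NA_real_)
  expect_equal(nrow(filter_hits(tm)), 1L)
})

test_that("overlap resolution drops conflicting lower-scoring hits", {
  # overlap 51 residues > 0.2 * 101 (shorter) -> conflict, keep higher score
  h <- dplyr::bind_rows(mk_hit(accession = "A", start = 1, end = 100,
                               bit_score = 80),
                        mk_hit(accession = "B", start = 50, end = 150,
                               bit_score = 60))
  out <- resolve_overlaps(h)
  expect_equal(out$accession, "A")
  # disjoint hits both kept, in positional order
  h2 <- dplyr::bind_rows(mk_hit(accession = "B", start = 101, end = 200),
                         mk_hit(accession = "A", start = 1, end = 100))
  expect_equal(resolve_overlaps(h2)$accession, c("A", "B"))
})

test_that("greedy resolution matches exhaustive search on conflict cliques", {
  h <- dplyr::bind_rows(
    mk_hit(accession = "A", start = 1, end = 100, bit_score = 90),
    mk_hit(accession = "B", start = 50, end = 150, bit_score = 80),
    mk_hit(accession = "C", start = 80, end = 180, bit_score = 70))
  conflict <- function(i, j) {
    ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
    ov > 0.2 * (min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1L)
  }
  # brute force: best-scoring conflict-free subset
  best <- character(0); best_score <- -Inf
  for (m in 0:7) {
    sel <- which(bitwAnd(m, 2^(0:2)) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (p in utils::combn(sel, 2, simplify = FALSE)) {
        if (conflict(p[1], p[2])) ok <- FALSE
      }
    }
    if (ok && sum(h$bit_score[sel]) > best_score) {
      best_score <- sum(h$bit_score[sel]); best <- h$accession[sel]
    }
  }
  expect_equal(sort(resolve_overlaps(h)$accession), sort(best))
  expect_equal(resolve_overlaps(h)$accession, "A")
})

test_that("filter then resolve never grows and output is non-overlapping", {
  cfg <- domains_config()
  for (s in 1:10) {
    fx <- synth_genome(fixture_spec(seed = s))
    # add decoy overlapping low-score hits to exercise resolution
    decoys <- dplyr::mutate(fx$hits, accession = paste0(accession, "_d"),
                            bit_score = bit_score / 2,
                            start = pmax(1L, start - 5L))
    h <- dplyr::bind_rows(fx$hits, decoys)
    arch <- build_architectures(h, cfg)
    expect_lte(nrow(arch), nrow(h))
    for (pid in unique(arch$protein_id)) {
      a <- arch[arch$protein_id == pid & arch$kind == "domain", ]
      if (nrow(a) < 2) next
      for (p in utils::combn(nrow(a), 2, simplify = FALSE)) {
        ov <- min(a$end[p[1]], a$end[p[2]]) -
          max(a$start[p[1]], a$start[p[2]]) + 1L
        shorter <- min(a$end[p[1]] - a$start[p[1]],
                       a$end[p[2]] - a$start[p[2]]) + 1L
        expect_lte(ov, cfg$overlap_fraction_max * shorter)
      }
    }
  }
})

test_that("gene_domain_set collapses duplicates and ignores TM features", {
  h <- dplyr::bind_rows(mk_hit(accession = "PAS", start = 1, end = 60),
                        mk_hit(accession = "PAS", start = 100, end = 160),
                        mk_hit(accession = "HATPase", start = 200, end = 300),
                        mk_hit(kind = "transmembrane", accession = "TM1",
                               start = 320, end = 340))
  expect_equal(gene_domain_set("P", h), c("HATPase", "PAS"))
  expect_equal(gene_domain_set("absent", h), character(0))
  expect_equal(gene_domain_set("P", mk_hit(kind = "transmembrane")[0, ]),
               character(0))
})
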