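#' Alignment-free k-mer distance matrix
#'
#' `d(i, j) = 1 - |Ki ∩ Kj| / min(|Ki|, |Kj|)` over the k-mer sets of the
#' two sequences: 0 for identical sequences, 1 when no k-mer is shared. This
#' is the built-in, dependency-free distance behind the default tree backend;
#' it is not a substitute model and is labeled `builtin_nj` in all metadata.
#'
#' @param records tibble of at least 3 ungapped sequence records.
#' @param k k-mer length (default 3).
#' @return list with `labels` (record ids) and `d` (symmetric matrix, zero
#'   diagonal, dimnames = labels).
#' @export
kmer_distance_matrix <- function(records, k = 3L) {
  stopifnot(nrow(records) >= 3L, k >= 1L)
  if (any(grepl("-", records$residues, fixed = TRUE))) {
    stop("k-mer distance requires ungapped sequences", call. = FALSE)
  }
  short <- records$id[nchar(records$residues) < k]
  if (length(short) > 0L) {
    stop("sequence(s) shorter than k = ", k, ": ",
         paste(sQuote(short), collapse = ", "), call. = FALSE)
  }
  kmer_set <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  sets <- lapply(records$residues, kmer_set)
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <-
        1 - shared / min(length(sets[[i]]), length(sets[[j]]))
    }
  }
  list(labels = records$id, d = d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining on the Q criterion. Deterministic:
#' when several pairs minimize Q the lexicographically smallest label pair is
#' joined. Negative branch lengths are clamped to zero with the deficit moved
#' to the sibling branch, so total path lengths are preserved. The final
#' three clusters are joined into an unrooted trifurcation.
#'
#' @param dm a distance matrix object (list with `labels`, `d`) as returned
#'   by [kmer_distance_matrix()], or a plain symmetric matrix with dimnames.
#' @return an `ape::phylo` tree (unrooted, trifurcating root).
#' @export
nj_tree <- function(dm) {
  if (is.matrix(dm)) dm <- list(labels = rownames(dm), d = dm)
  d <- dm$d
  labels <- dm$labels
  n <- length(labels)
  stopifnot(n >= 3L, is.matrix(d), nrow(d) == n, ncol(d) == n)
  if (any(!is.finite(d))) stop("non-finite distance matrix", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-9)) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  # each active cluster is a Newick subtree string; first_label orders ties
  node <- labels
  first_label <- labels
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q <= min(q) + 1e-12, arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    key <- apply(best, 1L, function(ij) {
      p <- sort(c(first_label[ij[1]], first_label[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- best[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt_bl(li), node[j], fmt_bl(lj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    fl <- c(first_label[keep],
            min(first_label[i], first_label[j]))
    first_label <- fl
    d <- d2
  }
  # close the final trifurcation
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], fmt_bl(ls[1]), node[2], fmt_bl(ls[2]),
                 node[3], fmt_bl(ls[3]))
  ape::read.tree(text = txt)
}

fmt_bl <- function(x) formatC(x, format = "g", digits = 12)
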