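#' Greedy sequence redundancy reduction
#'
#' CD-HIT-style greedy incremental clustering, longest sequence first: each
#' record joins the first existing representative whose global pairwise
#' identity is at least `identity_threshold`, otherwise it becomes a new
#' representative. Identity is matches / alignment length of a global
#' alignment scored match = 1, mismatch = 0, linear gap penalty -1
#' (computed with `Biostrings::pairwiseAlignment`).
#'
#' @param records tibble of ungapped sequence records.
#' @param identity_threshold identity in (0, 1].
#' @return list with `representatives` (tibble, subset of `records` in
#'   processing order) and `membership` (tibble `id`, `representative_id`).
#' @export
reduce_redundancy <- function(records, identity_threshold) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            identity_threshold > 0, identity_threshold <= 1)
  if (any(grepl("-", records$residues, fixed = TRUE))) {
    stop("reduce before aligning: input contains gap characters",
         call. = FALSE)
  }
  # longest first; ties broken lexicographically by id for determinism
  ord <- order(-nchar(records$residues), records$id)
  recs <- records[ord, ]
  rep_idx <- integer(0)
  member_of <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    assigned <- NA_character_
    for (j in rep_idx) {
      if (pairwise_identity(recs$residues[i], recs$residues[j]) >=
          identity_threshold) {
        assigned <- recs$id[j]
        break
      }
    }
    if (is.na(assigned)) {
      rep_idx <- c(rep_idx, i)
      assigned <- recs$id[i]
    }
    member_of[i] <- assigned
  }
  list(
    representatives = recs[rep_idx, ],
    membership = tibble::tibble(id = recs$id, representative_id = member_of)
  )
}

#' Global pairwise identity between two ungapped sequences
#'
#' Identity = matches / alignment length under global (Needleman-Wunsch)
#' alignment with match = 1, mismatch = 0, linear gap penalty -1.
#'
#' @param a,b residue strings.
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  alphabet <- unique(strsplit(paste0(a, b), "")[[1]])
  mat <- matrix(0, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / aln_len
}
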