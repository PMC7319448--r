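#' Extract the protein identifier from a tree leaf name
#'
#' Leaf names carry the protein identifier as a prefix, separated from the
#' rest of the name by an underscore, a space, a forward slash or a vertical
#' bar. Underscores are ambiguous because RefSeq accessions contain one
#' (`WP_011030745.1`), so resolution is ordered:
#'
#' 1. a leading accession-like token (letters, underscore, digits, dotted
#'    version) is taken whole, up to the next space, `|` or `/`;
#' 2. otherwise split at the first space, `|` or `/`;
#' 3. otherwise split at the first `_`;
#' 4. otherwise the whole name is the identifier.
#'
#' @param leaf_name character vector of leaf names.
#' @return character vector of protein identifiers.
#' @examples
#' parse_leaf_id("WP_011030745.1|Vibrio_cholerae")
#' parse_leaf_id("PA0413_Pseudomonas")
#' @export
parse_leaf_id <- function(leaf_name) {
  if (any(!nzchar(leaf_name))) stop("empty leaf name", call. = FALSE)
  vapply(leaf_name, function(nm) {
    acc <- regmatches(nm, regexpr("^[A-Za-z]+_[0-9]+\\.[0-9]+", nm))
    if (length(acc) == 1L) {
      rest <- substr(nm, nchar(acc) + 1L, nchar(nm))
      if (!nzchar(rest) || substr(rest, 1, 1) %in% c(" ", "|", "/")) {
        return(acc)
      }
    }
    pos <- regexpr("[ |/]", nm)
    if (pos > 0L) return(substr(nm, 1L, pos - 1L))
    pos <- regexpr("_", nm, fixed = TRUE)
    if (pos > 0L) return(substr(nm, 1L, pos - 1L))
    nm
  }, character(1), USE.NAMES = FALSE)
}

#' Auto-detect the type of a text input
#'
#' Classifies input text as one of `newick` (starts with `(` and parses),
#' `alignment` (FASTA, equal lengths, at least one gap), `sequences` (other
#' FASTA) or `id_list` (newline-separated bare tokens). The four grammars are
#' mutually exclusive.
#'
#' @param text input text or a file path.
#' @return one of `"sequences"`, `"alignment"`, `"newick"`, `"id_list"`.
#' @export
detect_input_type <- function(text) {
  lines <- as_text_lines(text)
  txt <- trimws(paste(lines, collapse = "\n"))
  if (!nzchar(txt)) stop("unrecognized input: empty text", call. = FALSE)
  if (startsWith(txt, "(")) {
    tree <- tryCatch(read_newick(txt), error = function(e) NULL)
    if (is.null(tree)) {
      stop("unrecognized input: starts with '(' but is not valid Newick",
           call. = FALSE)
    }
    return("newick")
  }
  if (startsWith(txt, ">")) {
    recs <- read_fasta(txt)
    return(if (is_alignment(recs)) "alignment" else "sequences")
  }
  toks <- trimws(strsplit(txt, "\n", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) > 0L && all(grepl("^[A-Za-z0-9._|-]+$", toks))) {
    return("id_list")
  }
  stop("unrecognized input", call. = FALSE)
}
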