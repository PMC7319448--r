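#' Read protein sequences from FASTA text
#'
#' Parses FASTA into a tibble of sequence records. The header line is split
#' into `id` (first whitespace-delimited token) and `description` (the rest);
#' residue lines are concatenated and uppercased. Gap characters (`-`) are
#' retained, so both unaligned sequence sets and alignments pass through the
#' same reader.
#'
#' @param x FASTA text: a single string, a character vector of lines, or a
#'   path to an existing file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' read_fasta(">A desc\nMKT\nLLV\n")
#' @export
read_fasta <- function(x) {
  lines <- as_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records", call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop("no records: text does not start with a '>' header", call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  residues <- vapply(
    split(lines[!is_header], rec_idx[!is_header]),
    function(ls) toupper(paste(gsub("\\s", "", ls), collapse = "")),
    character(1)
  )
  # records with a header but no sequence lines must still error
  res_full <- character(length(headers))
  res_full[as.integer(names(residues))] <- residues
  if (any(!nzchar(ids))) stop("record with empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate id", if (length(dup) > 1L) "s" else "", ": ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(res_full))) {
    stop("record ", sQuote(ids[!nzchar(res_full)][1]), " has no residues",
         call. = FALSE)
  }
  bad <- regexpr(paste0("[^", AA_CHARS, "-]"), res_full)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("invalid residue character ",
         sQuote(substr(res_full[i], bad[i], bad[i])),
         " in record ", sQuote(ids[i]), " at position ", bad[i],
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), description = unname(desc),
                 residues = unname(res_full))
}

# IUPAC amino-acid one-letter codes incl. ambiguity codes and stop
AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYBJZXUO\\*\\."

#' Write sequence records as FASTA text
#'
#' @param records tibble with `id`, `residues` and optionally `description`.
#' @param line_width residues per line (default 60).
#' @param path optional file path; when given the text is also written there.
#' @return FASTA text as a single string (invisibly when `path` is given).
#' @export
write_fasta <- function(records, line_width = 60L, path = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to write", call. = FALSE)
  if (line_width < 1L) stop("line_width must be >= 1", call. = FALSE)
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- paste0(">", records$id,
                   ifelse(nzchar(desc), paste0(" ", desc), ""))
  body <- vapply(records$residues, function(s) {
    n <- nchar(s)
    starts <- seq(1L, n, by = line_width)
    paste(substring(s, starts, pmin(starts + line_width - 1L, n)),
          collapse = "\n")
  }, character(1))
  out <- paste0(paste(rbind(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", out), path)
    return(invisible(out))
  }
  out
}

#' Do the records form an alignment?
#'
#' Records count as aligned when all residue strings have equal length and at
#' least one gap character is present; equal-length ungapped sets are treated
#' as plain (unaligned) sequences.
#'
#' @param records tibble of sequence records.
#' @return logical scalar.
#' @export
is_alignment <- function(records) {
  nrow(records) >= 2L &&
    length(unique(nchar(records$residues))) == 1L &&
    any(grepl("-", records$residues, fixed = TRUE))
}

#' Strip gap characters from records
#' @param records tibble of sequence records.
#' @return tibble with `-` removed from every residue string.
#' @export
degap <- function(records) {
  dplyr::mutate(records,
                residues = gsub("-", "", .data$residues, fixed = TRUE))
}

# Accept a path, a single string with newlines, or a vector of lines.
as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("[\n>]", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}
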