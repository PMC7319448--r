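#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' One feature hit per row. Envelope coordinates (columns 20-21) define the
#' feature extent, the per-domain independent E-value (column 13) is the
#' E-value and the per-domain bit score (column 14) the score; query accession
#' and query name become `accession` and `name`. All hits are `kind =
#' "domain"`.
#'
#' @param x domtblout text or a file path.
#' @return tibble of feature hits (`protein_id`, `kind`, `source`,
#'   `accession`, `name`, `start`, `end`, `bit_score`, `evalue`).
#' @export
read_domtblout <- function(x) {
  lines <- as_text_lines(x)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  rows <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(rows) == 0L) return(empty_hits())
  parsed <- purrr::map2(rows, lineno, function(row, ln) {
    tok <- strsplit(trimws(row), "\\s+")[[1]]
    if (length(tok) < 23L) {
      stop("domtblout line ", ln, ": expected >= 23 columns, got ",
           length(tok), call. = FALSE)
    }
    tibble::tibble(
      protein_id = tok[1],
      kind = "domain",
      source = "custom",
      accession = ifelse(tok[5] == "-", tok[4], tok[5]),
      name = tok[4],
      start = as.integer(tok[20]),          # envelope from
      end = as.integer(tok[21]),            # envelope to
      bit_score = as.numeric(tok[14]),
      evalue = as.numeric(tok[13])          # independent (i-)E-value
    )
  })
  out <- dplyr::bind_rows(parsed)
  validate_hits(out)
  out
}

#' Read a generic feature-hit TSV
#'
#' Header-required TSV with columns `protein_id`, `kind`, `source`,
#' `accession`, `name`, `start`, `end`, `bit_score`, `evalue`. `kind` is one
#' of `domain`, `transmembrane`, `low_complexity`; TM/low-complexity rows may
#' leave `bit_score`/`evalue` empty.
#'
#' @param x TSV text or a file path.
#' @return tibble of feature hits.
#' @export
read_hits_tsv <- function(x) {
  lines <- as_text_lines(x)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  needed <- c("protein_id", "kind", "source", "accession", "name",
              "start", "end", "bit_score", "evalue")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("hits TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[needed]) |>
    dplyr::mutate(start = as.integer(.data$start),
                  end = as.integer(.data$end),
                  bit_score = as.numeric(.data$bit_score),
                  evalue = as.numeric(.data$evalue))
  validate_hits(out)
  out
}

empty_hits <- function() {
  tibble::tibble(protein_id = character(), kind = character(),
                 source = character(), accession = character(),
                 name = character(), start = integer(), end = integer(),
                 bit_score = numeric(), evalue = numeric())
}

validate_hits <- function(hits) {
  if (!all(hits$kind %in% c("domain", "transmembrane", "low_complexity"))) {
    stop("unknown feature kind: ",
         paste(setdiff(unique(hits$kind),
                       c("domain", "transmembrane", "low_complexity")),
               collapse = ", "), call. = FALSE)
  }
  if (any(hits$start < 1L | hits$end < hits$start)) {
    stop("feature hit with invalid coordinates (need 1 <= start <= end)",
         call. = FALSE)
  }
  if (any(!is.na(hits$evalue) & hits$evalue < 0)) {
    stop("negative E-value", call. = FALSE)
  }
  invisible(hits)
}
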