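#' Genome annotation container
#'
#' A light container pairing a gene table with per-replicon metadata. Gene
#' coordinates are stored 0-based half-open internally; all external formats
#' (GFF3 in/out, JSON export) use their own convention (GFF3: 1-based
#' inclusive), and the conversion happens only at the format boundary.
#'
#' @param genes tibble with columns `gene_id`, `locus_tag`, `protein_id`,
#'   `replicon_id`, `start`, `end`, `strand`, `product` (0-based half-open).
#' @param replicons tibble with `replicon_id`, `length`, `circular`.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, replicons) {
  genes <- tibble::as_tibble(genes) |>
    dplyr::arrange(.data$replicon_id, .data$start, .data$end)
  replicons <- tibble::as_tibble(replicons)
  stopifnot(all(genes$start >= 0), all(genes$start < genes$end),
            all(genes$strand %in% c("+", "-")))
  if (anyDuplicated(genes[c("replicon_id", "start", "end", "strand")])) {
    stop("duplicate gene interval (replicon, start, end, strand)",
         call. = FALSE)
  }
  len <- replicons$length[match(genes$replicon_id, replicons$replicon_id)]
  if (any(!is.na(len) & genes$end > len)) {
    stop("gene coordinates exceed replicon length", call. = FALSE)
  }
  structure(list(genes = genes, replicons = replicons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes on ",
      nrow(x$replicons), " replicon(s)\n", sep = "")
  print(x$genes, n = 5)
  invisible(x)
}

#' Read CDS features from GFF3
#'
#' Imports GFF3 via `rtracklayer` and extracts CDS features into a
#' [genome_annotation()]. GFF3 1-based inclusive coordinates become 0-based
#' half-open; `##sequence-region` pragmas set replicon lengths; an
#' `Is_circular=true` attribute on a `region` feature marks the replicon
#' circular.
#'
#' @param x GFF3 text or a file path.
#' @return a `genome_annotation`.
#' @export
read_gff3 <- function(x) {
  path <- x
  if (length(x) > 1L || grepl("\n", x) || !file.exists(x)) {
    path <- tempfile(fileext = ".gff3")
    on.exit(unlink(path))
    writeLines(as_text_lines(x), path)
  }
  gr <- tryCatch(
    # honor ##sequence-region pragmas; fall back when they are absent
    tryCatch(rtracklayer::import(path, format = "gff3",
                                 sequenceRegionsAsSeqinfo = TRUE),
             error = function(e) rtracklayer::import(path, format = "gff3")),
    error = function(e) stop("GFF3 parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  col <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(NA_character_, length(gr))
  }
  circular <- stats::setNames(
    tolower(col("Is_circular"))[mc$type == "region"] %in% "true",
    as.character(GenomeInfoDb::seqnames(gr))[mc$type == "region"]
  )
  is_cds <- mc$type == "CDS"
  cds <- gr[is_cds]
  if (length(cds) > 0L) {
    ids <- col("ID")[is_cds]
    if (any(is.na(ids) | !nzchar(ids))) {
      stop("CDS without ID attribute", call. = FALSE)
    }
    strands <- as.character(BiocGenerics::strand(cds))
    if (any(!strands %in% c("+", "-"))) {
      bad <- ids[!strands %in% c("+", "-")]
      stop("CDS with undefined strand: ", paste(sQuote(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  genes <- tibble::tibble(
    gene_id = if (length(cds)) col("ID")[is_cds] else character(),
    locus_tag = col("locus_tag")[is_cds],
    protein_id = col("protein_id")[is_cds],
    replicon_id = as.character(GenomeInfoDb::seqnames(cds)),
    start = BiocGenerics::start(cds) - 1L,   # 1-based incl -> 0-based half-open
    end = BiocGenerics::end(cds),
    strand = as.character(BiocGenerics::strand(cds)),
    product = col("product")[is_cds]
  )
  seqi <- GenomeInfoDb::seqinfo(gr)
  replicons <- tibble::tibble(
    replicon_id = GenomeInfoDb::seqnames(seqi),
    length = as.integer(GenomeInfoDb::seqlengths(seqi)),
    circular = unname(circular[GenomeInfoDb::seqnames(seqi)]) %in% TRUE
  )
  genome_annotation(genes, replicons)
}

#' Write a genome annotation as GFF3 text
#'
#' Inverse of [read_gff3()] for the fields this package tracks; internal
#' half-open coordinates are converted back to GFF3 1-based inclusive, so
#' read/write round-trips are exact.
#'
#' @param annotation a `genome_annotation`.
#' @param path optional output file.
#' @return GFF3 text as a single string.
#' @export
write_gff3 <- function(annotation, path = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d",
                   annotation$replicons$replicon_id,
                   annotation$replicons$length))
  region <- sprintf(
    "%s\tphylotracks\tregion\t1\t%d\t.\t+\t.\tID=region-%s%s",
    annotation$replicons$replicon_id, annotation$replicons$length,
    annotation$replicons$replicon_id,
    ifelse(annotation$replicons$circular, ";Is_circular=true", "")
  )
  g <- annotation$genes
  attrs <- paste0(
    "ID=", g$gene_id,
    ifelse(is.na(g$locus_tag), "", paste0(";locus_tag=", g$locus_tag)),
    ifelse(is.na(g$protein_id), "", paste0(";protein_id=", g$protein_id)),
    ifelse(is.na(g$product), "", paste0(";product=", g$product))
  )
  rows <- sprintf("%s\tphylotracks\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  g$replicon_id, g$start + 1L, g$end, g$strand, attrs)
  out <- paste0(paste(c(hdr, region, rows), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", out), path)
    return(invisible(out))
  }
  out
}
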