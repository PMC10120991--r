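# Standard-format I/O. Internally every coordinate is 0-based half-open;
# SAM/BAM conversion happens only at the file boundary, and BED output is
# 0-based half-open by definition.

#' Read aligned reads from SAM/BAM into the pipeline's record layout
#'
#' Keeps only mapped primary alignments with mapping quality at or above
#' `min_mapq`; secondary and supplementary records are dropped. SAM input
#' is converted to sorted, indexed BAM in a temporary location first.
#'
#' @param path SAM or BAM file (by extension). A header is required.
#' @param region Optional `GRanges` (or `"chrom:start-end"` string,
#'   1-based) restricting the query; requires a BAM index and keeps memory
#'   bounded by the region, not the file.
#' @param min_mapq Minimum mapping quality (default 20; standard practice
#'   for enrichment-type analyses, configurable).
#' @param dedup Collapse reads identical in (chrom, start, end, strand,
#'   cigar). Off by default: enrichment protocols legitimately produce
#'   identical fragments.
#' @return Data frame with columns chrom, start, end (0-based half-open
#'   aligned span; soft clips do not move the terminus), strand, cigar,
#'   seq, mapq.
#' @export
read_alignments <- function(path, region = NULL, min_mapq = 20L, dedup = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  which <- NULL
  if (!is.null(region)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("region query requires a BAM index (.bai) for ", bam, call. = FALSE)
    }
    if (is.character(region)) region <- as(region, "GRanges")
    which <- region
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flags, what = c("mapq", "seq"),
                            mapqFilter = min_mapq)
  } else {
    Rsamtools::ScanBamParam(flag = flags, what = c("mapq", "seq"),
                            mapqFilter = min_mapq, which = which)
  }
  ga <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam), param = param)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ga)),
    start = BiocGenerics::start(ga) - 1L,
    end = BiocGenerics::end(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    seq = as.character(S4Vectors::mcols(ga)$seq),
    mapq = S4Vectors::mcols(ga)$mapq,
    stringsAsFactors = FALSE)
  if (dedup) {
    df <- df[!duplicated(df[c("chrom", "start", "end", "strand", "cigar")]), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write aligned reads as coordinate-sorted SAM
#'
#' @param reads Read table as produced by the simulator or
#'   [read_alignments()].
#' @param path Output SAM path.
#' @param lengths Named vector of contig lengths (for the `@SQ` header).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, lengths) {
  if (is.null(names(lengths))) stop("contig lengths must be named", call. = FALSE)
  o <- order(match(reads$chrom, names(lengths)), reads$start, reads$end,
             reads$strand, reads$cigar)
  reads <- reads[o, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), as.integer(lengths)),
              "@PG\tID:crossseq\tPN:crossseq")
  n <- nrow(reads)
  body <- if (n) {
    sprintf("read%06d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            seq_len(n),
            ifelse(reads$strand == "-", 16L, 0L),
            reads$chrom,
            reads$start + 1L,
            as.integer(reads$mapq),
            reads$cigar,
            reads$seq)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write called sites as BED6 or a TSV report
#'
#' BED uses 0-based half-open single-base intervals at the cut position
#' with the CROSS score in the score column. The TSV report carries a
#' `#`-prefixed header line and one row per site with all available
#' evidence and annotation columns.
#'
#' @param sites Site table from [scan_genome()] (possibly augmented by
#'   [annotate_sites()] / [score_site_by_mode()]).
#' @param path Output file path.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    if (!nrow(sites)) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    strand <- if ("orientation" %in% names(sites)) {
      ifelse(is.na(sites$orientation), "*", sites$orientation)
    } else rep("*", nrow(sites))
    gr <- GenomicRanges::GRanges(
      sites$chrom,
      IRanges::IRanges(sites$cut_pos + 1L, sites$cut_pos + 1L),
      strand = strand)
    S4Vectors::mcols(gr)$name <- sprintf("site_%d", seq_len(nrow(sites)))
    S4Vectors::mcols(gr)$score <- sites$cross_score
    rtracklayer::export(gr, path, format = "BED")
  } else {
    df <- sites
    # serialise list columns (per-position counts) as comma lists
    for (cn in names(df)) {
      if (is.list(df[[cn]])) {
        df[[cn]] <- vapply(df[[cn]], function(v)
          paste(v, collapse = ","), character(1))
      }
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
    if (nrow(df)) {
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a TSV site report written by [write_sites()]
#'
#' @param path TSV report path.
#' @return Data frame with the report columns.
#' @export
read_sites_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty report: ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  if (length(lines) == 1L) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    return(df)
  }
  utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                    col.names = cols, comment.char = "",
                    stringsAsFactors = FALSE)
}
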