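#' In-memory genome index
#'
#' A minimal random-access view over a set of contigs, the common currency
#' between the simulator, the pileup builder and the annotation steps.
#' Sequences are held as uppercase character strings; coordinates are
#' 0-based half-open throughout.
#'
#' @param seqs Named character vector of contig sequences.
#' @return An object of class `genome_index`.
#' @seealso [genome_index_fasta()] for an on-disk FASTA backend.
#' @examples
#' gi <- genome_index(c(chr1 = "ACGTACGTAC"))
#' fetch_seq(gi, "chr1", 2, 6)
#' @export
genome_index <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("contig sequences must be named", call. = FALSE)
  }
  seqs <- toupper(seqs)
  structure(list(seqs = seqs,
                 lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = c("genome_index_mem", "genome_index"))
}

#' FASTA-backed genome index
#'
#' Wraps an indexed FASTA file (sidecar `.fai` created on first use) for
#' random-access base fetches without loading whole contigs.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_index`.
#' @export
genome_index_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  idx <- Rsamtools::scanFaIndex(fa)
  structure(list(fa = fa,
                 lengths = stats::setNames(
                   BiocGenerics::width(idx),
                   as.character(GenomicRanges::seqnames(idx)))),
            class = c("genome_index_fa", "genome_index"))
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$lengths), "contig(s),",
      sum(as.numeric(x$lengths)), "bp\n")
  invisible(x)
}

#' Contig names of a genome index
#' @param genome A `genome_index`.
#' @return Character vector.
#' @export
contig_names <- function(genome) names(genome$lengths)

#' Contig lengths of a genome index
#' @param genome A `genome_index`.
#' @return Named integer vector.
#' @export
contig_lengths <- function(genome) genome$lengths

#' Fetch reference bases
#'
#' @param genome A `genome_index`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase string of `end - start` bases.
#' @export
fetch_seq <- function(genome, chrom, start, end) UseMethod("fetch_seq")

#' @noRd
check_fetch_range <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$lengths)) {
    stop("unknown contig: ", chrom, call. = FALSE)
  }
  len <- genome$lengths[[chrom]]
  if (start < 0 || end > len || start > end) {
    stop(sprintf("fetch range [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
}

#' @export
fetch_seq.genome_index_mem <- function(genome, chrom, start, end) {
  check_fetch_range(genome, chrom, start, end)
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' @export
fetch_seq.genome_index_fa <- function(genome, chrom, start, end) {
  check_fetch_range(genome, chrom, start, end)
  if (start == end) return("")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  toupper(as.character(Rsamtools::scanFa(genome$fa, gr)[[1]]))
}

#' Write a genome index to FASTA (with sidecar index)
#'
#' @param genome An in-memory `genome_index`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_index_mem"))
  dss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dss, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
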