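# Read-end pileups and CROSS scoring.
#
# The site statistic is the depth-normalized count of cleavage-signal
# reads: reads whose aligned terminus coincides with the modeled cut.
# Reported in reads-per-million of the library, with the local end
# fraction kept as a candidate gate rather than the headline score.
# Internal vectors are indexed so that vector index i corresponds to
# 0-based genomic position i - 1.

#' Caller parameters
#'
#' @param m Minimum strand-specific end count at a candidate cut (the
#'   bidirectional-support gate requires both forward starts and reverse
#'   ends to reach `m`).
#' @param f_min Minimum end fraction (cleavage-signal reads over local
#'   depth) for a candidate.
#' @param c_max Maximum control end count tolerated at a candidate before
#'   the score-ratio test is required.
#' @param ratio_min Minimum treated/control score ratio when the control
#'   carries more than `c_max` end reads at the position.
#' @param merge_window Candidates within this many bases are merged,
#'   keeping the highest-scoring position.
#' @param require_bidirectional Require `m` end reads on both strands
#'   (blunt-cut signature). When `FALSE` (e.g. nickase data, where repair
#'   can blur one strand), the gate becomes a combined end count of at
#'   least `2 * m`.
#' @param r_min Minimum editor-signal ratio (conversion or insertion) for
#'   a BE/PE candidate.
#' @param pe_tolerance Placement tolerance in bases for the programmed
#'   insertion (0 = exactly at +1).
#' @param min_mapq Mapping-quality filter applied when reading alignments.
#' @param dedup Collapse duplicate fragments when reading alignments.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(m = 3L, f_min = 0.2, c_max = 1L, ratio_min = 5,
                          merge_window = 10L, require_bidirectional = TRUE,
                          r_min = 0.01, pe_tolerance = 0L,
                          min_mapq = 20L, dedup = FALSE) {
  p <- list(m = assert_count(m, "m"), f_min = assert_fraction(f_min, "f_min"),
            c_max = assert_count(c_max, "c_max"),
            ratio_min = as.numeric(ratio_min),
            merge_window = assert_count(merge_window, "merge_window"),
            require_bidirectional = isTRUE(require_bidirectional),
            r_min = assert_fraction(r_min, "r_min"),
            pe_tolerance = assert_count(pe_tolerance, "pe_tolerance"),
            min_mapq = assert_count(min_mapq, "min_mapq"),
            dedup = isTRUE(dedup))
  if (p$ratio_min < 1) stop("ratio_min must be >= 1", call. = FALSE)
  class(p) <- "caller_params"
  p
}

#' Build a strand-resolved read-end pileup
#'
#' Counts, per position: forward-strand reads whose first aligned base is
#' here (`fwd_starts`), reverse-strand reads whose last aligned base is
#' here (`rev_ends`), and per-strand aligned-span coverage. Soft-clipped
#' bases never move a terminus — the terminus is the first/last
#' reference-aligned base, which is how the read table stores `start` and
#' `end`.
#'
#' @param reads Read table ([read_alignments()] / simulator output).
#' @param lengths Named contig lengths (e.g. [contig_lengths()]).
#' @return Object of class `end_pileup`: per-contig count vectors plus
#'   `total_mapped`, the library size in reads.
#' @export
build_end_pileup <- function(reads, lengths) {
  if (is.null(names(lengths))) stop("contig lengths must be named", call. = FALSE)
  unknown <- setdiff(unique(reads$chrom), names(lengths))
  if (length(unknown)) {
    stop("reads on unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  contigs <- lapply(names(lengths), function(cn) {
    len <- as.integer(lengths[[cn]])
    r <- reads[reads$chrom == cn, , drop = FALSE]
    fwd <- r[r$strand == "+", , drop = FALSE]
    rev <- r[r$strand == "-", , drop = FALSE]
    cov_vec <- function(rr) {
      if (!nrow(rr)) return(integer(len))
      as.integer(IRanges::coverage(IRanges::IRanges(rr$start + 1L, rr$end),
                                   width = len))
    }
    list(length = len,
         fwd_starts = tabulate(fwd$start + 1L, nbins = len),
         rev_ends = tabulate(rev$end, nbins = len),
         depth_fwd = cov_vec(fwd),
         depth_rev = cov_vec(rev))
  })
  names(contigs) <- names(lengths)
  structure(list(contigs = contigs, total_mapped = nrow(reads)),
            class = "end_pileup")
}

#' @export
print.end_pileup <- function(x, ...) {
  cat("end_pileup:", length(x$contigs), "contig(s),",
      x$total_mapped, "mapped reads\n")
  invisible(x)
}

#' @noRd
pileup_contig <- function(pileup, chrom) {
  ct <- pileup$contigs[[chrom]]
  if (is.null(ct)) stop("unknown contig in pileup: ", chrom, call. = FALSE)
  ct
}

#' CROSS score at a position
#'
#' Let `F` be the forward-strand starts at `cut_pos`, `R` the
#' reverse-strand ends at `cut_pos - 1` and `D` the both-strand depth at
#' `cut_pos`. The score is `1e6 * (F + R) / total_mapped` (cleavage-signal
#' reads per million mapped reads), reported with the end fraction
#' `f = (F + R) / D` (0 when `D = 0`). The position is a candidate only
#' with bidirectional support (`F >= m` and `R >= m`) and `f >= f_min`;
#' otherwise the score is still reported but flagged non-candidate.
#'
#' @param pileup An [build_end_pileup()] result.
#' @param chrom Contig name.
#' @param cut_pos 0-based cut position (cut between `cut_pos - 1` and
#'   `cut_pos`). At `cut_pos = 0` there is no position for `R`; the score
#'   uses `R = 0` and the result is flagged `edge`.
#' @param params [caller_params()].
#' @return List: chrom, cut_pos, cross_score, end_count_fwd,
#'   end_count_rev, local_depth, end_fraction, candidate, edge.
#' @export
cross_score <- function(pileup, chrom, cut_pos, params = caller_params()) {
  ct <- pileup_contig(pileup, chrom)
  if (cut_pos < 0L || cut_pos >= ct$length) {
    stop("cut_pos outside contig ", chrom, call. = FALSE)
  }
  i <- cut_pos + 1L
  F_ <- ct$fwd_starts[i]
  R_ <- if (cut_pos >= 1L) ct$rev_ends[i - 1L] else 0L
  D <- ct$depth_fwd[i] + ct$depth_rev[i]
  score <- if (pileup$total_mapped > 0) 1e6 * (F_ + R_) / pileup$total_mapped else 0
  f <- if (D > 0) (F_ + R_) / D else 0
  gate <- if (params$require_bidirectional) {
    F_ >= params$m && R_ >= params$m
  } else {
    (F_ + R_) >= 2L * params$m
  }
  list(chrom = chrom, cut_pos = as.integer(cut_pos),
       cross_score = score, end_count_fwd = F_, end_count_rev = R_,
       local_depth = D, end_fraction = f,
       candidate = gate && f >= params$f_min,
       edge = cut_pos == 0L)
}

#' Scan a genome for candidate cleavage sites
#'
#' Every position passing the [cross_score()] candidate gates and the
#' no-guide control test becomes a candidate: the control may carry at
#' most `c_max` end reads at the position, or the treated score must be
#' at least `ratio_min` times the control score. Candidates within
#' `merge_window` bases are merged keeping the highest-scoring position;
#' the result is sorted by descending score with dense 1-based ranks,
#' ties broken by (chrom, cut_pos).
#'
#' @param treated,control `end_pileup` objects over the same contigs.
#' @param params [caller_params()].
#' @return Data frame of ranked candidate sites (class
#'   `c("cleavage_sites", "data.frame")`).
#' @export
scan_genome <- function(treated, control, params = caller_params()) {
  if (!identical(names(treated$contigs), names(control$contigs)) ||
      !all(vapply(names(treated$contigs), function(cn)
        treated$contigs[[cn]]$length == control$contigs[[cn]]$length,
        logical(1)))) {
    stop("treated and control pileups cover different contigs", call. = FALSE)
  }
  rows <- lapply(names(treated$contigs), function(cn) {
    tc <- treated$contigs[[cn]]
    cc <- control$contigs[[cn]]
    len <- tc$length
    F_ <- tc$fwd_starts
    R_ <- c(0L, tc$rev_ends[-len])
    E <- F_ + R_
    D <- tc$depth_fwd + tc$depth_rev
    f <- ifelse(D > 0, E / pmax(D, 1L), 0)
    score <- if (treated$total_mapped > 0) 1e6 * E / treated$total_mapped else
      numeric(len)
    gate <- if (params$require_bidirectional) {
      F_ >= params$m & R_ >= params$m
    } else {
      E >= 2L * params$m
    }
    cand <- gate & f >= params$f_min
    Ec <- cc$fwd_starts + c(0L, cc$rev_ends[-len])
    score_c <- if (control$total_mapped > 0) 1e6 * Ec / control$total_mapped else
      numeric(len)
    pass_ctrl <- Ec <= params$c_max | score >= params$ratio_min * score_c
    pos <- which(cand & pass_ctrl) - 1L
    if (!length(pos)) return(NULL)
    # merge nearby candidates, keeping the maximum-score position
    grp <- cumsum(c(1L, diff(pos) > params$merge_window))
    keep <- vapply(split(pos, grp), function(pp) {
      s <- score[pp + 1L]
      pp[which(s == max(s))[1]]
    }, integer(1))
    data.frame(chrom = cn, cut_pos = as.integer(keep),
               cross_score = score[keep + 1L],
               end_count_fwd = F_[keep + 1L],
               end_count_rev = R_[keep + 1L],
               local_depth = D[keep + 1L],
               end_fraction = f[keep + 1L],
               control_score = score_c[keep + 1L],
               control_end_count = Ec[keep + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), cut_pos = integer(0),
                      cross_score = numeric(0), end_count_fwd = integer(0),
                      end_count_rev = integer(0), local_depth = integer(0),
                      end_fraction = numeric(0), control_score = numeric(0),
                      control_end_count = integer(0))
  }
  out <- out[order(-out$cross_score, out$chrom, out$cut_pos), , drop = FALSE]
  out$rank <- dense_rank_desc(out$cross_score)
  rownames(out) <- NULL
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

#' Strand-specific truncation fraction at a position
#'
#' The fraction of reads on one strand whose terminus falls exactly at a
#' position — the nickase signature: a clear pile of read ends toward the
#' nick on the cut strand.
#'
#' @param pileup An `end_pileup`.
#' @param chrom Contig name.
#' @param pos 0-based position.
#' @param strand `"+"` (read starts at `pos`) or `"-"` (read ends at
#'   `pos`).
#' @return Fraction in \[0,1\]; 0 when the strand depth is 0.
#' @export
truncation_fraction <- function(pileup, chrom, pos, strand = c("+", "-")) {
  strand <- match.arg(strand)
  ct <- pileup_contig(pileup, chrom)
  if (pos < 0L || pos >= ct$length) stop("pos outside contig", call. = FALSE)
  i <- pos + 1L
  if (strand == "+") {
    if (ct$depth_fwd[i] == 0L) 0 else ct$fwd_starts[i] / ct$depth_fwd[i]
  } else {
    if (ct$depth_rev[i] == 0L) 0 else ct$rev_ends[i] / ct$depth_rev[i]
  }
}
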