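# Bulge-aware alignment of candidate loci to the guide, PAM discovery,
# consensus matrices over called sites, and the guanine-availability
# check for ssDNA labeling.

#' @noRd
iupac_match <- function(pattern, seq) {
  pv <- strsplit(pattern, "")[[1]]
  sv <- strsplit(seq, "")[[1]]
  if (length(pv) != length(sv)) return(FALSE)
  all(mapply(function(p, s) {
    opts <- Biostrings::IUPAC_CODE_MAP[[p]]
    !is.null(opts) && grepl(s, opts, fixed = TRUE)
  }, pv, sv))
}

#' Find PAM matches in a genomic window, both strands
#'
#' @param genome A `genome_index`.
#' @param chrom Contig name.
#' @param window 0-based half-open `c(start, end)` interval to scan.
#' @param pattern PAM pattern in IUPAC codes (e.g. `"NGG"`). The reverse
#'   strand is matched against the reverse complement of the window.
#' @return Data frame with one row per match: `strand`; `pos`, the
#'   0-based offset of the pattern start on that strand's own 5'->3'
#'   representation of the window (offset from the window's left edge for
#'   `+`, from its right edge for `-`); and the forward-strand genomic
#'   interval `fwd_start`, `fwd_end`.
#' @examples
#' gi <- genome_index(c(chr1 = "AAGG"))
#' find_pam(gi, "chr1", c(0, 4), "NGG")
#' @export
find_pam <- function(genome, chrom, window, pattern) {
  pattern <- toupper(pattern)
  if (!all(strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP))) {
    stop("invalid IUPAC symbol in PAM pattern '", pattern, "'", call. = FALSE)
  }
  ws <- as.integer(window[1]); we <- as.integer(window[2])
  seq <- fetch_seq(genome, chrom, ws, we)
  subject <- Biostrings::DNAString(seq)
  plen <- nchar(pattern)
  wlen <- we - ws
  hit_rows <- function(starts1, strand) {
    if (!length(starts1)) return(NULL)
    pos <- starts1 - 1L
    if (strand == "+") {
      data.frame(strand = "+", pos = pos,
                 fwd_start = ws + pos, fwd_end = ws + pos + plen,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(strand = "-", pos = pos,
                 fwd_start = ws + wlen - pos - plen,
                 fwd_end = ws + wlen - pos,
                 stringsAsFactors = FALSE)
    }
  }
  plus <- Biostrings::start(
    Biostrings::matchPattern(pattern, subject, fixed = FALSE))
  minus <- Biostrings::start(
    Biostrings::matchPattern(pattern, Biostrings::reverseComplement(subject),
                             fixed = FALSE))
  out <- rbind(hit_rows(plus, "+"), hit_rows(minus, "-"))
  if (is.null(out)) {
    out <- data.frame(strand = character(0), pos = integer(0),
                      fwd_start = integer(0), fwd_end = integer(0))
  }
  out[order(out$fwd_start, out$strand), , drop = FALSE]
}

#' Align a candidate locus to the guide, allowing one bulge
#'
#' Evaluates, in both orientations of the context: (a) the ungapped
#' alignment, (b) every single-base DNA-bulge placement (one extra target
#' base skipped), and (c) every single-base sgRNA-bulge placement (one
#' spacer base skipped), each anchored on the cut geometry and requiring
#' a valid PAM. Returns the alignment minimizing
#' `(bulge_count, n_mismatches)` lexicographically; ties prefer the most
#' PAM-proximal bulge, then the `+` orientation.
#'
#' @param target_context Genomic sequence around the candidate cut; must
#'   extend at least spacer + PAM + 1 bases on each side of the cut.
#' @param guide A [guide_spec()].
#' @param max_mm Maximum mismatches (default 6).
#' @param max_bulge Maximum bulges, 0 or 1 (default 1).
#' @param cut_at 0-based offset of the cut within `target_context` (the
#'   cut falls between `cut_at - 1` and `cut_at`). Default: the midpoint,
#'   for contexts fetched symmetrically around the cut.
#' @return A `guide_alignment` object (fields `target_seq`,
#'   `n_mismatches`, `bulge_type`, `bulge_pos`, `pam_matches`,
#'   `alignment_string`, `orientation`, `aligned_target`), or `NULL` if no
#'   alignment within `(max_mm, max_bulge)` has a valid PAM.
#' @export
align_guide <- function(target_context, guide, max_mm = 6L, max_bulge = 1L,
                        cut_at = NULL) {
  target_context <- assert_dna(target_context, "target_context", allow_n = TRUE)
  S <- nchar(guide$spacer)
  if (nchar(target_context) < S - 1L) {
    stop("target_context shorter than spacer - 1", call. = FALSE)
  }
  if (!max_bulge %in% c(0L, 1L)) stop("max_bulge must be 0 or 1", call. = FALSE)
  if (is.null(cut_at)) cut_at <- nchar(target_context) %/% 2L
  plen <- nchar(guide$pam)
  spacer_v <- strsplit(guide$spacer, "")[[1]]

  best <- NULL
  better <- function(a, b) {
    # only alignments within the search limits compete; among those,
    # lexicographic (bulge, mm); ties -> most PAM-proximal bulge, then "+"
    if (a$n_mismatches > max_mm || a$n_bulges > max_bulge) return(FALSE)
    if (is.null(b)) return(TRUE)
    ka <- c(a$n_bulges, a$n_mismatches)
    kb <- c(b$n_bulges, b$n_mismatches)
    if (!identical(ka, kb)) {
      return(ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] < kb[2]))
    }
    ba <- if (is.na(a$bulge_pos)) -Inf else a$bulge_pos
    bb <- if (is.na(b$bulge_pos)) -Inf else b$bulge_pos
    if (ba != bb) return(ba > bb)
    a$orientation == "+" && b$orientation != "+"
  }

  for (ori in c("+", "-")) {
    oc <- if (ori == "+") target_context else revcomp(target_context)
    cut <- if (ori == "+") cut_at else nchar(target_context) - cut_at
    pam_start <- cut - guide$cut_offset  # oriented offset of PAM
    if (pam_start + plen > nchar(oc)) next
    pam_seq <- substr(oc, pam_start + 1L, pam_start + plen)
    if (!iupac_match(guide$pam, pam_seq)) next

    grab <- function(len) {
      if (pam_start - len < 0L) return(NULL)
      strsplit(substr(oc, pam_start - len + 1L, pam_start), "")[[1]]
    }

    # (a) ungapped
    tp <- grab(S)
    if (!is.null(tp)) {
      cand <- list(orientation = ori, n_bulges = 0L,
                   n_mismatches = sum(tp != spacer_v),
                   bulge_type = "none", bulge_pos = NA_integer_,
                   target_proto = tp, pam_seq = pam_seq)
      if (better(cand, best)) best <- cand
    }
    if (max_bulge >= 1L) {
      # (b) DNA bulge: target one base longer, skip one target base
      tp1 <- grab(S + 1L)
      if (!is.null(tp1)) {
        for (j in seq_len(S + 1L)) {
          cand <- list(orientation = ori, n_bulges = 1L,
                       n_mismatches = sum(tp1[-j] != spacer_v),
                       bulge_type = "dna", bulge_pos = min(j, S),
                       target_proto = tp1, bulge_skip = j, pam_seq = pam_seq)
          if (better(cand, best)) best <- cand
        }
      }
      # (c) sgRNA bulge: target one base shorter, skip one spacer base
      tp2 <- grab(S - 1L)
      if (!is.null(tp2)) {
        for (j in seq_len(S)) {
          cand <- list(orientation = ori, n_bulges = 1L,
                       n_mismatches = sum(tp2 != spacer_v[-j]),
                       bulge_type = "rna", bulge_pos = j,
                       target_proto = tp2, bulge_skip = j, pam_seq = pam_seq)
          if (better(cand, best)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  render_guide_alignment(best, spacer_v, guide)
}

#' @noRd
render_guide_alignment <- function(al, spacer_v, guide) {
  S <- length(spacer_v)
  if (al$bulge_type == "none") {
    sp_row <- spacer_v
    tg_row <- al$target_proto
    aligned_target <- al$target_proto
  } else if (al$bulge_type == "dna") {
    j <- al$bulge_skip
    sp_row <- append(spacer_v, "-", after = j - 1L)
    tg_row <- al$target_proto
    aligned_target <- al$target_proto[-j]
  } else {
    j <- al$bulge_skip
    sp_row <- spacer_v
    tg_row <- append(al$target_proto, "-", after = j - 1L)
    aligned_target <- tg_row
    aligned_target[j] <- "-"
  }
  bars <- ifelse(sp_row == "-" | tg_row == "-", " ",
                 ifelse(sp_row == tg_row, "|", "."))
  alignment_string <- paste(
    paste0(paste(sp_row, collapse = ""), " ", strrep(" ", nchar(guide$pam)),
           " (spacer 5'->3')"),
    paste0(paste(bars, collapse = ""), " ", strrep(" ", nchar(guide$pam))),
    paste0(paste(tg_row, collapse = ""), " ", al$pam_seq, " (target + PAM)"),
    sep = "\n")
  structure(list(
    target_seq = paste0(paste(al$target_proto, collapse = ""), al$pam_seq),
    n_mismatches = as.integer(al$n_mismatches),
    bulge_type = al$bulge_type,
    bulge_pos = al$bulge_pos,
    pam_matches = TRUE,
    alignment_string = alignment_string,
    orientation = al$orientation,
    aligned_target = aligned_target),
    class = "guide_alignment")
}

#' @export
print.guide_alignment <- function(x, ...) {
  cat(sprintf("guide_alignment (%s): %d mismatch(es), bulge %s%s\n",
              x$orientation, x$n_mismatches, x$bulge_type,
              if (!is.na(x$bulge_pos)) sprintf(" at %d", x$bulge_pos) else ""))
  cat(x$alignment_string, "\n")
  invisible(x)
}

#' Consensus matrix over aligned called sites
#'
#' Projects each alignment onto spacer coordinates (a DNA-bulged target
#' drops its extra base; an sgRNA-bulged target leaves a gap that simply
#' does not contribute to that column) and tallies per-column base
#' frequencies with Shannon information content in bits
#' (`2 - entropy`, raw frequencies, no small-sample correction and no
#' background composition — a plain sequence-logo presentation).
#'
#' @param alignments List of `guide_alignment` objects.
#' @return Object of class `consensus_matrix`: `freq` (4 x spacer-length
#'   matrix over A,C,G,T), `counts`, and `information` per column.
#' @export
consensus_matrix <- function(alignments) {
  if (!length(alignments)) stop("no alignments given", call. = FALSE)
  alignments <- Filter(Negate(is.null), alignments)
  if (!length(alignments)) stop("no alignments given", call. = FALSE)
  S <- length(alignments[[1]]$aligned_target)
  counts <- matrix(0L, nrow = 4L, ncol = S,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (al in alignments) {
    at <- al$aligned_target
    stopifnot(length(at) == S)
    for (j in seq_len(S)) {
      b <- at[j]
      if (b %in% rownames(counts)) counts[b, j] <- counts[b, j] + 1L
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  info <- apply(freq, 2L, function(f) {
    nz <- f[f > 0]
    if (!length(nz)) return(NA_real_)
    2 + sum(nz * log2(nz))
  })
  structure(list(freq = freq, counts = counts, information = info,
                 n_sites = length(alignments)),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("consensus_matrix over", x$n_sites, "site(s);",
      "mean information", sprintf("%.2f", mean(x$information, na.rm = TRUE)),
      "bits\n")
  consensus <- rownames(x$freq)[apply(x$freq, 2L, which.max)]
  cat("consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' Guanine availability on the labeled strand
#'
#' The ssDNA probe reacts with guanines, so a target region is labelable
#' only if the strand displaced in the R-loop (the non-target strand,
#' which displays the protospacer) carries at least one G.
#'
#' @param target_context Genomic sequence of the putative target region
#'   (forward strand).
#' @param orientation Orientation of the site: `"+"` means the forward
#'   strand is the non-target strand.
#' @return List with `g_count` (integer) and `labelable`
#'   (`g_count >= 1`).
#' @examples
#' g_content("GGTTAA", "+")
#' @export
g_content <- function(target_context, orientation = c("+", "-")) {
  orientation <- match.arg(orientation)
  target_context <- assert_dna(target_context, "target_context", allow_n = TRUE)
  if (!nzchar(target_context)) stop("empty sequence", call. = FALSE)
  base <- if (orientation == "+") "G" else "C"
  n <- lengths(regmatches(target_context,
                          gregexpr(base, target_context, fixed = TRUE)))
  list(g_count = as.integer(n), labelable = n >= 1L)
}
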