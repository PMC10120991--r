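# Editor-specific read signatures at candidate loci: the base-conversion
# ratio within the editing window (CBE/ABE) and the programmed-insertion
# fraction at the +1 position after the nick (PE). Both are read-level
# ratios: a read counts once regardless of how many window positions are
# converted, with per-position counts reported separately.

#' @noRd
site_orientation <- function(site) {
  ori <- site$orientation
  if (is.null(ori) || length(ori) != 1L || is.na(ori) || !ori %in% c("+", "-")) {
    stop("site orientation undetermined; annotate the site (align_guide) first",
         call. = FALSE)
  }
  ori
}

#' Base-conversion ratio within the editing window
#'
#' A read counts as signal if it spans the entire editing window and
#' carries at least one reference-mismatching base matching the
#' programmed conversion (C->T for CBE, A->G for ABE) as observed on the
#' non-target strand of the site. For a `-`-oriented site the forward
#' strand shows the complement (e.g. G->A for a CBE), which is resolved
#' here. Reads carrying only other mismatches are not signal.
#'
#' @param reads Read table.
#' @param genome A `genome_index`.
#' @param site Site record with `chrom`, `cut_pos` and `orientation`
#'   (a row of an annotated site table, or a list).
#' @param guide A [guide_spec()] with `editor_mode` `"cbe"` or `"abe"`.
#' @return Object of class `editing_signal`: `n_spanning`, `n_signal`,
#'   `ratio` (`NA` when no read spans the window) and `per_position`
#'   conversion counts named by protospacer position.
#' @export
conversion_ratio <- function(reads, genome, site, guide) {
  if (!guide$editor_mode %in% c("cbe", "abe")) {
    stop("conversion_ratio requires a cbe/abe guide, got editor_mode '",
         guide$editor_mode, "'", call. = FALSE)
  }
  ori <- site_orientation(site)
  W <- editing_window_coords(site$cut_pos, ori, guide)
  src_fwd <- if (ori == "+") guide$conversion[["from"]] else
    complement_bases(guide$conversion[["from"]])
  tgt_fwd <- if (ori == "+") guide$conversion[["to"]] else
    complement_bases(guide$conversion[["to"]])
  r <- reads[reads$chrom == site$chrom &
             reads$start <= min(W) & reads$end >= max(W) + 1L, , drop = FALSE]
  n_span <- nrow(r)
  per_pos <- stats::setNames(integer(length(W)), names(W))
  n_sig <- 0L
  if (n_span) {
    ref_bases <- vapply(W, function(g)
      fetch_seq(genome, site$chrom, g, g + 1L), character(1))
    convertible <- ref_bases == src_fwd
    if (any(convertible)) {
      for (j in seq_len(n_span)) {
        hit <- FALSE
        for (k in which(convertible)) {
          off <- query_offset_at(r$cigar[j], r$start[j], W[k])
          if (!is.na(off) && substr(r$seq[j], off, off) == tgt_fwd) {
            per_pos[k] <- per_pos[k] + 1L
            hit <- TRUE
          }
        }
        if (hit) n_sig <- n_sig + 1L
      }
    }
  }
  structure(list(site = list(chrom = site$chrom, cut_pos = site$cut_pos,
                             orientation = ori),
                 mode = guide$editor_mode,
                 n_spanning = n_span, n_signal = n_sig,
                 ratio = if (n_span > 0L) n_sig / n_span else NA_real_,
                 per_position = per_pos),
            class = "editing_signal")
}

#' Programmed-insertion fraction at the +1 position
#'
#' A read counts as signal if its alignment contains an insertion
#' operation placed exactly at the nick junction (the +1 position — the
#' first nucleotide following the nick) whose inserted bases equal the
#' programmed insert, orientation-resolved (a `-`-oriented site expects
#' the reverse complement on the forward strand). `n_spanning` counts
#' reads covering both bases flanking the nick.
#'
#' @param reads Read table.
#' @param site Site record with `chrom`, `cut_pos`, `orientation`.
#' @param guide A [guide_spec()] with `editor_mode = "pe"`.
#' @param tolerance Allowed placement offset in bases (default 0:
#'   the insertion must sit exactly at +1; repair can shift placement in
#'   real data).
#' @return An `editing_signal` (ratio 0 when spanning reads exist but
#'   none carries the insert; `NA` when nothing spans the nick).
#' @export
insertion_fraction <- function(reads, site, guide, tolerance = 0L) {
  if (guide$editor_mode != "pe") {
    stop("insertion_fraction requires a pe guide, got editor_mode '",
         guide$editor_mode, "'", call. = FALSE)
  }
  if (!nzchar(guide$pe_insert)) stop("pe_insert is empty", call. = FALSE)
  ori <- site_orientation(site)
  nick <- site$cut_pos
  expected <- if (ori == "+") guide$pe_insert else revcomp(guide$pe_insert)
  r <- reads[reads$chrom == site$chrom &
             reads$start <= nick - 1L & reads$end >= nick + 1L, , drop = FALSE]
  n_span <- nrow(r)
  n_sig <- 0L
  if (n_span) {
    for (j in seq_len(n_span)) {
      cg <- parse_cigar(r$cigar[j])
      ref <- r$start[j]
      q <- 0L
      for (i in seq_along(cg$op)) {
        op <- cg$op[i]; len <- cg$len[i]
        if (op == "I") {
          if (abs(ref - nick) <= tolerance && len == nchar(expected) &&
              substr(r$seq[j], q + 1L, q + len) == expected) {
            n_sig <- n_sig + 1L
            break
          }
          q <- q + len
        } else if (op %in% c("M", "=", "X")) {
          ref <- ref + len; q <- q + len
        } else if (op == "S") {
          q <- q + len
        } else if (op %in% c("D", "N")) {
          ref <- ref + len
        }
      }
    }
  }
  structure(list(site = list(chrom = site$chrom, cut_pos = site$cut_pos,
                             orientation = ori),
                 mode = "pe",
                 n_spanning = n_span, n_signal = n_sig,
                 ratio = if (n_span > 0L) n_sig / n_span else NA_real_,
                 per_position = NULL),
            class = "editing_signal")
}

#' @export
print.editing_signal <- function(x, ...) {
  cat(sprintf("editing_signal [%s] %s:%d(%s): %d/%d reads, ratio %s\n",
              x$mode, x$site$chrom, x$site$cut_pos, x$site$orientation,
              x$n_signal, x$n_spanning,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio))))
  invisible(x)
}

#' Score a site according to the editor mode
#'
#' Combines the cleavage-score evidence with the mode's editing
#' signature: nuclease mode reports [cross_score()] evidence alone;
#' CBE/ABE add the window [conversion_ratio()]; PE adds the
#' [insertion_fraction()]. In BE/PE modes candidate status additionally
#' requires the editing ratio to reach `params$r_min`.
#'
#' @param site Site record with `chrom`, `cut_pos`, `orientation`.
#' @param pileup Treated `end_pileup`.
#' @param reads Treated read table.
#' @param genome A `genome_index`.
#' @param guide A [guide_spec()].
#' @param params [caller_params()].
#' @return List with the cross-score evidence, the mode, and (in editor
#'   modes) `n_spanning`, `n_signal`, `ratio`, `per_position`; plus the
#'   final `candidate` flag.
#' @export
score_site_by_mode <- function(site, pileup, reads, genome, guide,
                               params = caller_params()) {
  cs <- cross_score(pileup, site$chrom, site$cut_pos, params)
  out <- c(cs, list(mode = guide$editor_mode))
  if (guide$editor_mode %in% c("cbe", "abe")) {
    sig <- conversion_ratio(reads, genome, site, guide)
  } else if (guide$editor_mode == "pe") {
    sig <- insertion_fraction(reads, site, guide, tolerance = params$pe_tolerance)
  } else {
    return(out)
  }
  out$n_spanning <- sig$n_spanning
  out$n_signal <- sig$n_signal
  out$ratio <- sig$ratio
  out$per_position <- sig$per_position
  out$candidate <- isTRUE(cs$candidate) && !is.na(sig$ratio) &&
    sig$ratio >= params$r_min
  out
}
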