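# Shared fixtures and independent oracles. The oracles deliberately use
# naive per-read / per-position loops so that they share no code path
# with the package's vectorised implementations.

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

test_guide <- function(mode = "nuclease", ...) {
  guide_spec("GGTGACTTTAGCCATGGCAA", editor_mode = mode, ...)
}

make_reads <- function(chrom, start, end, strand, cigar = NULL, seq = NULL,
                       mapq = 60L) {
  n <- length(start)
  if (is.null(cigar)) cigar <- paste0(end - start, "M")
  if (is.null(seq)) seq <- strrep("A", end - start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), cigar = rep_len(cigar, n),
             seq = rep_len(seq, n), mapq = rep_len(mapq, n),
             stringsAsFactors = FALSE)
}

# Naive recount of F (forward starts), R (reverse ends) and per-strand
# depth from a raw read list, one read at a time.
oracle_end_counts <- function(reads, len) {
  F_ <- integer(len); R_ <- integer(len)
  Df <- integer(len); Dr <- integer(len)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]
    span <- (s + 1L):e
    if (reads$strand[i] == "+") {
      F_[s + 1L] <- F_[s + 1L] + 1L
      Df[span] <- Df[span] + 1L
    } else {
      R_[e] <- R_[e] + 1L          # last aligned base is e - 1 (0-based)
      Dr[span] <- Dr[span] + 1L
    }
  }
  list(fwd_starts = F_, rev_ends = R_, depth_fwd = Df, depth_rev = Dr)
}

iupac_ok <- function(pat_char, base) {
  grepl(base, Biostrings::IUPAC_CODE_MAP[[pat_char]], fixed = TRUE)
}

# Brute-force PAM scan: test every offset on both strands by character
# comparison.
oracle_find_pam <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  rv <- strsplit(crossseq_revcomp(seq), "")[[1]]
  plen <- length(pv)
  hits <- list()
  for (strand in c("+", "-")) {
    v <- if (strand == "+") sv else rv
    for (off in 0:(length(v) - plen)) {
      if (all(mapply(iupac_ok, pv, v[(off + 1):(off + plen)]))) {
        hits[[length(hits) + 1L]] <- data.frame(strand = strand, pos = off)
      }
    }
  }
  if (!length(hits)) return(data.frame(strand = character(0), pos = integer(0)))
  do.call(rbind, hits)
}

crossseq_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Exhaustive guide-alignment oracle: enumerate every orientation,
# ungapped placement and single-bulge placement with plain loops and
# return the best (bulge_count, n_mismatches) within the limits, or NULL.
oracle_align_guide <- function(context, guide, max_mm = 6L, max_bulge = 1L,
                               cut_at = NULL) {
  if (is.null(cut_at)) cut_at <- nchar(context) %/% 2L
  spacer <- strsplit(guide$spacer, "")[[1]]
  S <- length(spacer)
  pamv <- strsplit(guide$pam, "")[[1]]
  plen <- length(pamv)
  best <- NULL
  consider <- function(bulges, mm) {
    if (mm > max_mm || bulges > max_bulge) return()
    key <- c(bulges, mm)
    if (is.null(best) || key[1] < best[1] ||
        (key[1] == best[1] && key[2] < best[2])) best <<- key
  }
  for (ori in c("+", "-")) {
    oc <- if (ori == "+") context else crossseq_revcomp(context)
    ocv <- strsplit(oc, "")[[1]]
    cut <- if (ori == "+") cut_at else nchar(context) - cut_at
    ps <- cut - guide$cut_offset
    if (ps + plen > length(ocv) || ps < 0) next
    if (!all(mapply(iupac_ok, pamv, ocv[(ps + 1):(ps + plen)]))) next
    if (ps - S >= 0) {
      tp <- ocv[(ps - S + 1):ps]
      consider(0L, sum(tp != spacer))
    }
    if (max_bulge >= 1L) {
      if (ps - S - 1L >= 0) {
        tp1 <- ocv[(ps - S):ps]
        for (j in seq_len(S + 1L)) consider(1L, sum(tp1[-j] != spacer))
      }
      if (ps - S + 1L >= 0) {
        tp2 <- ocv[(ps - S + 2):ps]
        for (j in seq_len(S)) consider(1L, sum(tp2 != spacer[-j]))
      }
    }
  }
  best
}

# Random (spacer-derived) target context with planted substitutions and
# optionally one bulge, embedded in random flanks with a valid PAM and
# the cut at the centre of the returned context.
random_pair <- function(guide, n_sub, bulge = c("none", "dna", "rna"),
                        flank = 30L) {
  bulge <- match.arg(bulge)
  bases <- c("A", "C", "G", "T")
  tv <- strsplit(guide$spacer, "")[[1]]
  S <- length(tv)
  if (n_sub > 0) {
    pos <- sample(S, n_sub)
    for (p in pos) tv[p] <- sample(setdiff(bases, tv[p]), 1L)
  }
  if (bulge == "dna") {
    j <- sample(2:(S + guide$cut_offset - 1L), 1L)
    tv <- append(tv, sample(bases, 1L), after = j - 1L)
  } else if (bulge == "rna") {
    j <- sample(2:(S + guide$cut_offset - 1L), 1L)
    tv <- tv[-j]
  }
  pam <- vapply(strsplit(guide$pam, "")[[1]], function(p) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[p]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  site <- paste0(paste(tv, collapse = ""), paste(pam, collapse = ""))
  left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  full <- paste0(left, site, right)
  # cut is cut_offset bases 5' of the PAM within the site
  cut_at <- flank + length(tv) + guide$cut_offset
  # trim/pad so that the cut sits at the centre (align_guide's default)
  half <- max(cut_at, nchar(full) - cut_at)
  pad_l <- paste(sample(bases, half - cut_at, replace = TRUE), collapse = "")
  pad_r <- paste(sample(bases, half - (nchar(full) - cut_at), replace = TRUE),
                 collapse = "")
  list(context = paste0(pad_l, full, pad_r), cut_at = half)
}
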