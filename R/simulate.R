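# Planted-signal read simulator.
#
# The simulator emits already-aligned single-end records (mapping is an
# external commodity step; the pipeline's computation begins at aligned
# reads). Cleavage is modeled on the molecules: a background fragment
# covering a planted cut is itself cut with probability cleavage_fraction,
# so its read terminus is re-anchored to the cut — at saturation every
# read overlapping the cut terminates there, the signature seen in
# enrichment data.

#' Simulate a random reference contig
#'
#' @param config A [sim_config()].
#' @return A [genome_index()] holding one contig named `chr1` of the
#'   configured length and GC content. Deterministic per seed.
#' @examples
#' gi <- simulate_genome(sim_config(seed = 1, genome_length = 10000))
#' contig_lengths(gi)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_fraction
  seq <- with_seed(stage_seed(config$seed, 0L), {
    paste(sample(c("A", "T", "G", "C"), config$genome_length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
  genome_index(c(chr1 = seq))
}

#' @noRd
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7L + stage * 104729) %% 2147483647)
}

#' Plant on- and off-target protospacer copies into a genome
#'
#' Writes one exact on-target (spacer + concrete PAM) and
#' `config$n_offtargets` degenerate copies into the contig at
#' non-overlapping positions on random strands, each adjacent to a valid
#' PAM instance. `config$planted_bulges` of the off-targets additionally
#' carry a single-base bulge: a DNA bulge inserts one extra target base
#' (target one base longer than the spacer), an sgRNA bulge deletes one
#' (target one base shorter).
#'
#' @param genome A [genome_index()] from [simulate_genome()] (in-memory).
#' @param guide A [guide_spec()].
#' @param config A [sim_config()].
#' @return A list with the modified `genome` and a data frame `sites`
#'   (ground truth: chrom, site_id, cut_pos, protospacer_start, target_len,
#'   orientation, target_seq, n_mismatches, bulge, bulge_pos and the planted
#'   signal fractions).
#' @export
plant_sites <- function(genome, guide, config) {
  stopifnot(inherits(genome, "genome_index_mem"),
            inherits(guide, "guide_spec"),
            inherits(config, "sim_config"))
  S <- nchar(guide$spacer)
  if (config$mismatch_range[2] > S) {
    stop("mismatch_range exceeds spacer length", call. = FALSE)
  }
  allowed_mm <- config$mismatch_positions
  if (is.null(allowed_mm)) allowed_mm <- seq_len(S)
  if (any(allowed_mm < 1L | allowed_mm > S)) {
    stop("mismatch_positions outside [1, spacer length]", call. = FALSE)
  }
  plen <- nchar(guide$pam)
  G <- unname(contig_lengths(genome)[1])
  chrom <- contig_names(genome)[1]
  n_sites <- 1L + config$n_offtargets
  bases <- c("A", "C", "G", "T")

  with_seed(stage_seed(config$seed, 1L), {
    spacer_v <- strsplit(guide$spacer, "")[[1]]
    pam_v <- strsplit(guide$pam, "")[[1]]

    make_pam <- function() {
      paste(vapply(pam_v, function(s) {
        opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[s]], "")[[1]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
      }, character(1)), collapse = "")
    }

    # which off-targets get a bulge: the last planted_bulges of them
    bulged <- if (config$planted_bulges > 0L) {
      seq(config$n_offtargets - config$planted_bulges + 1L, config$n_offtargets)
    } else integer(0)

    rows <- vector("list", n_sites)
    occupied <- integer(0)  # cut positions already used
    margin <- config$read_length + 2L * (S + plen)
    min_sep <- 3L * config$read_length

    for (i in seq_len(n_sites)) {
      is_on <- i == 1L
      tv <- spacer_v
      n_mm <- 0L
      bulge <- "none"
      bulge_pos <- NA_integer_
      if (!is_on) {
        n_mm <- if (config$mismatch_range[1] == config$mismatch_range[2]) {
          config$mismatch_range[1]
        } else sample(seq(config$mismatch_range[1], config$mismatch_range[2]), 1L)
        mm_pos <- sort(sample(allowed_mm, min(n_mm, length(allowed_mm))))
        n_mm <- length(mm_pos)
        for (p in mm_pos) tv[p] <- sample(setdiff(bases, tv[p]), 1L)
        if ((i - 1L) %in% bulged) {
          bulge <- if ((i - 1L) %% 2L == 1L) "dna" else "rna"
          # keep bulges PAM-distal of the cut so the cut-to-PAM geometry holds
          eligible <- setdiff(seq(2L, S + guide$cut_offset - 1L), mm_pos)
          bulge_pos <- sample(eligible, 1L)
          if (bulge == "dna") {
            tv <- append(tv, sample(bases, 1L), after = bulge_pos - 1L)
          } else {
            tv <- tv[-bulge_pos]
          }
        }
      }
      target_len <- length(tv)
      pam_concrete <- make_pam()
      site_fwd_plus <- paste0(paste(tv, collapse = ""), pam_concrete)
      total_len <- target_len + plen

      placed <- FALSE
      for (try in seq_len(1000L)) {
        orientation <- sample(c("+", "-"), 1L)
        a <- sample.int(G - total_len - 2L * margin, 1L) + margin  # 0-based
        ps <- if (orientation == "+") a else a + plen
        cut <- site_cut_pos(ps, orientation, guide, target_len)
        if (all(abs(cut - occupied) >= min_sep)) {
          fwd <- if (orientation == "+") site_fwd_plus else revcomp(site_fwd_plus)
          s <- genome$seqs[[chrom]]
          substr(s, a + 1L, a + total_len) <- fwd
          genome$seqs[[chrom]] <- s
          occupied <- c(occupied, cut)
          rows[[i]] <- data.frame(
            chrom = chrom,
            site_id = if (is_on) "on_target" else sprintf("OT%d", i - 1L),
            cut_pos = cut, protospacer_start = ps, target_len = target_len,
            orientation = orientation, target_seq = site_fwd_plus,
            n_mismatches = n_mm, bulge = bulge, bulge_pos = bulge_pos,
            cleavage_fraction = config$cleavage_fraction,
            conversion_fraction = if (guide$editor_mode %in% c("cbe", "abe"))
              config$conversion_fraction else 0,
            insertion_fraction = if (guide$editor_mode == "pe")
              config$insertion_fraction else 0,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place planted site ", i,
             " without overlap after bounded retries", call. = FALSE)
      }
    }
    list(genome = genome, sites = do.call(rbind, rows))
  })
}

#' Simulate aligned ssDNA-enrichment reads
#'
#' Emits coordinate-sorted aligned-read tables for a treated sample and,
#' if configured, a no-guide control. The background layer is uniform at
#' `mean_depth`, with optional shared coverage hotspots present in both
#' streams. In the treated stream, molecules covering a planted cut are
#' cleaved with probability `cleavage_fraction` (forward-strand reads then
#' start exactly at `cut_pos`, reverse-strand reads end exactly at
#' `cut_pos - 1`); BE modes add the programmed conversion to
#' window-spanning reads, PE mode adds the programmed insertion at the +1
#' position after the nick.
#'
#' @param genome The planted [genome_index()].
#' @param sites Ground-truth site table from [plant_sites()].
#' @param guide A [guide_spec()].
#' @param config A [sim_config()].
#' @return List with elements `treated` and `control` (`NULL` when
#'   `control_included` is `FALSE`), each a data frame with columns
#'   chrom, start, end (0-based half-open, aligned span), strand, cigar,
#'   seq (forward-strand bases, as stored in SAM), mapq.
#' @export
simulate_reads <- function(genome, sites, guide, config) {
  stopifnot(inherits(genome, "genome_index_mem"),
            inherits(guide, "guide_spec"),
            inherits(config, "sim_config"))
  G <- unname(contig_lengths(genome)[1])
  chrom <- contig_names(genome)[1]
  L <- config$read_length
  if (!is.null(sites) && nrow(sites) &&
      any(sites$cut_pos < L | sites$cut_pos > G - L)) {
    stop("planted sites must lie at least one read length from contig ends",
         call. = FALSE)
  }

  hotspots <- with_seed(stage_seed(config$seed, 2L), {
    pick_hotspots(G, sites, config)
  })

  treated <- with_seed(stage_seed(config$seed, 3L), {
    sim_stream(genome, chrom, G, sites, guide, config, hotspots, signal = TRUE)
  })
  control <- if (config$control_included) {
    with_seed(stage_seed(config$seed, 4L), {
      sim_stream(genome, chrom, G, sites, guide, config, hotspots, signal = FALSE)
    })
  }
  list(treated = treated, control = control)
}

#' @noRd
pick_hotspots <- function(G, sites, config) {
  if (config$n_hotspots == 0L) return(integer(0))
  W <- config$hotspot_width
  keepout <- W %/% 2L + 2L * config$read_length
  centers <- integer(0)
  guard <- 0L
  while (length(centers) < config$n_hotspots && guard < 1000L) {
    guard <- guard + 1L
    c0 <- sample.int(G - W, 1L) + W %/% 2L
    clear_sites <- is.null(sites) || !nrow(sites) ||
      all(abs(c0 - sites$cut_pos) > keepout)
    if (clear_sites && all(abs(c0 - centers) > 2L * W)) centers <- c(centers, c0)
  }
  centers
}

#' @noRd
sim_stream <- function(genome, chrom, G, sites, guide, config, hotspots, signal) {
  L <- config$read_length
  n_bg <- round(G * config$mean_depth / L)
  start <- sample.int(G - L + 1L, n_bg, replace = TRUE) - 1L
  end <- start + L
  strand <- sample(c("+", "-"), n_bg, replace = TRUE)

  # random endogenous breaks: truncate a fraction of background reads
  if (config$background_end_rate > 0) {
    tr <- which(stats::runif(n_bg) < config$background_end_rate)
    if (length(tr)) {
      newlen <- sample(seq(20L, L), length(tr), replace = TRUE)
      plus <- strand[tr] == "+"
      end[tr[plus]] <- start[tr[plus]] + newlen[plus]
      start[tr[!plus]] <- end[tr[!plus]] - newlen[!plus]
    }
  }

  # shared coverage hotspots (endogenous ssDNA loci)
  for (c0 in hotspots) {
    W <- config$hotspot_width
    n_h <- round((config$hotspot_fold - 1) * config$mean_depth * W / L)
    lo <- max(0L, c0 - W %/% 2L)
    hi <- min(G - L, c0 + W %/% 2L - L)
    if (hi <= lo || n_h <= 0L) next
    hs <- sample.int(hi - lo + 1L, n_h, replace = TRUE) + lo - 1L
    start <- c(start, hs)
    end <- c(end, hs + L)
    strand <- c(strand, sample(c("+", "-"), n_h, replace = TRUE))
  }

  cigar <- NULL  # filled after signal edits
  seq <- NULL

  if (signal && !is.null(sites) && nrow(sites)) {
    for (k in seq_len(nrow(sites))) {
      st <- sites[k, ]
      cut <- st$cut_pos
      cover <- start < cut & end > cut
      cut_draw <- stats::runif(length(start)) < st$cleavage_fraction
      len <- end - start
      sel_p <- which(cover & cut_draw & strand == "+")
      start[sel_p] <- cut
      end[sel_p] <- pmin(cut + len[sel_p], G)
      sel_m <- which(cover & cut_draw & strand == "-")
      end[sel_m] <- cut
      start[sel_m] <- pmax(cut - len[sel_m], 0L)
    }
  }

  seq <- substring(genome$seqs[[chrom]], start + 1L, end)
  cigar <- paste0(end - start, "M")

  if (signal && !is.null(sites) && nrow(sites)) {
    if (guide$editor_mode %in% c("cbe", "abe")) {
      src <- guide$conversion[["from"]]
      tgt <- guide$conversion[["to"]]
      for (k in seq_len(nrow(sites))) {
        st <- sites[k, ]
        if (st$conversion_fraction <= 0 || st$bulge != "none") next
        W <- editing_window_coords(st$cut_pos, st$orientation, guide)
        span <- start <= min(W) & end >= max(W) + 1L
        sel <- which(span & stats::runif(length(start)) < st$conversion_fraction)
        if (!length(sel)) next
        src_fwd <- if (st$orientation == "+") src else complement_bases(src)
        tgt_fwd <- if (st$orientation == "+") tgt else complement_bases(tgt)
        for (g in W) {
          if (fetch_seq(genome, chrom, g, g + 1L) != src_fwd) next
          off <- g - start[sel] + 1L
          seq[sel] <- paste0(substr(seq[sel], 1L, off - 1L), tgt_fwd,
                             substring(seq[sel], off + 1L))
        }
      }
    }
    if (guide$editor_mode == "pe") {
      for (k in seq_len(nrow(sites))) {
        st <- sites[k, ]
        if (st$insertion_fraction <= 0) next
        cut <- st$cut_pos
        span <- start <= cut - 1L & end >= cut + 1L
        sel <- which(span & stats::runif(length(start)) < st$insertion_fraction)
        if (!length(sel)) next
        ins <- if (st$orientation == "+") guide$pe_insert else revcomp(guide$pe_insert)
        left <- cut - start[sel]
        seq[sel] <- paste0(substr(seq[sel], 1L, left), ins,
                           substring(seq[sel], left + 1L))
        cigar[sel] <- paste0(left, "M", nchar(ins), "I", end[sel] - cut, "M")
      }
    }
  }

  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   cigar = cigar, seq = seq, mapq = 60L,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end, df$strand, df$cigar), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate a full planted-signal experiment
#'
#' Convenience wrapper chaining [simulate_genome()], [plant_sites()] and
#' [simulate_reads()].
#'
#' @param guide A [guide_spec()].
#' @param config A [sim_config()].
#' @return List with `genome`, `sites`, `treated`, `control`, `guide`,
#'   `config`.
#' @examples
#' g <- guide_spec("GGTGACTTTAGCCATGGCAA")
#' sim <- simulate_experiment(g, sim_config(seed = 7, genome_length = 20000,
#'                                          n_offtargets = 1,
#'                                          planted_bulges = 0,
#'                                          mean_depth = 50))
#' nrow(sim$treated)
#' @export
simulate_experiment <- function(guide, config) {
  genome <- simulate_genome(config)
  planted <- plant_sites(genome, guide, config)
  reads <- simulate_reads(planted$genome, planted$sites, guide, config)
  list(genome = planted$genome, sites = planted$sites,
       treated = reads$treated, control = reads$control,
       guide = guide, config = config)
}
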