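#' Simulation configuration
#'
#' Describes a complete planted-signal experiment: a random reference
#' contig, one on-target plus `n_offtargets` degenerate protospacer copies
#' written into it, and aligned ssDNA-enrichment reads for a treated sample
#' and (optionally) a no-guide control.
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 100-kb contig at human-like GC, five off-targets carrying 2-4
#' spacer mismatches, one additional bulged off-target, 200x mean depth,
#' and half of the cut-covering molecules cleaved (enrichment libraries
#' show the large majority of reads terminating at the cut, and 0.5 keeps
#' the per-site end fraction well clear of the caller's gates while still
#' leaving uncleaved molecules to carry base-editor conversions).
#'
#' @param seed Integer RNG seed; identical configs are reproduced byte for
#'   byte.
#' @param genome_length Contig length in bases (>= 50 x `read_length`).
#' @param gc_fraction Genome GC content in \[0,1\].
#' @param n_offtargets Number of mismatched off-target copies to plant
#'   (in addition to the exact on-target).
#' @param mismatch_range Inclusive integer pair: spacer mismatches per
#'   off-target are drawn uniformly from this range.
#' @param mismatch_positions Protospacer positions (1 = PAM-distal) eligible
#'   to carry planted mismatches; `NULL` means all spacer positions.
#' @param planted_bulges How many of the off-targets additionally carry a
#'   single-base bulge (target one base longer or shorter than the spacer).
#'   Must not exceed `n_offtargets`.
#' @param read_length Read length in bases (single-end).
#' @param mean_depth Mean fold-coverage of the background read layer.
#' @param cleavage_fraction Probability that a molecule covering a planted
#'   cut is cleaved there, so that its read terminates at the cut position.
#' @param conversion_fraction Probability that a read spanning the editing
#'   window of a planted site carries the programmed base conversion
#'   (BE modes).
#' @param insertion_fraction Probability that a read spanning the nick of a
#'   planted site carries the programmed insertion (PE mode).
#' @param background_end_rate Probability that a background read is
#'   truncated at a random internal position, emulating random breaks in
#'   endogenous ssDNA.
#' @param control_included Emit a matched no-guide control read stream.
#' @param n_hotspots Number of endogenous-ssDNA hotspots (loci with elevated
#'   coverage present in both treated and control), which make control
#'   subtraction non-trivial.
#' @param hotspot_fold Coverage multiplier inside a hotspot.
#' @param hotspot_width Hotspot width in bases.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_fraction = 0.41,
                       n_offtargets = 5L,
                       mismatch_range = c(2L, 4L),
                       mismatch_positions = NULL,
                       planted_bulges = 1L,
                       read_length = 100L,
                       mean_depth = 200,
                       cleavage_fraction = 0.5,
                       conversion_fraction = 0.3,
                       insertion_fraction = 0.5,
                       background_end_rate = 0.01,
                       control_included = TRUE,
                       n_hotspots = 2L,
                       hotspot_fold = 5,
                       hotspot_width = 1000L) {
  cfg <- list(
    seed = assert_count(seed, "seed"),
    genome_length = assert_count(genome_length, "genome_length", min = 1L),
    gc_fraction = assert_fraction(gc_fraction, "gc_fraction"),
    n_offtargets = assert_count(n_offtargets, "n_offtargets"),
    mismatch_range = as.integer(mismatch_range),
    mismatch_positions = if (!is.null(mismatch_positions)) as.integer(mismatch_positions),
    planted_bulges = assert_count(planted_bulges, "planted_bulges"),
    read_length = assert_count(read_length, "read_length", min = 20L),
    mean_depth = as.numeric(mean_depth),
    cleavage_fraction = assert_fraction(cleavage_fraction, "cleavage_fraction"),
    conversion_fraction = assert_fraction(conversion_fraction, "conversion_fraction"),
    insertion_fraction = assert_fraction(insertion_fraction, "insertion_fraction"),
    background_end_rate = assert_fraction(background_end_rate, "background_end_rate"),
    control_included = isTRUE(control_included),
    n_hotspots = assert_count(n_hotspots, "n_hotspots"),
    hotspot_fold = as.numeric(hotspot_fold),
    hotspot_width = assert_count(hotspot_width, "hotspot_width", min = 1L))
  if (length(cfg$mismatch_range) != 2L || any(is.na(cfg$mismatch_range)) ||
      cfg$mismatch_range[1] > cfg$mismatch_range[2] || cfg$mismatch_range[1] < 0L) {
    stop("mismatch_range must be an ordered non-negative integer pair", call. = FALSE)
  }
  if (cfg$genome_length < 50L * cfg$read_length) {
    stop("genome_length must be at least 50 x read_length", call. = FALSE)
  }
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth <= 0) {
    stop("mean_depth must be positive", call. = FALSE)
  }
  if (cfg$planted_bulges > cfg$n_offtargets) {
    stop("planted_bulges cannot exceed n_offtargets", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d bp (GC %.2f), %dx depth, %d-nt reads, seed %d\n",
              x$genome_length, x$gc_fraction, round(x$mean_depth),
              x$read_length, x$seed))
  cat(sprintf("  sites: 1 on-target + %d off-targets (%d-%d mm) + %d bulged\n",
              x$n_offtargets, x$mismatch_range[1], x$mismatch_range[2],
              x$planted_bulges))
  cat(sprintf("  fractions: cleavage %.2f, conversion %.2f, insertion %.2f\n",
              x$cleavage_fraction, x$conversion_fraction, x$insertion_fraction))
  invisible(x)
}
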