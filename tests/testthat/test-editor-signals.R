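# Editing-window conversion ratios and +1 insertion fractions on
# constructed reads, plus mode dispatch and estimator calibration.

# A tiny genome whose forward strand carries the CBE guide's protospacer
# at a known position, so window coordinates are easy to reason about.
be_fixture <- function(orientation = "+") {
  guide <- test_guide("cbe")
  S <- nchar(guide$spacer)
  flank <- strrep("T", 60)
  site_fwd <- if (orientation == "+") paste0(guide$spacer, "AGG") else
    crossseq_revcomp(paste0(guide$spacer, "AGG"))
  genome <- genome_index(c(chr1 = paste0(flank, site_fwd, flank)))
  ps <- if (orientation == "+") 60L else 63L
  cut <- site_cut_pos(ps, orientation, guide)
  list(guide = guide, genome = genome, ps = ps,
       site = list(chrom = "chr1", cut_pos = cut, orientation = orientation))
}

ref_read <- function(genome, start, end) {
  make_reads("chr1", start, end, "+",
             seq = fetch_seq(genome, "chr1", start, end))
}

mutate_at <- function(reads, genome, gpos, to) {
  off <- gpos - reads$start + 1L
  substr(reads$seq, off, off) <- to
  reads
}

test_that("conversion ratio counts window-spanning converted reads", {
  fx <- be_fixture("+")
  W <- editing_window_coords(fx$site$cut_pos, "+", fx$guide)
  # spacer position 6 is a C (GGTGAC...), convertible on the + site
  g6 <- W[["6"]]
  expect_equal(fetch_seq(fx$genome, "chr1", g6, g6 + 1L), "C")
  span <- do.call(rbind, replicate(20, ref_read(fx$genome, 30L, 130L),
                                   simplify = FALSE))
  span[1:5, ] <- mutate_at(span[1:5, ], fx$genome, g6, "T")
  sig <- conversion_ratio(span, fx$genome, fx$site, fx$guide)
  expect_equal(sig$n_spanning, 20L)
  expect_equal(sig$n_signal, 5L)
  expect_equal(sig$ratio, 0.25)
  expect_equal(unname(sig$per_position[["6"]]), 5L)
})

test_that("reads with unrelated mismatches only are not signal", {
  fx <- be_fixture("+")
  W <- editing_window_coords(fx$site$cut_pos, "+", fx$guide)
  reads <- do.call(rbind, replicate(10, ref_read(fx$genome, 30L, 130L),
                                    simplify = FALSE))
  # a C -> G change is not the programmed C -> T conversion
  reads[1:4, ] <- mutate_at(reads[1:4, ], fx$genome, W[["6"]], "G")
  sig <- conversion_ratio(reads, fx$genome, fx$site, fx$guide)
  expect_equal(sig$n_signal, 0L)
  expect_equal(sig$ratio, 0)
})

test_that("minus-oriented sites count the complement conversion", {
  fx <- be_fixture("-")
  W <- editing_window_coords(fx$site$cut_pos, "-", fx$guide)
  g6 <- W[["6"]]
  # C on the non-target strand reads as G on the forward strand
  expect_equal(fetch_seq(fx$genome, "chr1", g6, g6 + 1L), "G")
  reads <- do.call(rbind, replicate(10, ref_read(fx$genome, 30L, 130L),
                                    simplify = FALSE))
  reads[1:7, ] <- mutate_at(reads[1:7, ], fx$genome, g6, "A")  # G->A == C->T
  sig <- conversion_ratio(reads, fx$genome, fx$site, fx$guide)
  expect_equal(sig$n_signal, 7L)
  expect_equal(sig$ratio, 0.7)
})

test_that("no window-spanning reads reports a missing ratio", {
  fx <- be_fixture("+")
  off_site <- ref_read(fx$genome, 0L, 30L)
  sig <- conversion_ratio(off_site, fx$genome, fx$site, fx$guide)
  expect_equal(sig$n_spanning, 0L)
  expect_true(is.na(sig$ratio))
})

test_that("conversion ratio is invariant under strand involution", {
  fx <- be_fixture("+")
  W <- editing_window_coords(fx$site$cut_pos, "+", fx$guide)
  reads <- do.call(rbind, replicate(12, ref_read(fx$genome, 30L, 130L),
                                    simplify = FALSE))
  reads[1:5, ] <- mutate_at(reads[1:5, ], fx$genome, W[["6"]], "T")
  G <- unname(contig_lengths(fx$genome)[1])
  flipped_genome <- genome_index(c(chr1 = crossseq_revcomp(
    fx$genome$seqs[["chr1"]])))
  flipped_reads <- data.frame(
    chrom = "chr1",
    start = G - reads$end, end = G - reads$start,
    strand = ifelse(reads$strand == "+", "-", "+"),
    cigar = reads$cigar,  # pure-match CIGARs are palindromic
    seq = crossseq_revcomp(reads$seq), mapq = reads$mapq,
    stringsAsFactors = FALSE)
  flipped_site <- list(chrom = "chr1", cut_pos = G - fx$site$cut_pos,
                       orientation = "-")
  a <- conversion_ratio(reads, fx$genome, fx$site, fx$guide)
  b <- conversion_ratio(flipped_reads, flipped_genome, flipped_site, fx$guide)
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$n_spanning, b$n_spanning)
})

pe_fixture <- function(orientation = "+") {
  guide <- test_guide("pe", pe_insert = "CTT")
  flank <- strrep("A", 60)
  site_fwd <- if (orientation == "+") paste0(guide$spacer, "TGG") else
    crossseq_revcomp(paste0(guide$spacer, "TGG"))
  genome <- genome_index(c(chr1 = paste0(flank, site_fwd, flank)))
  ps <- if (orientation == "+") 60L else 63L
  cut <- site_cut_pos(ps, orientation, guide)
  list(guide = guide, genome = genome,
       site = list(chrom = "chr1", cut_pos = cut, orientation = orientation))
}

ins_read <- function(genome, start, end, nick, ins) {
  left <- nick - start
  seq <- fetch_seq(genome, "chr1", start, end)
  data.frame(chrom = "chr1", start = start, end = end, strand = "+",
             cigar = paste0(left, "M", nchar(ins), "I", end - nick, "M"),
             seq = paste0(substr(seq, 1, left), ins, substring(seq, left + 1)),
             mapq = 60L, stringsAsFactors = FALSE)
}

test_that("insertion fraction requires the exact insert at +1", {
  fx <- pe_fixture("+")
  nick <- fx$site$cut_pos
  plain <- do.call(rbind, replicate(3, ref_read(fx$genome, 20L, 120L),
                                    simplify = FALSE))
  with_ins <- do.call(rbind, replicate(
    7, ins_read(fx$genome, 20L, 120L, nick, "CTT"), simplify = FALSE))
  sig <- insertion_fraction(rbind(plain, with_ins), fx$site, fx$guide)
  expect_equal(sig$n_spanning, 10L)
  expect_equal(sig$ratio, 0.7)

  # wrong inserted bases are not signal
  wrong <- ins_read(fx$genome, 20L, 120L, nick, "CTA")
  sig_w <- insertion_fraction(rbind(plain, wrong), fx$site, fx$guide)
  expect_equal(sig_w$n_signal, 0L)

  # displaced insertion is not signal at tolerance 0 but is at 2
  shifted <- ins_read(fx$genome, 20L, 120L, nick + 2L, "CTT")
  expect_equal(insertion_fraction(rbind(plain, shifted), fx$site,
                                  fx$guide)$n_signal, 0L)
  expect_equal(insertion_fraction(rbind(plain, shifted), fx$site, fx$guide,
                                  tolerance = 2L)$n_signal, 1L)

  # no insertion-bearing reads -> ratio 0
  expect_equal(insertion_fraction(plain, fx$site, fx$guide)$ratio, 0)
})

test_that("minus-oriented PE sites expect the reverse-complement insert", {
  fx <- pe_fixture("-")
  nick <- fx$site$cut_pos
  ok <- ins_read(fx$genome, 20L, 140L, nick, "AAG")   # revcomp(CTT)
  wrong <- ins_read(fx$genome, 20L, 140L, nick, "CTT")
  expect_equal(insertion_fraction(ok, fx$site, fx$guide)$n_signal, 1L)
  expect_equal(insertion_fraction(wrong, fx$site, fx$guide)$n_signal, 0L)
})

test_that("signature functions enforce the guide's editor mode", {
  fx <- be_fixture("+")
  nuc <- test_guide("nuclease")
  reads <- ref_read(fx$genome, 30L, 130L)
  expect_error(conversion_ratio(reads, fx$genome, fx$site, nuc), "cbe/abe")
  expect_error(insertion_fraction(reads, fx$site, fx$guide), "pe guide")
  no_ori <- list(chrom = "chr1", cut_pos = fx$site$cut_pos, orientation = NA)
  expect_error(conversion_ratio(reads, fx$genome, no_ori, fx$guide),
               "orientation")
})

test_that("simulated editor signals are recovered within binomial error", {
  for (mode in c("abe", "pe")) {
    guide <- if (mode == "pe") test_guide("pe", pe_insert = "CTT") else
      test_guide(mode)
    cfg <- sim_config(seed = 401, genome_length = 20000, n_offtargets = 0,
                      planted_bulges = 0, mean_depth = 200,
                      conversion_fraction = 0.3, insertion_fraction = 0.5)
    sim <- simulate_experiment(guide, cfg)
    st <- as.list(sim$sites[1, c("chrom", "cut_pos", "orientation")])
    planted <- if (mode == "pe") 0.5 else 0.3
    sig <- if (mode == "pe") {
      insertion_fraction(sim$treated, st, guide)
    } else {
      conversion_ratio(sim$treated, sim$genome, st, guide)
    }
    sd3 <- 3 * sqrt(planted * (1 - planted) / sig$n_spanning)
    expect_gt(sig$n_spanning, 60)
    expect_lt(abs(sig$ratio - planted), sd3)
    # the matched no-guide control carries no editing signal
    ctrl_sig <- if (mode == "pe") {
      insertion_fraction(sim$control, st, guide)
    } else {
      conversion_ratio(sim$control, sim$genome, st, guide)
    }
    expect_equal(ctrl_sig$n_signal, 0L)
  }
})

test_that("score_site_by_mode combines gates with the editing ratio", {
  guide <- test_guide("abe")
  cfg <- sim_config(seed = 411, genome_length = 20000, n_offtargets = 0,
                    planted_bulges = 0, mean_depth = 150,
                    conversion_fraction = 0.3)
  sim <- simulate_experiment(guide, cfg)
  pile <- build_end_pileup(sim$treated, contig_lengths(sim$genome))
  st <- as.list(sim$sites[1, c("chrom", "cut_pos", "orientation")])
  rec <- score_site_by_mode(st, pile, sim$treated, sim$genome, guide)
  expect_equal(rec$mode, "abe")
  expect_true(rec$candidate)
  expect_gt(rec$ratio, 0.1)
  expect_gt(rec$cross_score, 0)
})
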