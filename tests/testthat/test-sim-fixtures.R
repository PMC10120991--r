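# Simulator: determinism, composition, planted ground truth, read signatures.

test_that("genome simulation is deterministic and honours composition", {
  cfg <- sim_config(seed = 11, genome_length = 10000, mean_depth = 60)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(unname(contig_lengths(g1)[1]), 10000L)

  gc1 <- simulate_genome(sim_config(seed = 2, genome_length = 10000,
                                    gc_fraction = 1))
  expect_false(grepl("[AT]", gc1$seqs[["chr1"]]))

  # observed GC within 3 binomial SDs of the requested fraction
  cfg_gc <- sim_config(seed = 5, genome_length = 100000, gc_fraction = 0.41)
  g <- simulate_genome(cfg_gc)
  n_gc <- sum(strsplit(g$seqs[["chr1"]], "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(100000 * 0.41 * 0.59)
  expect_lt(abs(n_gc - 100000 * 0.41), sd3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(sim_config(genome_length = 100), "50 x read_length")
  expect_error(sim_config(cleavage_fraction = -0.1), "cleavage_fraction")
  expect_error(sim_config(n_offtargets = 1, planted_bulges = 2),
               "planted_bulges")
})

test_that("plant_sites writes ground truth consistent with the genome", {
  guide <- test_guide()
  cfg <- sim_config(seed = 21, genome_length = 50000, n_offtargets = 4,
                    planted_bulges = 1, mismatch_range = c(2, 2))
  pl <- plant_sites(simulate_genome(cfg), guide, cfg)
  st <- pl$sites
  expect_equal(nrow(st), 5L)
  expect_equal(st$site_id[1], "on_target")
  expect_equal(st$n_mismatches[1], 0L)
  expect_true(all(st$n_mismatches[-1] == 2L))
  expect_equal(sum(st$target_len != nchar(guide$spacer)), 1L)

  # target_seq (protospacer + PAM, site orientation) matches the genome
  for (i in seq_len(nrow(st))) {
    tl <- st$target_len[i]; pl_len <- nchar(guide$pam)
    if (st$orientation[i] == "+") {
      got <- fetch_seq(pl$genome, st$chrom[i], st$protospacer_start[i],
                       st$protospacer_start[i] + tl + pl_len)
    } else {
      fwd <- fetch_seq(pl$genome, st$chrom[i],
                       st$protospacer_start[i] - pl_len,
                       st$protospacer_start[i] + tl)
      got <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(fwd)))
    }
    expect_identical(got, st$target_seq[i])
  }

  # cut geometry: 3 bp 5' of the PAM
  for (i in seq_len(nrow(st))) {
    expected <- site_cut_pos(st$protospacer_start[i], st$orientation[i],
                             guide, st$target_len[i])
    expect_identical(st$cut_pos[i], expected)
  }
})

test_that("a single exact site is planted when n_offtargets = 0", {
  guide <- test_guide()
  cfg <- sim_config(seed = 3, genome_length = 20000, n_offtargets = 0,
                    planted_bulges = 0)
  pl <- plant_sites(simulate_genome(cfg), guide, cfg)
  expect_equal(nrow(pl$sites), 1L)
  expect_equal(pl$sites$n_mismatches, 0L)
  expect_equal(pl$sites$bulge, "none")
})

test_that("read simulation is deterministic and conserves reads in bounds", {
  guide <- test_guide()
  cfg <- sim_config(seed = 31, genome_length = 20000, n_offtargets = 1,
                    planted_bulges = 0, mean_depth = 50)
  s1 <- simulate_experiment(guide, cfg)
  s2 <- simulate_experiment(guide, cfg)
  expect_identical(s1$treated, s2$treated)
  expect_identical(s1$control, s2$control)

  G <- unname(contig_lengths(s1$genome)[1])
  L <- cfg$read_length
  n_bg <- round(G * cfg$mean_depth / L)
  n_hot <- cfg$n_hotspots *
    round((cfg$hotspot_fold - 1) * cfg$mean_depth * cfg$hotspot_width / L)
  expect_equal(nrow(s1$treated), n_bg + n_hot)
  expect_true(all(s1$treated$start >= 0 & s1$treated$end <= G))
  expect_true(all(s1$treated$start < s1$treated$end))
  # query sequence length always matches the aligned span for pure-match CIGARs
  m_only <- grepl("^\\d+M$", s1$treated$cigar)
  expect_true(all(nchar(s1$treated$seq[m_only]) ==
                  (s1$treated$end - s1$treated$start)[m_only]))
})

test_that("saturating cleavage re-anchors every cut-covering read", {
  guide <- test_guide()
  cfg <- sim_config(seed = 41, genome_length = 20000, n_offtargets = 0,
                    planted_bulges = 0, mean_depth = 100,
                    cleavage_fraction = 1)
  sim <- simulate_experiment(guide, cfg)
  cut <- sim$sites$cut_pos[1]
  over <- sim$treated[sim$treated$start <= cut & sim$treated$end > cut, ]
  expect_gt(nrow(over), 0)
  expect_true(all(over$start == cut))   # only reads starting at the cut remain
  # reverse-strand products end exactly at the cut
  rev_ends <- sim$treated$strand == "-" & sim$treated$end == cut
  expect_gt(sum(rev_ends), 0)
})

test_that("null cleavage leaves treated and control exchangeable at the cut", {
  guide <- test_guide()
  cfg <- sim_config(seed = 51, genome_length = 20000, n_offtargets = 0,
                    planted_bulges = 0, mean_depth = 100,
                    cleavage_fraction = 0)
  sim <- simulate_experiment(guide, cfg)
  cut <- sim$sites$cut_pos[1]
  # expected background start rate per strand per position
  G <- unname(contig_lengths(sim$genome)[1])
  mu <- nrow(sim$treated) / (2 * G)
  for (rd in list(sim$treated, sim$control)) {
    F_ <- sum(rd$start == cut & rd$strand == "+")
    expect_lt(abs(F_ - mu), 3 * sqrt(mu) + 1)
  }
})

test_that("planted end fractions are recoverable within binomial error", {
  guide <- test_guide()
  cfg <- sim_config(seed = 61, genome_length = 50000, n_offtargets = 2,
                    planted_bulges = 0, mean_depth = 150)
  sim <- simulate_experiment(guide, cfg)
  pile <- build_end_pileup(sim$treated, contig_lengths(sim$genome))
  for (i in seq_len(nrow(sim$sites))) {
    cut <- sim$sites$cut_pos[i]
    tf <- truncation_fraction(pile, "chr1", cut, "+")
    d <- pile$contigs$chr1$depth_fwd[cut + 1L]
    sd3 <- 3 * sqrt(cfg$cleavage_fraction * (1 - cfg$cleavage_fraction) / d)
    # small upward allowance: background starts also land on the position
    expect_lt(abs(tf - cfg$cleavage_fraction), sd3 + 0.05)
  }
})

test_that("planted conversions appear at the configured rate", {
  guide <- test_guide("abe")
  cfg <- sim_config(seed = 71, genome_length = 20000, n_offtargets = 0,
                    planted_bulges = 0, mean_depth = 200,
                    conversion_fraction = 0.3)
  sim <- simulate_experiment(guide, cfg)
  st <- sim$sites[1, ]
  W <- editing_window_coords(st$cut_pos, st$orientation, guide)
  src_fwd <- if (st$orientation == "+") "A" else "T"
  conv_pos <- W[vapply(W, function(g)
    fetch_seq(sim$genome, "chr1", g, g + 1L) == src_fwd, logical(1))]
  expect_gt(length(conv_pos), 0)  # this spacer has an A in its window
  span <- sim$treated[sim$treated$start <= min(W) &
                      sim$treated$end >= max(W) + 1L, ]
  # independent direct count: a read is converted if its base differs
  # from the reference at any editable window position
  converted <- vapply(seq_len(nrow(span)), function(j) {
    any(vapply(conv_pos, function(g) {
      off <- g - span$start[j] + 1L
      substr(span$seq[j], off, off) !=
        fetch_seq(sim$genome, "chr1", g, g + 1L)
    }, logical(1)))
  }, logical(1))
  n <- nrow(span)
  sd3 <- 3 * sqrt(n * 0.3 * 0.7)
  expect_lt(abs(sum(converted) - n * 0.3), sd3)
})
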