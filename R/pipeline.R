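# End-to-end orchestration: simulate -> score -> match -> report, plus
# the YAML run configuration shared with the command-line wrapper in
# inst/scripts/crossseq.

#' @noRd
known_config_keys <- list(
  top = c("treated", "control", "genome", "outdir", "guide", "caller",
          "sim", "seed", "allow_no_control"),
  guide = c("spacer", "pam", "cut_offset", "editor_mode", "editing_window",
            "pe_insert", "nick_strand"),
  caller = c("m", "f_min", "c_max", "ratio_min", "merge_window",
             "require_bidirectional", "r_min", "pe_tolerance", "min_mapq",
             "dedup"),
  sim = c("seed", "genome_length", "gc_fraction", "n_offtargets",
          "mismatch_range", "mismatch_positions", "planted_bulges",
          "read_length", "mean_depth", "cleavage_fraction",
          "conversion_fraction", "insertion_fraction", "background_end_rate",
          "control_included", "n_hotspots", "hotspot_fold", "hotspot_width"))

#' @noRd
reject_unknown_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with a message naming the key.
#'
#' @param path YAML file with sections `guide`, `caller`, `sim` and
#'   top-level `treated`, `control`, `genome`, `outdir`, `seed`.
#' @return Validated list of class `run_config` with `guide`
#'   ([guide_spec()]), `caller` ([caller_params()]) and `sim`
#'   ([sim_config()]) materialised.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname load_run_config
#' @param raw A configuration list (as parsed from YAML).
#' @export
as_run_config <- function(raw) {
  reject_unknown_keys(raw, known_config_keys$top, "config")
  out <- raw
  if (!is.null(raw$guide)) {
    reject_unknown_keys(raw$guide, known_config_keys$guide, "guide")
    out$guide <- do.call(guide_spec, raw$guide)
  }
  if (!is.null(raw$caller)) {
    reject_unknown_keys(raw$caller, known_config_keys$caller, "caller")
    out$caller <- do.call(caller_params, raw$caller)
  } else {
    out$caller <- caller_params()
  }
  if (!is.null(raw$sim)) {
    reject_unknown_keys(raw$sim, known_config_keys$sim, "sim")
    if (is.null(raw$sim$seed) && !is.null(raw$seed)) raw$sim$seed <- raw$seed
    out$sim <- do.call(sim_config, raw$sim)
  }
  class(out) <- "run_config"
  out
}

#' Annotate candidate sites with guide alignments and labeling check
#'
#' For each site, fetches the genomic context around the cut, runs
#' [align_guide()] in both orientations, and adds the target sequence,
#' mismatch/bulge annotation, orientation and the guanine count on the
#' labeled (non-target) strand. Sites without any guide alignment near
#' the cut are kept and reported unmatched, so guide-independent
#' background remains visible.
#'
#' @param sites Site table from [scan_genome()].
#' @param genome A `genome_index`.
#' @param guide A [guide_spec()].
#' @param max_mm,max_bulge Alignment search limits (see [align_guide()]).
#' @return The site table with columns `target_seq`, `n_mismatches`,
#'   `bulge`, `bulge_pos`, `orientation`, `alignment_string`, `g_count`,
#'   `labelable` added, plus an `alignments` attribute holding the
#'   `guide_alignment` objects (NULL where unmatched).
#' @export
annotate_sites <- function(sites, genome, guide, max_mm = 6L, max_bulge = 1L) {
  n <- nrow(sites)
  ctx_half <- nchar(guide$spacer) + nchar(guide$pam) + 2L
  als <- vector("list", n)
  cols <- data.frame(target_seq = rep(NA_character_, n),
                     n_mismatches = rep(NA_integer_, n),
                     bulge = rep(NA_character_, n),
                     bulge_pos = rep(NA_integer_, n),
                     orientation = rep(NA_character_, n),
                     alignment_string = rep(NA_character_, n),
                     g_count = rep(NA_integer_, n),
                     labelable = rep(NA, n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    len <- contig_lengths(genome)[[sites$chrom[i]]]
    lo <- max(0L, sites$cut_pos[i] - ctx_half)
    hi <- min(len, sites$cut_pos[i] + ctx_half)
    ctx <- fetch_seq(genome, sites$chrom[i], lo, hi)
    al <- align_guide(ctx, guide, max_mm = max_mm, max_bulge = max_bulge,
                      cut_at = sites$cut_pos[i] - lo)
    als[[i]] <- al
    if (!is.null(al)) {
      cols$target_seq[i] <- al$target_seq
      cols$n_mismatches[i] <- al$n_mismatches
      cols$bulge[i] <- al$bulge_type
      cols$bulge_pos[i] <- al$bulge_pos
      cols$orientation[i] <- al$orientation
      cols$alignment_string[i] <- gsub("\n", ";", al$alignment_string)
      gc <- g_content(al$target_seq, "+")
      cols$g_count[i] <- gc$g_count
      cols$labelable[i] <- gc$labelable
    }
  }
  out <- cbind(sites, cols)
  attr(out, "alignments") <- als
  out
}

#' Run the full off-target calling pipeline
#'
#' Reads treated and control alignments, builds end pileups, scans for
#' candidate cleavage sites, annotates them against the guide, adds
#' editor-mode signals where applicable, and writes a ranked TSV report,
#' BED, per-strand end-count bedGraph tracks and a JSON run manifest
#' under `outdir`. A run with zero candidates is a success.
#'
#' @param config A `run_config` (or path to a YAML file). The no-guide
#'   control is integral to the method; omitting it is an error unless
#'   `allow_no_control: true` is set, which compares the treated sample
#'   against an empty control and warns prominently.
#' @return The annotated site table, invisibly; side effect: files under
#'   `outdir` (`sites.tsv`, `sites.bed`, `ends_fwd.bedGraph`,
#'   `ends_rev.bedGraph`, `manifest.json`).
#' @export
run_call <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$guide)) stop("config must include a guide section", call. = FALSE)
  if (is.null(config$treated) || is.null(config$genome) || is.null(config$outdir)) {
    stop("config must name treated, genome and outdir", call. = FALSE)
  }
  guide <- config$guide
  params <- config$caller
  genome <- genome_index_fasta(config$genome)
  lens <- contig_lengths(genome)

  treated_reads <- read_alignments(config$treated,
                                   min_mapq = params$min_mapq,
                                   dedup = params$dedup)
  if (is.null(config$control)) {
    if (!isTRUE(config$allow_no_control)) {
      stop("no control alignments given; the no-guide control is integral ",
           "to background subtraction (set allow_no_control: true to ",
           "proceed without one)", call. = FALSE)
    }
    warning("running WITHOUT a no-guide control: endogenous ssDNA ",
            "background cannot be subtracted", call. = FALSE)
    control_reads <- treated_reads[0, , drop = FALSE]
  } else {
    control_reads <- read_alignments(config$control,
                                     min_mapq = params$min_mapq,
                                     dedup = params$dedup)
  }

  treated <- build_end_pileup(treated_reads, lens)
  control <- build_end_pileup(control_reads, lens)
  sites <- scan_genome(treated, control, params)
  sites <- annotate_sites(sites, genome, guide)

  if (guide$editor_mode != "nuclease" && nrow(sites)) {
    extra <- data.frame(mode = guide$editor_mode,
                        n_spanning = NA_integer_, n_signal = NA_integer_,
                        ratio = NA_real_, stringsAsFactors = FALSE)
    extra <- extra[rep(1L, nrow(sites)), , drop = FALSE]
    per_pos <- vector("list", nrow(sites))
    keep <- rep(TRUE, nrow(sites))
    for (i in seq_len(nrow(sites))) {
      if (is.na(sites$orientation[i])) next  # unmatched: no editor signal
      rec <- score_site_by_mode(sites[i, ], treated, treated_reads, genome,
                                guide, params)
      extra$n_spanning[i] <- rec$n_spanning
      extra$n_signal[i] <- rec$n_signal
      extra$ratio[i] <- rec$ratio
      per_pos[[i]] <- rec$per_position
      keep[i] <- isTRUE(rec$candidate)
    }
    extra$per_position_counts <- I(per_pos)
    sites <- cbind(sites, extra)
    sites <- sites[keep | is.na(sites$orientation), , drop = FALSE]
    if (nrow(sites)) {
      sites$rank <- dense_rank_desc(sites$cross_score)
    }
    rownames(sites) <- NULL
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_sites(sites, file.path(config$outdir, "sites.tsv"), "tsv")
  write_sites(sites, file.path(config$outdir, "sites.bed"), "bed")
  write_end_bedgraph(treated, file.path(config$outdir, "ends_fwd.bedGraph"), "+")
  write_end_bedgraph(treated, file.path(config$outdir, "ends_rev.bedGraph"), "-")
  manifest <- list(
    tool = "crossseq",
    version = as.character(utils::packageVersion("crossseq")),
    config = strip_classes(config),
    library_sizes = list(treated = treated$total_mapped,
                         control = control$total_mapped),
    n_candidates = nrow(sites))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(sites)
}

#' @noRd
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Export per-position read-end counts as bedGraph
#'
#' @param pileup An `end_pileup`.
#' @param path Output path.
#' @param strand `"+"` for forward-strand start counts, `"-"` for
#'   reverse-strand end counts.
#' @return `path`, invisibly.
#' @export
write_end_bedgraph <- function(pileup, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  rows <- lapply(names(pileup$contigs), function(cn) {
    ct <- pileup$contigs[[cn]]
    v <- if (strand == "+") ct$fwd_starts else ct$rev_ends
    pos <- which(v > 0L) - 1L
    if (!length(pos)) return(NULL)
    GenomicRanges::GRanges(cn, IRanges::IRanges(pos + 1L, pos + 1L),
                           score = v[pos + 1L])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- do.call(c, rows)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Generate a simulated fixture directory
#'
#' Writes the planted reference (FASTA + index), treated and control
#' alignments (SAM and sorted/indexed BAM), the ground-truth site table
#' and a manifest.
#'
#' @param config A `run_config` with a `sim` section and `outdir`
#'   (or a path to such a YAML file), or a bare [sim_config()] plus
#'   `outdir`/`guide` arguments.
#' @param outdir Output directory (overrides the config's).
#' @param guide A [guide_spec()] (required if `config` is a bare
#'   `sim_config`).
#' @return List of written paths, invisibly.
#' @export
run_simulate <- function(config, outdir = NULL, guide = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  if (inherits(config, "run_config")) {
    sim_cfg <- config$sim
    guide <- config$guide
    if (is.null(outdir)) outdir <- config$outdir
  } else if (inherits(config, "sim_config")) {
    sim_cfg <- config
  } else {
    stop("config must be a run_config, sim_config or YAML path", call. = FALSE)
  }
  if (is.null(sim_cfg)) stop("no sim section in config", call. = FALSE)
  if (is.null(guide)) stop("a guide is required to plant sites", call. = FALSE)
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_experiment(guide, sim_cfg)
  paths <- list(fasta = file.path(outdir, "genome.fa"),
                treated_sam = file.path(outdir, "treated.sam"),
                control_sam = file.path(outdir, "control.sam"),
                truth = file.path(outdir, "truth.tsv"),
                manifest = file.path(outdir, "manifest.json"))
  write_genome_fasta(sim$genome, paths$fasta)
  lens <- contig_lengths(sim$genome)
  write_sam(sim$treated, paths$treated_sam, lens)
  paths$treated_bam <- Rsamtools::asBam(paths$treated_sam,
                                        file.path(outdir, "treated"),
                                        overwrite = TRUE)
  if (!is.null(sim$control)) {
    write_sam(sim$control, paths$control_sam, lens)
    paths$control_bam <- Rsamtools::asBam(paths$control_sam,
                                          file.path(outdir, "control"),
                                          overwrite = TRUE)
  }
  truth <- sim$sites
  con <- file(paths$truth, "w")
  writeLines(paste0("#", paste(names(truth), collapse = "\t")), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  manifest <- list(tool = "crossseq",
                   version = as.character(utils::packageVersion("crossseq")),
                   sim = strip_classes(sim_cfg),
                   guide = strip_classes(guide),
                   n_treated = nrow(sim$treated),
                   n_control = if (is.null(sim$control)) 0L else nrow(sim$control))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(paths)
}

#' Re-annotate a BED of loci against a guide
#'
#' @param bed Path to a BED file of candidate cut positions (single-base
#'   intervals, as written by [write_sites()]).
#' @param genome_fa Path to the reference FASTA.
#' @param guide A [guide_spec()].
#' @param out Output TSV path.
#' @return Annotated table, invisibly.
#' @export
run_match <- function(bed, genome_fa, guide, out) {
  genome <- genome_index_fasta(genome_fa)
  gr <- rtracklayer::import(bed, format = "BED")
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      cut_pos = BiocGenerics::start(gr) - 1L,
                      stringsAsFactors = FALSE)
  ann <- annotate_sites(sites, genome, guide)
  write_sites(ann, out, "tsv")
  invisible(ann)
}

#' Build a consensus matrix from a site report
#'
#' @param report Path to a `sites.tsv` report (with alignment columns).
#' @param genome_fa Path to the reference FASTA.
#' @param guide A [guide_spec()].
#' @param out Output TSV path for the frequency/information table.
#' @return The `consensus_matrix`, invisibly.
#' @export
run_logo <- function(report, genome_fa, guide, out) {
  df <- read_sites_tsv(report)
  genome <- genome_index_fasta(genome_fa)
  df <- df[!is.na(df$cut_pos), , drop = FALSE]
  ann <- annotate_sites(df[, c("chrom", "cut_pos"), drop = FALSE], genome, guide)
  als <- Filter(Negate(is.null), attr(ann, "alignments"))
  if (!length(als)) stop("no alignable sites in report", call. = FALSE)
  cm <- consensus_matrix(als)
  tab <- data.frame(position = seq_len(ncol(cm$freq)),
                    t(cm$freq),
                    information = cm$information)
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cm)
}
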