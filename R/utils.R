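# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of character DNA sequences (vectorised)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement of single bases / sequences without reversing
#' @noRd
complement_bases <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

#' @noRd
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1], got %s",
                 name, paste(format(x), collapse = ",")), call. = FALSE)
  }
  as.numeric(x)
}

#' @noRd
assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @noRd
assert_dna <- function(x, name, allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single character string", name), call. = FALSE)
  }
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (!grepl(sprintf("^[%s]*$", alphabet), x)) {
    stop(sprintf("'%s' contains symbols outside {%s}", name,
                 paste(strsplit(alphabet, "")[[1]], collapse = ",")), call. = FALSE)
  }
  x
}

#' Hamming distance between equal-length strings
#' @noRd
hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

#' Parse a CIGAR string into (op, length) vectors
#' @noRd
parse_cigar <- function(cigar) {
  if (cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(0), len = integer(0)))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' Reference-space width of a CIGAR
#' @noRd
cigar_ref_width <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

#' Query offset (1-based) corresponding to a 0-based reference position, or NA
#' if the position falls in a deletion or outside the aligned span.
#' @noRd
query_offset_at <- function(cigar, read_start, gpos) {
  cg <- parse_cigar(cigar)
  ref <- read_start   # 0-based cursor on the reference
  q <- 0L             # query bases consumed
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (gpos >= ref && gpos < ref + len) return(q + (gpos - ref) + 1L)
      ref <- ref + len; q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (gpos >= ref && gpos < ref + len) return(NA_integer_)
      ref <- ref + len
    }
  }
  NA_integer_
}

#' Dense 1-based ranks for a vector sorted in descending order
#' @noRd
dense_rank_desc <- function(x) {
  u <- sort(unique(x), decreasing = TRUE)
  match(x, u)
}
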