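#' Guide specification
#'
#' Bundles the guide RNA spacer, PAM pattern, cut geometry and editor mode
#' that drive every scorer in the pipeline. Protospacer positions are
#' numbered 1..length(spacer) with position 1 at the PAM-distal end, the
#' convention used for base-editor editing windows.
#'
#' @param spacer Spacer sequence, 5'->3', as DNA (A/C/G/T), 15-25 nt.
#'   Typically 20 nt for SpCas9.
#' @param pam PAM pattern in IUPAC codes, 3' of the protospacer
#'   (default `"NGG"` for SpCas9).
#' @param cut_offset Signed offset of the cut/nick from the PAM-proximal end
#'   of the spacer, in bases. `-3` models the canonical SpCas9 blunt cut
#'   between protospacer positions 17 and 18.
#' @param editor_mode One of `"nuclease"`, `"cbe"`, `"abe"`, `"pe"`.
#' @param editing_window Inclusive protospacer position range where a base
#'   editor deaminates efficiently (PAM-distal position = 1). Default 4-8.
#' @param pe_insert Programmed insertion sequence expected at the +1 position
#'   after the nick (prime editing). Must be non-empty iff
#'   `editor_mode = "pe"`.
#' @param nick_strand Which strand the nickase cuts: `"target"` (D10A, used
#'   in BE3/BE4max-style editors) or `"nontarget"` (H840A, used in prime
#'   editors). Defaults follow the editor mode.
#'
#' @return An object of class `guide_spec`. The conversion assayed in BE
#'   modes is fixed by the mode: C->T for CBE and A->G for ABE, as observed
#'   on the non-target strand.
#' @examples
#' g <- guide_spec("GGTGACTTTAGCCATGGCAA", editor_mode = "nuclease")
#' g$cut_offset
#' @export
guide_spec <- function(spacer,
                       pam = "NGG",
                       cut_offset = -3L,
                       editor_mode = c("nuclease", "cbe", "abe", "pe"),
                       editing_window = c(4L, 8L),
                       pe_insert = "",
                       nick_strand = NULL) {
  spacer <- assert_dna(spacer, "spacer")
  if (nchar(spacer) < 15L || nchar(spacer) > 25L) {
    stop("spacer length must be 15-25 nt, got ", nchar(spacer), call. = FALSE)
  }
  editor_mode <- match.arg(editor_mode)
  pam <- toupper(pam)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!nzchar(pam) || !all(strsplit(pam, "")[[1]] %in% iupac)) {
    stop("pam must be a non-empty IUPAC pattern, got '", pam, "'", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset >= 0L || -cut_offset >= nchar(spacer)) {
    stop("cut_offset must be a negative offset within the spacer", call. = FALSE)
  }
  editing_window <- as.integer(editing_window)
  if (length(editing_window) != 2L || any(is.na(editing_window)) ||
      editing_window[1] > editing_window[2] ||
      editing_window[1] < 1L || editing_window[2] > nchar(spacer)) {
    stop("editing_window must be an inclusive position pair within [1, ",
         nchar(spacer), "]", call. = FALSE)
  }
  if (editor_mode == "pe") {
    pe_insert <- assert_dna(pe_insert, "pe_insert")
    if (!nzchar(pe_insert)) stop("pe_insert must be non-empty in pe mode", call. = FALSE)
  } else if (nzchar(pe_insert)) {
    stop("pe_insert is only meaningful when editor_mode = 'pe'", call. = FALSE)
  }
  if (is.null(nick_strand)) {
    nick_strand <- switch(editor_mode, cbe = , abe = "target",
                          pe = "nontarget", nuclease = "both")
  }
  nick_strand <- match.arg(nick_strand, c("target", "nontarget", "both"))
  conversion <- switch(editor_mode,
                       cbe = c(from = "C", to = "T"),
                       abe = c(from = "A", to = "G"),
                       NULL)
  structure(
    list(spacer = spacer, pam = pam, cut_offset = cut_offset,
         editor_mode = editor_mode, editing_window = editing_window,
         conversion = conversion, pe_insert = pe_insert,
         nick_strand = nick_strand),
    class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("guide_spec:", x$spacer, "+", x$pam, "\n")
  cat("  mode:", x$editor_mode,
      "| cut offset:", x$cut_offset, "\n")
  if (!is.null(x$conversion)) {
    cat("  conversion:", x$conversion[["from"]], "->", x$conversion[["to"]],
        "in window", paste(x$editing_window, collapse = "-"), "\n")
  }
  if (nzchar(x$pe_insert)) cat("  pe insert at +1:", x$pe_insert, "\n")
  invisible(x)
}

#' Cut position implied by a protospacer placement
#'
#' Coordinates are 0-based; the cut falls between `cut_pos - 1` and
#' `cut_pos`. For a `+`-oriented site the protospacer occupies
#' `[protospacer_start, protospacer_start + len)` with the PAM to its right;
#' for a `-`-oriented site the PAM lies to the left on the forward strand.
#' A blunt cut has the same duplex coordinate for either orientation.
#'
#' @param protospacer_start 0-based forward-strand start of the protospacer.
#' @param orientation `"+"` or `"-"` (strand carrying the protospacer as
#'   spacer-equivalent sequence).
#' @param guide A [guide_spec()].
#' @param target_len Protospacer length on the genome (differs from the
#'   spacer length by one for bulged sites). Default: spacer length.
#' @return 0-based cut position.
#' @export
site_cut_pos <- function(protospacer_start, orientation, guide,
                         target_len = nchar(guide$spacer)) {
  if (orientation == "+") {
    protospacer_start + target_len + guide$cut_offset
  } else {
    protospacer_start - guide$cut_offset
  }
}

#' Protospacer start implied by a cut position (ungapped geometry)
#' @inheritParams site_cut_pos
#' @param cut_pos 0-based cut position.
#' @return 0-based forward-strand protospacer start.
#' @export
protospacer_start_from_cut <- function(cut_pos, orientation, guide) {
  if (orientation == "+") {
    cut_pos - nchar(guide$spacer) - guide$cut_offset
  } else {
    cut_pos + guide$cut_offset
  }
}

#' Forward-strand genomic coordinates of editing-window positions
#'
#' @inheritParams site_cut_pos
#' @param cut_pos 0-based cut position of the site.
#' @return Integer vector of 0-based forward-strand coordinates, named by
#'   protospacer position.
#' @export
editing_window_coords <- function(cut_pos, orientation, guide) {
  ps <- protospacer_start_from_cut(cut_pos, orientation, guide)
  w <- seq(guide$editing_window[1], guide$editing_window[2])
  g <- if (orientation == "+") ps + w - 1L else ps + nchar(guide$spacer) - w
  stats::setNames(as.integer(g), w)
}
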