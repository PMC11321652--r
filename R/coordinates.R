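#' Amplicon reference with protospacer coordinate system
#'
#' Defines the coordinate system used throughout the package: protospacer
#' positions are 1-based on the protospacer (sgRNA-matching) strand, the PAM
#' occupies positions 21-23, and bases 5' of position 1 are numbered -1, -2,
#' ... with no position 0. All edit calls are reported on the protospacer
#' strand regardless of amplicon orientation.
#'
#' @param reference Amplicon DNA string (A/C/G/T/N).
#' @param protospacer_offset 0-based index of protospacer position 1 on the
#'   protospacer strand (for `strand = "reverse"` the protospacer strand is
#'   the reverse complement of `reference`).
#' @param strand `"forward"` or `"reverse"`: which strand of `reference`
#'   carries the protospacer.
#' @param protospacer_length Protospacer length in nt (default 20).
#' @param pam Expected 3-nt PAM at positions 21-23. If supplied it is checked
#'   against the reference; if `NULL` it is read off the reference.
#' @return An object of class `protospacer_spec`.
#' @examples
#' spec <- protospacer_spec(
#'   paste0("GATCC", strrep("CT", 5), "ACGTACCAGCTGCTGCTGCT", "CGG", "TTGCA"),
#'   protospacer_offset = 15
#' )
#' proto_base(spec, c(1, 5, 8))
#' @export
protospacer_spec <- function(reference, protospacer_offset,
                             strand = c("forward", "reverse"),
                             protospacer_length = 20L, pam = NULL) {
  strand <- match.arg(strand)
  reference <- toupper(reference)
  if (!grepl("^[ACGTN]+$", reference)) {
    abort("`reference` may contain only A/C/G/T/N.")
  }
  protospacer_offset <- as.integer(protospacer_offset)
  protospacer_length <- as.integer(protospacer_length)
  L <- nchar(reference)
  if (protospacer_offset < 0L ||
      protospacer_offset + protospacer_length + 3L > L) {
    abort("protospacer plus PAM does not fit inside the reference.")
  }
  strand_seq <- if (strand == "forward") reference else revcomp(reference)
  found_pam <- substr(strand_seq,
                      protospacer_offset + protospacer_length + 1L,
                      protospacer_offset + protospacer_length + 3L)
  if (is.null(pam)) {
    pam <- found_pam
  } else if (!identical(toupper(pam), found_pam)) {
    abort(paste0("declared PAM '", pam, "' does not match reference PAM '",
                 found_pam, "' at protospacer positions 21-23."))
  }
  structure(
    list(reference = reference, strand_seq = strand_seq,
         protospacer_offset = protospacer_offset, strand = strand,
         protospacer_length = protospacer_length, pam = pam),
    class = "protospacer_spec"
  )
}

#' @export
print.protospacer_spec <- function(x, ...) {
  cat("<protospacer_spec> ", nchar(x$reference), " nt amplicon, ",
      x$strand, " strand\n", sep = "")
  cat("  protospacer: ", protospacer_seq(x), "  PAM: ", x$pam, "\n", sep = "")
  invisible(x)
}

#' @rdname protospacer_spec
#' @param spec A `protospacer_spec`.
#' @export
protospacer_seq <- function(spec) {
  substr(spec$strand_seq, spec$protospacer_offset + 1L,
         spec$protospacer_offset + spec$protospacer_length)
}

# protospacer position -> 1-based index on the protospacer strand.
# Positions are 1-based with no zero; -1 abuts +1.
position_index <- function(spec, position) {
  position <- as.integer(position)
  if (any(position == 0L)) abort("protospacer position 0 does not exist.")
  idx <- spec$protospacer_offset + position + ifelse(position < 0L, 1L, 0L)
  if (any(idx < 1L | idx > nchar(spec$strand_seq))) {
    abort("position(s) fall outside the amplicon reference.")
  }
  idx
}

# inverse of position_index for a vector of strand-seq indices
index_position <- function(spec, idx) {
  p <- idx - spec$protospacer_offset
  ifelse(p >= 1L, p, p - 1L)
}

#' Reference base at protospacer positions
#'
#' @param spec A [protospacer_spec()].
#' @param position Integer protospacer positions (negative allowed, no 0).
#' @return Character vector of bases on the protospacer strand.
#' @export
proto_base <- function(spec, position) {
  idx <- position_index(spec, position)
  substring(spec$strand_seq, idx, idx)
}

# integer positions covered by a window c(lo, hi), skipping 0
window_positions <- function(window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2]) {
    abort("`window` must be c(lo, hi) with lo <= hi.")
  }
  setdiff(seq(window[1], window[2]), 0L)
}

#' View an aligned segment in protospacer coordinates
#'
#' Extracts bases from a read segment (given in reference orientation and
#' reference coordinates) keyed by protospacer position, on the protospacer
#' strand. Reverse-strand specs are reverse-complemented exactly once, here;
#' no other function in the package touches strand.
#'
#' @param spec A [protospacer_spec()].
#' @param segment DNA string aligned to the reference (reference orientation).
#' @param positions Protospacer positions to report (default the protospacer,
#'   1..protospacer_length).
#' @param segment_start 1-based reference coordinate of `segment`'s first base.
#' @return A tibble with columns `position` and `base`.
#' @export
protospacer_view <- function(spec, segment,
                             positions = seq_len(spec$protospacer_length),
                             segment_start = 1L) {
  segment <- toupper(segment)
  positions <- as.integer(positions)
  idx <- position_index(spec, positions)
  L <- nchar(spec$reference)
  ref_idx <- if (spec$strand == "forward") idx else L - idx + 1L
  seg_idx <- ref_idx - segment_start + 1L
  if (any(seg_idx < 1L | seg_idx > nchar(segment))) {
    abort("segment does not cover the requested protospacer positions.")
  }
  base <- substring(segment, seg_idx, seg_idx)
  if (spec$strand == "reverse") base <- complement_base(base)
  tibble(position = positions, base = base)
}
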