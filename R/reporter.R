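# The stop-codon EGFP reporter: a short insert between the start codon and
# the EGFP coding sequence carries an in-frame premature stop whose adenine
# sits inside the protospacer. A-to-G conversion of that adenine (TGA -> TGG,
# Trp) removes the stop and switches EGFP on; that is the selection readout
# the sort-seq screen is built on.

REPORTER_INSERT <- "ATCGTGTGACTGGTCCTCGTGCTGGTC"  # 27 nt, TGA at codon 3
REPORTER_UPSTREAM <- "GGCACTGAGG"
REPORTER_EGFP_HEAD <- "GTGAGCAAGGGCGAGGAGCT"

#' Stop-codon EGFP reporter construct
#'
#' @param insert Insert DNA placed between the start codon and the EGFP CDS;
#'   length must be a multiple of 3 when `frame_offset = 0` so EGFP stays in
#'   frame. Default: the bundled 27-nt insert with an in-frame TGA whose
#'   editable adenine is protospacer position +7.
#' @param protospacer_offset_in_insert 0-based offset of protospacer position
#'   1 within the insert (default 2).
#' @param upstream Sequence 5' of the start codon in the amplicon reference.
#' @param egfp_head First bases of the EGFP CDS included in the reference.
#' @param frame_offset Phase of the insert relative to the ATG (only 0 is
#'   currently meaningful; kept explicit because the invariants depend on it).
#' @return An object of class `reporter_construct`, with the amplicon-level
#'   [protospacer_spec()] in `$spec`.
#' @export
reporter_construct <- function(insert = REPORTER_INSERT,
                               protospacer_offset_in_insert = 2L,
                               upstream = REPORTER_UPSTREAM,
                               egfp_head = REPORTER_EGFP_HEAD,
                               frame_offset = 0L) {
  insert <- toupper(insert)
  if (frame_offset == 0L && nchar(insert) %% 3L != 0L) {
    abort("insert length must be a multiple of 3 when frame_offset is 0.")
  }
  reference <- paste0(upstream, "ATG", insert, egfp_head)
  insert_start <- nchar(upstream) + 4L  # 1-based reference coord of insert
  spec <- protospacer_spec(
    reference,
    protospacer_offset = insert_start - 1L + protospacer_offset_in_insert,
    strand = "forward")
  construct <- structure(
    list(insert = insert, insert_start = insert_start,
         insert_offset = as.integer(protospacer_offset_in_insert),
         frame_offset = as.integer(frame_offset), spec = spec),
    class = "reporter_construct")
  if (!"off" %in% egfp_state(construct, NULL)) {
    abort("unedited insert must contain an in-frame stop codon (defective EGFP).")
  }
  construct
}

# protospacer position -> 1-based position within the insert
proto_to_insert <- function(construct, position) {
  position <- as.integer(position)
  if (any(position == 0L)) abort("protospacer position 0 does not exist.")
  construct$insert_offset + position + ifelse(position < 0L, 1L, 0L)
}

#' EGFP on/off state of an edited reporter
#'
#' Applies substitution edits to the insert and reads it in frame from the
#' ATG: EGFP is `"on"` iff no stop codon remains before the EGFP coding
#' sequence and the insert length is still a multiple of 3.
#'
#' @param construct A [reporter_construct()].
#' @param edits A data frame with columns `position` (protospacer
#'   coordinate), `ref`, `alt`; or a combo string; or `NULL` for unedited.
#' @return `"on"` or `"off"`.
#' @examples
#' rc <- reporter_construct()
#' egfp_state(rc, NULL)                 # "off": in-frame TGA
#' egfp_state(rc, "7A>G")               # "on":  TGA -> TGG
#' @export
egfp_state <- function(construct, edits) {
  stopifnot(inherits(construct, "reporter_construct"))
  if (is.character(edits)) edits <- parse_combo(edits)
  insert <- construct$insert
  if (!is.null(edits) && nrow(edits) > 0L) {
    ipos <- proto_to_insert(construct, edits$position)
    if (any(ipos < 1L | ipos > nchar(insert))) {
      abort("edit position(s) outside the reporter insert.")
    }
    cur <- substring(insert, ipos, ipos)
    if (any(cur != toupper(edits$ref))) {
      abort("edit ref base(s) do not match the insert sequence.")
    }
    for (i in seq_along(ipos)) {
      substr(insert, ipos[i], ipos[i]) <- toupper(edits$alt[i])
    }
  }
  if (nchar(insert) %% 3L != 0L) return("off")
  codons <- substring(insert, seq(1L, nchar(insert), 3L),
                      seq(3L, nchar(insert), 3L))
  if (any(codons %in% STOP_CODONS)) "off" else "on"
}
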