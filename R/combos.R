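# Edit-combination ("combo") string utilities.
#
# A combo is the canonical label of the set of substitutions a read carries
# inside the quantification window, e.g. "5A>G;8A>G" or "-1A>G;6A>G".
# The empty string is the wild-type (unedited) combo. Edits are always on the
# protospacer strand and sorted by position, so string equality is set
# equality.

#' Build a canonical combo string from edit calls
#'
#' @param edits A data frame with columns `position`, `ref`, `alt`
#'   (protospacer-strand bases), or `NULL`/zero rows for wild type.
#' @return A combo string such as `"5A>G;8A>G"`; `""` for wild type.
#' @export
format_combo <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  stopifnot(all(c("position", "ref", "alt") %in% names(edits)))
  if (anyDuplicated(edits$position)) {
    abort("edit calls in a combo must have distinct positions.")
  }
  if (any(edits$ref == edits$alt)) abort("ref and alt bases must differ.")
  if (any(edits$position == 0L)) abort("protospacer position 0 does not exist.")
  edits <- arrange(edits, .data$position)
  paste0(edits$position, edits$ref, ">", edits$alt, collapse = ";")
}

#' Parse a combo string into edit calls
#'
#' @param combo A single combo string (`""` for wild type).
#' @return A tibble with columns `position`, `ref`, `alt` (0 rows for `""`).
#' @export
parse_combo <- function(combo) {
  stopifnot(length(combo) == 1L)
  if (is.na(combo) || combo == "") {
    return(tibble(position = integer(), ref = character(), alt = character()))
  }
  parts <- strsplit(combo, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(-?[0-9]+)([ACGTN])>([ACGTN])$", parts))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort(paste0("malformed combo element(s): ", paste(parts[bad], collapse = ", ")))
  }
  tibble(
    position = as.integer(map_chr(m, 2)),
    ref = map_chr(m, 3),
    alt = map_chr(m, 4)
  )
}

# long tibble of all edits across a vector of combo strings
combos_long <- function(combo) {
  out <- map(combo, parse_combo)
  tibble(combo = rep(combo, map_int(out, nrow)), bind_rows(out))
}

# integer positions of a single combo, fast path
combo_positions <- function(combo) {
  if (combo == "") return(integer())
  as.integer(sub("([ACGTN])>([ACGTN])$", "",
                 strsplit(combo, ";", fixed = TRUE)[[1]]))
}

# canonical key for a set of positions (used to match focal/competing combos)
position_key <- function(positions) {
  paste(sort(as.integer(positions)), collapse = ",")
}
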