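# Amplicon quantification: reads -> allele table -> per-position frequencies.
#
# Alignment is deliberately ungapped: amplicon sequencing yields fixed-layout
# reads, base editors produce almost no indels, and length anomalies are
# counted rather than resolved. Each read is anchored at the offset (within
# +/- anchor_range) minimising Hamming distance to the reference; reads are
# dereplicated first so cost scales with distinct sequences, not depth.

#' Quantify amplicon reads into an allele table
#'
#' @param reads A tibble from [read_fastq()] (columns `id`, `sequence`) or a
#'   character vector of read sequences.
#' @param spec The amplicon's [protospacer_spec()].
#' @param quant_window Protospacer-coordinate window `c(lo, hi)` in which
#'   substitutions are called as edits (default `c(-3, 12)`, wide enough for
#'   a -1 bystander and a +12 bystander).
#' @param mismatch_budget Maximum number of mismatches *outside*
#'   `quant_window` before a read is discarded as mismatch (default 5).
#'   Out-of-window mismatches are tolerated as sequencing error but never
#'   called as edits.
#' @param expected_length Expected read span in nt (default: the full
#'   reference). Reads of any other length are discarded as indel; reads
#'   shorter by more than `anchor_range` are counted as short.
#' @param anchor_range Anchoring search half-width in nt (default 5).
#' @return An [allele_table()].
#' @export
align_and_call <- function(reads, spec, quant_window = c(-3L, 12L),
                           mismatch_budget = 5L, expected_length = NULL,
                           anchor_range = 5L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) == 0L) abort("empty read stream.")
  stopifnot(inherits(spec, "protospacer_spec"))
  wpos <- window_positions(quant_window)
  widx <- position_index(spec, wpos)   # errors if window leaves the amplicon
  L <- nchar(spec$reference)
  expected_length <- as.integer(expected_length %||% L)
  if (expected_length > L) abort("expected_length exceeds the reference.")

  len <- nchar(seqs)
  short <- len < expected_length - anchor_range
  indel <- !short & len != expected_length
  keep <- !short & !indel
  n_short <- sum(short); n_indel <- sum(indel)

  combos <- character(0); combo_counts <- integer(0); n_mismatch <- 0L
  if (any(keep)) {
    derep <- tibble(sequence = toupper(seqs[keep])) |> count(.data$sequence)
    res <- call_unique_reads(derep$sequence, spec, wpos, widx,
                             mismatch_budget, anchor_range)
    n_mismatch <- sum(derep$n[is.na(res)])
    ok <- !is.na(res)
    if (any(ok)) {
      agg <- tibble(combo = res[ok], count = derep$n[ok]) |>
        group_by(.data$combo) |> summarise(count = sum(.data$count))
      combos <- agg$combo; combo_counts <- agg$count
    }
  }
  if (length(combos) == 0L) { combos <- ""; combo_counts <- 0L }
  allele_table(combos, combo_counts, spec = spec, window = quant_window,
               discards = c(indel = n_indel, mismatch = n_mismatch,
                            short = n_short))
}

# Returns one combo string per unique sequence, NA for mismatch-discards.
call_unique_reads <- function(useq, spec, wpos, widx, budget, anchor_range) {
  L <- nchar(spec$reference)
  ref_chars <- strsplit(spec$reference, "")[[1]]
  # reference-strand indices of the window positions, and protospacer lookup
  ref_widx <- if (spec$strand == "forward") widx else L - widx + 1L
  pos_of_ref <- integer(L); pos_of_ref[ref_widx] <- wpos
  in_window <- logical(L); in_window[ref_widx] <- TRUE

  vapply(useq, function(s) {
    rl <- nchar(s)
    rchars <- strsplit(s, "")[[1]]
    offsets <- unique(c(0L, seq(-anchor_range, anchor_range)))
    best <- NULL; best_dist <- Inf
    for (k in offsets[order(abs(offsets), offsets)]) {
      i1 <- max(1L, 1L - k); i2 <- min(rl, L - k)
      if (i2 < i1) next
      mism <- sum(rchars[i1:i2] != ref_chars[(i1:i2) + k])
      dist <- mism + abs(k) + (L - (i2 - i1 + 1L))
      if (dist < best_dist) { best_dist <- dist; best <- k }
      if (best_dist == 0) break
    }
    k <- best
    i1 <- max(1L, 1L - k); i2 <- min(rl, L - k)
    covered <- logical(L); covered[(i1:i2) + k] <- TRUE
    if (!all(covered[ref_widx])) return(NA_character_)  # window not covered
    ii <- i1:i2
    mm <- ii[rchars[ii] != ref_chars[ii + k]]
    rpos <- mm + k
    inside <- in_window[rpos]
    callable <- inside & rchars[mm] %in% DNA_BASES & ref_chars[rpos] %in% DNA_BASES
    n_out <- sum(!callable) + (L - length(ii))
    if (n_out > budget) return(NA_character_)
    if (!any(callable)) return("")
    rp <- rpos[callable]
    refb <- ref_chars[rp]; altb <- rchars[mm[callable]]
    if (spec$strand == "reverse") {
      refb <- complement_base(refb); altb <- complement_base(altb)
    }
    format_combo(tibble(position = pos_of_ref[rp], ref = refb, alt = altb))
  }, character(1), USE.NAMES = FALSE)
}

#' Per-position substitution frequencies
#'
#' The fraction of passing reads carrying a given substitution type at each
#' window position. Positions whose reference base is not `from_base` are
#' flagged `applicable = FALSE` with frequency `NA`, never 0: a C position
#' has no A-to-G frequency.
#'
#' @param table An [allele_table()] with an attached [protospacer_spec()].
#' @param from_base,to_base Substitution type (default A-to-G).
#' @return A tibble of class `freq_vector` with columns `position`,
#'   `ref_base`, `applicable`, `n_edited`, `frequency`; the denominator is
#'   total passing reads (`n_total` attribute).
#' @examples
#' at <- allele_table(c("", "6A>G", "6A>G;7A>G"), c(50, 30, 20))
#' # spec-free toy tables can use per_position_frequencies via a fixture spec;
#' # see make_locus_fixture().
#' @export
per_position_frequencies <- function(table, from_base = "A", to_base = "G") {
  stopifnot(inherits(table, "allele_tbl"))
  nt <- n_total(table)
  if (nt == 0L) abort("allele table has no passing reads (n_total = 0).")
  spec <- at_spec(table)
  if (is.null(spec)) {
    abort("allele table has no protospacer_spec attached; frequencies need the reference bases.")
  }
  positions <- window_positions(at_window(table))
  ref_base <- proto_base(spec, positions)
  applicable <- ref_base == from_base

  edits <- combos_long(table$combo) |>
    filter(.data$ref == from_base, .data$alt == to_base) |>
    left_join(as_tibble(table)[, c("combo", "count")], by = "combo") |>
    group_by(.data$position) |> summarise(n_edited = sum(.data$count))

  out <- tibble(position = positions, ref_base = ref_base,
                applicable = applicable) |>
    left_join(edits, by = "position") |>
    mutate(n_edited = ifelse(is.na(.data$n_edited), 0L, .data$n_edited),
           n_edited = ifelse(.data$applicable, .data$n_edited, NA_integer_),
           frequency = ifelse(.data$applicable, .data$n_edited / nt, NA_real_))
  structure(out, from_base = from_base, to_base = to_base, n_total = nt,
            class = c("freq_vector", class(out)))
}

#' Per-substitution-type frequency profiles (byproduct analysis)
#'
#' One frequency vector per substitution type, all sharing the same
#' denominator, so cytosine-deamination byproducts (C-to-T/G/A) can be read
#' next to the intended A-to-G signal.
#'
#' @param table An [allele_table()].
#' @param substitutions Character vector of `"X>Y"` types; defaults to the
#'   canonical four (A>G, C>T, C>G, C>A) plus any other type observed.
#' @return A tibble: `substitution` plus the [per_position_frequencies()]
#'   columns.
#' @export
byproduct_profile <- function(table,
                              substitutions = NULL) {
  stopifnot(inherits(table, "allele_tbl"))
  seen <- combos_long(table$combo)
  seen_types <- if (nrow(seen)) unique(paste0(seen$ref, ">", seen$alt)) else character()
  substitutions <- substitutions %||%
    union(c("A>G", "C>T", "C>G", "C>A"), seen_types)
  map(substitutions, function(st) {
    fb <- substr(st, 1, 1); tb <- substr(st, 3, 3)
    fv <- per_position_frequencies(table, from_base = fb, to_base = tb)
    mutate(as_tibble(fv), substitution = st, .before = 1L)
  }) |> bind_rows()
}

#' Editing window of a frequency vector
#'
#' The maximal contiguous run of applicable positions whose frequency is at
#' least `threshold_fraction` times the maximum frequency, containing the
#' position of the maximum (ties toward 5', i.e. the lower position).
#'
#' @param freq A `freq_vector` from [per_position_frequencies()].
#' @param threshold_fraction Fraction of the maximum in `(0, 1]`
#'   (default 0.3).
#' @return A one-row tibble (`start`, `end`, `width`, `max_frequency`,
#'   `cutoff`); zero rows when all frequencies are zero.
#' @export
editing_window <- function(freq, threshold_fraction = 0.3) {
  stopifnot(is.data.frame(freq),
            all(c("position", "applicable", "frequency") %in% names(freq)))
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("`threshold_fraction` must be in (0, 1].")
  }
  app <- freq |> filter(.data$applicable) |> arrange(.data$position)
  empty <- tibble(start = integer(), end = integer(), width = integer(),
                  max_frequency = double(), cutoff = double())
  if (nrow(app) == 0L) return(empty)
  v <- app$frequency
  mx <- max(v)
  if (mx == 0) return(empty)
  cutoff <- threshold_fraction * mx
  ok <- v >= cutoff
  imax <- which(v == mx)[1]          # 5'-most argmax
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  r <- which(starts <= imax & imax <= ends & runs$values)
  idx <- starts[r]:ends[r]
  tibble(start = app$position[min(idx)], end = app$position[max(idx)],
         width = length(idx), max_frequency = mx, cutoff = cutoff)
}

#' @exportS3Method ggplot2::autoplot
autoplot.freq_vector <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$applicable)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = "protospacer position",
      y = paste0(attr(object, "from_base"), "→",
                 attr(object, "to_base"), " frequency")) +
    ggplot2::theme_minimal()
}
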