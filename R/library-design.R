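# Variant-library enumeration. A variant is identified by its canonical
# substitution string: single-letter parent residue, 1-based position,
# replacement residue, multiple substitutions sorted by position and joined
# with "+", e.g. "S109A+D110G". The identity (parent) sequence is always the
# single variant "WT" — it anchors enrichment normalisation downstream.

sub_id <- function(position, from_aa, to_aa) paste0(from_aa, position, to_aa)

variant_id_from_subs <- function(position, from_aa, to_aa) {
  if (length(position) == 0L) return("WT")
  o <- order(position)
  paste(sub_id(position[o], from_aa[o], to_aa[o]), collapse = "+")
}

#' Parse a variant identifier into its substitutions
#'
#' @param variant_id A variant id such as `"S109A+D110G"` (`"WT"` for the
#'   identity variant).
#' @return A tibble with columns `position`, `from_aa`, `to_aa`.
#' @export
parse_variant_id <- function(variant_id) {
  stopifnot(length(variant_id) == 1L)
  if (variant_id == "WT") {
    return(tibble(position = integer(), from_aa = character(),
                  to_aa = character()))
  }
  parts <- strsplit(variant_id, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Y])([0-9]+)([A-Y])$", parts))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort(paste0("malformed substitution id(s): ",
                 paste(parts[bad], collapse = ", ")))
  }
  out <- tibble(position = as.integer(map_chr(m, 3)),
                from_aa = map_chr(m, 2), to_aa = map_chr(m, 4))
  if (anyDuplicated(out$position)) {
    abort("substitutions within a variant must have distinct positions.")
  }
  if (any(out$from_aa == out$to_aa)) {
    abort("from_aa and to_aa must differ for every substitution.")
  }
  out
}

check_parent_window <- function(parent, positions) {
  aa <- strsplit(parent, "")[[1]]
  if (any(positions < 1L | positions > length(aa))) {
    abort("position(s) outside the parent sequence.")
  }
  aa
}

#' Single-substitution range scan
#'
#' One variant per (position, amino acid) pair over a residue range; pairs
#' whose amino acid equals the parent residue collapse to the single identity
#' variant `"WT"`.
#'
#' @param parent Parent protein (one-letter string).
#' @param first,last 1-based residue range, inclusive.
#' @param alphabet Amino-acid set to substitute with (default the 20
#'   canonical).
#' @return A tibble with columns `variant_id`, `n_substitutions`,
#'   `sub_library`.
#' @examples
#' nrow(enumerate_range_scan(tada_sequences()$sequence[1], 106, 157))  # 989
#' @export
enumerate_range_scan <- function(parent, first, last, alphabet = AA20) {
  first <- as.integer(first); last <- as.integer(last)
  if (first > last) abort("`first` must be <= `last`.")
  aa <- check_parent_window(parent, c(first, last))
  if (length(alphabet) == 0L) {
    return(tibble(variant_id = character(), n_substitutions = integer(),
                  sub_library = character()))
  }
  grid <- tidyr::expand_grid(position = first:last, to_aa = alphabet) |>
    mutate(from_aa = aa[.data$position]) |>
    filter(.data$from_aa != .data$to_aa) |>
    mutate(variant_id = sub_id(.data$position, .data$from_aa, .data$to_aa))
  bind_rows(
    tibble(variant_id = "WT", n_substitutions = 0L),
    tibble(variant_id = grid$variant_id, n_substitutions = 1L)
  ) |>
    distinct(.data$variant_id, .keep_all = TRUE) |>
    mutate(sub_library = "range_scan")
}

#' Combinatorial site-saturation library
#'
#' Full Cartesian product of the alphabet over the given positions; a
#' position assigned its parent residue contributes no substitution, and the
#' all-parent tuple is the identity variant `"WT"`.
#'
#' @inheritParams enumerate_range_scan
#' @param positions Distinct 1-based residue positions.
#' @return A tibble with columns `variant_id`, `n_substitutions`,
#'   `sub_library`; one row per tuple (e.g. `20^3 = 8000` for three
#'   positions).
#' @export
enumerate_site_saturation <- function(parent, positions, alphabet = AA20) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) abort("`positions` must be non-empty.")
  if (anyDuplicated(positions)) abort("`positions` must be distinct.")
  aa <- check_parent_window(parent, positions)
  tuples <- tidyr::expand_grid(
    !!!setNames(rep(list(alphabet), length(positions)),
                paste0("p", positions)))
  ids <- apply(as.matrix(tuples), 1L, function(row) {
    changed <- row != aa[positions]
    variant_id_from_subs(positions[changed], aa[positions][changed],
                         row[changed])
  })
  tibble(variant_id = ids,
         n_substitutions = map_int(strsplit(ids, "+", fixed = TRUE),
                                   ~ if (identical(.x, "WT")) 0L else length(.x)),
         sub_library = "site_saturation")
}

#' Same-charge substitution library
#'
#' For each listed residue, one single-substitution variant per other member
#' of its charge class.
#'
#' @inheritParams enumerate_range_scan
#' @param residues A data frame with columns `position`, `expected_aa`; the
#'   expected residue must match the parent (a consistency check against
#'   off-by-one position errors).
#' @param charge_classes A partition of the amino acids, as from
#'   [default_charge_classes()].
#' @return A tibble with columns `variant_id`, `n_substitutions`,
#'   `sub_library` (identity variant included once).
#' @export
enumerate_charge_swap <- function(parent, residues,
                                  charge_classes = default_charge_classes()) {
  res <- as_tibble(residues)
  stopifnot(all(c("position", "expected_aa") %in% names(res)))
  res$position <- as.integer(res$position)
  aa <- check_parent_window(parent, res$position)
  actual <- aa[res$position]
  bad <- actual != res$expected_aa
  if (any(bad)) {
    abort(paste0("expected_aa mismatch at position(s): ",
                 paste(res$position[bad], collapse = ", "),
                 " (parent has ", paste(actual[bad], collapse = ", "), ")"))
  }
  all_members <- unlist(charge_classes, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    abort("`charge_classes` must be a partition (no amino acid in two classes).")
  }
  rows <- map(seq_len(nrow(res)), function(i) {
    from <- res$expected_aa[i]
    cls <- charge_classes[[which(map_lgl(charge_classes, ~ from %in% .x))]]
    to <- setdiff(cls, from)
    if (length(to) == 0L) return(NULL)
    tibble(variant_id = sub_id(res$position[i], from, to),
           n_substitutions = 1L)
  })
  bind_rows(tibble(variant_id = "WT", n_substitutions = 0L), rows) |>
    distinct(.data$variant_id, .keep_all = TRUE) |>
    mutate(sub_library = "charge_swap")
}

#' Rational back-mutation variants around screen hits
#'
#' For each single-substitution screen hit, finds the two nearest residues
#' (scanning outward within `flank`, ties toward the lower index) where the
#' modern sequence differs from the ancestral one, and emits the hit combined
#' with each single reversion and with both reversions (three variants per
#' hit with two neighbours), deduplicated across hits.
#'
#' @param seeds Character vector of single-substitution variant ids (or a
#'   data frame with a `variant_id` column).
#' @param modern,ancestral Equal-length protein strings; reversions change a
#'   residue from its modern to its ancestral state.
#' @param flank Neighbourhood half-width in residues (default 10).
#' @return A tibble with columns `variant_id`, `seed_id`, `n_substitutions`,
#'   `sub_library`. Hits with fewer than two differing neighbours emit what
#'   exists, with a warning.
#' @export
enumerate_back_mutations <- function(seeds, modern, ancestral, flank = 10L) {
  if (is.data.frame(seeds)) seeds <- seeds$variant_id
  if (nchar(modern) != nchar(ancestral)) {
    abort("`modern` and `ancestral` must have equal length.")
  }
  m <- strsplit(toupper(modern), "")[[1]]
  a <- strsplit(toupper(ancestral), "")[[1]]
  diff_pos <- which(m != a)
  out <- map(seeds, function(sid) {
    sub <- parse_variant_id(sid)
    if (nrow(sub) != 1L) {
      abort(paste0("seed '", sid, "' must carry exactly one substitution."))
    }
    if (m[sub$position] != sub$from_aa) {
      abort(paste0("seed '", sid, "' does not match the modern sequence."))
    }
    cand <- setdiff(diff_pos, sub$position)
    cand <- cand[abs(cand - sub$position) <= flank]
    cand <- cand[order(abs(cand - sub$position), cand)]
    near <- head(cand, 2L)
    if (length(near) < 2L) {
      warn(paste0("seed '", sid, "' has ", length(near),
                  " modern/ancestral difference(s) within ", flank,
                  " residues; emitting ",
                  c("no", "one single-reversion")[length(near) + 1L],
                  " back-mutation variant(s)."))
    }
    if (length(near) == 0L) return(NULL)
    revs <- tibble(position = near, from_aa = m[near], to_aa = a[near])
    sets <- c(map(seq_along(near), ~ revs[.x, , drop = FALSE]),
              if (length(near) == 2L) list(revs))
    tibble(
      variant_id = map_chr(sets, function(rv) {
        all_sub <- bind_rows(sub, rv)
        variant_id_from_subs(all_sub$position, all_sub$from_aa, all_sub$to_aa)
      }),
      seed_id = sid,
      n_substitutions = map_int(sets, ~ nrow(.x) + 1L)
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(variant_id = character(), seed_id = character(),
                  n_substitutions = integer(),
                  sub_library = character()))
  }
  res |>
    distinct(.data$variant_id, .keep_all = TRUE) |>
    mutate(sub_library = "back_mutation")
}

#' Combine candidate variant sets
#'
#' Distinct union of variant ids from several sources (e.g. screen hits and
#' back-mutation variants), keeping the first source label seen.
#'
#' @param ... Data frames with a `variant_id` column, or character vectors.
#'   Named arguments label the `source` column.
#' @return A tibble with columns `variant_id`, `source`.
#' @export
combine_candidates <- function(...) {
  sets <- list(...)
  nm <- names(sets) %||% rep("", length(sets))
  nm[nm == ""] <- paste0("set", which(nm == ""))
  bind_rows(imap(setNames(sets, nm), function(x, label) {
    ids <- if (is.data.frame(x)) x$variant_id else as.character(x)
    tibble(variant_id = ids, source = label)
  })) |>
    distinct(.data$variant_id, .keep_all = TRUE)
}

#' Emit clonable oligos for a variant library
#'
#' Rebuilds each variant's coding sequence from the parent CDS, substituting
#' the top-ranked codon for each replaced residue and falling back down the
#' ranking when a choice would create the forbidden Type IIS recognition site
#' (default BsmBI, CGTCTC, checked on both strands) in its local context. A
#' variant for which no codon choice avoids the site is returned as a
#' rejected record, never silently dropped.
#'
#' @param variants A data frame with a `variant_id` column.
#' @param parent_cds Parent coding sequence (must translate to the parent
#'   protein the variant ids refer to).
#' @param codon_ranks Codon preference ranking, see [human_codon_ranks()].
#' @param forbidden_site Recognition motif to exclude (default `"CGTCTC"`).
#' @param flank_5,flank_3 Cloning flanks carrying the outward-cutting Type
#'   IIS sites and overhangs; attached verbatim, excluded from the
#'   internal-site check.
#' @return A tibble with columns `variant_id`, `dna`, `flank_5`, `flank_3`,
#'   `status` (`"ok"`/`"rejected"`), `reason`.
#' @export
emit_oligos <- function(variants, parent_cds,
                        codon_ranks = human_codon_ranks(),
                        forbidden_site = "CGTCTC",
                        flank_5 = "AGCGTCTCA", flank_3 = "TGAGACGGCT") {
  ids <- if (is.data.frame(variants)) variants$variant_id else variants
  parent_cds <- toupper(parent_cds)
  parent_protein <- translate_cds(parent_cds)
  site_rc <- revcomp(forbidden_site)
  has_site <- function(x) grepl(forbidden_site, x, fixed = TRUE) ||
    grepl(site_rc, x, fixed = TRUE)

  rows <- map(ids, function(vid) {
    subs <- parse_variant_id(vid)
    dna <- parent_cds
    for (i in seq_len(nrow(subs))) {
      p <- subs$position[i]
      if (substr(parent_protein, p, p) != subs$from_aa[i]) {
        abort(paste0("variant '", vid, "': parent residue at ", p,
                     " is not ", subs$from_aa[i], "."))
      }
      ranks <- codon_ranks[[subs$to_aa[i]]]
      if (is.null(ranks)) {
        abort(paste0("codon ranking missing amino acid ", subs$to_aa[i], "."))
      }
      placed <- FALSE
      for (codon in ranks) {
        trial <- dna
        substr(trial, 3L * p - 2L, 3L * p) <- codon
        ctx <- substr(trial, max(1L, 3L * p - 7L),
                      min(nchar(trial), 3L * p + 5L))
        if (!has_site(ctx)) { dna <- trial; placed <- TRUE; break }
      }
      if (!placed) {
        return(tibble(variant_id = vid, dna = NA_character_,
                      flank_5 = flank_5, flank_3 = flank_3,
                      status = "rejected",
                      reason = paste0("every codon for ", subs$to_aa[i],
                                      " at residue ", p,
                                      " creates the forbidden site in context")))
      }
    }
    if (has_site(dna)) {
      return(tibble(variant_id = vid, dna = NA_character_,
                    flank_5 = flank_5, flank_3 = flank_3,
                    status = "rejected",
                    reason = "substituted codons jointly create the forbidden site"))
    }
    tibble(variant_id = vid, dna = dna, flank_5 = flank_5,
           flank_3 = flank_3, status = "ok", reason = NA_character_)
  })
  bind_rows(rows)
}

#' Apply a variant's substitutions to a protein sequence
#'
#' @param parent Parent protein string.
#' @param variant_id Canonical variant id.
#' @return The mutated protein string.
#' @export
apply_variant <- function(parent, variant_id) {
  subs <- parse_variant_id(variant_id)
  aa <- strsplit(parent, "")[[1]]
  if (nrow(subs)) {
    if (any(aa[subs$position] != subs$from_aa)) {
      abort("from_aa does not match the parent sequence.")
    }
    aa[subs$position] <- subs$to_aa
  }
  paste(aa, collapse = "")
}
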