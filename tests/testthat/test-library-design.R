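# Library enumeration rules, verified against brute-force oracles rather
# than closed forms.

tada <- tada_sequences()
modern <- tada$sequence[tada$id == "tada8e_synthetic"]
ancestral <- tada$sequence[tada$id == "tada710_synthetic"]

test_that("range scan matches the exhaustive pair-grid oracle", {
  lib <- enumerate_range_scan(modern, 106, 157)
  # oracle: loop over the full (position, amino acid) grid
  aa <- strsplit(modern, "")[[1]]
  expected <- character()
  for (p in 106:157) for (x in bescreen:::AA20) {
    expected <- c(expected,
                  if (x == aa[p]) "WT" else paste0(aa[p], p, x))
  }
  expect_equal(length(expected), 52 * 20)  # 1040 raw pairs
  expect_setequal(lib$variant_id, unique(expected))
  expect_equal(nrow(lib), 989)
  expect_false(anyDuplicated(lib$variant_id) > 0)
  expect_equal(sum(lib$variant_id == "WT"), 1L)

  one <- enumerate_range_scan(modern, 111, 111)
  expect_equal(nrow(one), 20L)  # 19 substitutions + identity
  expect_equal(nrow(enumerate_range_scan(modern, 111, 111,
                                         alphabet = character())), 0L)
  expect_error(enumerate_range_scan(modern, 160, 200), "outside")
})

test_that("site saturation matches the nested-loop oracle", {
  lib <- enumerate_site_saturation(modern, c(111, 119, 149))
  aa <- strsplit(modern, "")[[1]]
  expected <- character()
  for (a in bescreen:::AA20) for (b in bescreen:::AA20) for (d in bescreen:::AA20) {
    subs <- c(
      if (a != aa[111]) paste0(aa[111], 111, a),
      if (b != aa[119]) paste0(aa[119], 119, b),
      if (d != aa[149]) paste0(aa[149], 149, d))
    expected <- c(expected,
                  if (length(subs) == 0L) "WT" else paste(subs, collapse = "+"))
  }
  expect_equal(nrow(lib), 20^3)
  expect_setequal(lib$variant_id, unique(expected))
  expect_equal(sum(lib$variant_id == "WT"), 1L)
  expect_equal(sum(lib$n_substitutions == 0L), 1L)

  one <- enumerate_site_saturation(modern, 111)
  expect_equal(nrow(one), 20L)
  expect_error(enumerate_site_saturation(modern, c(111, 111)), "distinct")
  expect_error(enumerate_site_saturation(modern, integer()), "non-empty")
})

test_that("charge swap emits one variant per same-class alternative", {
  residues <- tibble::tibble(
    position = c(109L, 111L, 119L, 122L, 147L, 149L),
    expected_aa = c("S", "R", "N", "N", "D", "Y"))
  lib <- enumerate_charge_swap(modern, residues)
  # class-lookup oracle for the unambiguous charged residues
  expect_true(all(c("R111K", "R111H") %in% lib$variant_id))
  expect_true("D147E" %in% lib$variant_id)
  expect_equal(sum(grepl("^R111", lib$variant_id)), 2L)
  expect_equal(sum(grepl("^D147", lib$variant_id)), 1L)
  # polar class {S,T,N,Q,C,Y}: 5 alternatives each for S/N/N/Y
  expect_equal(nrow(lib), 1L + 5L + 2L + 5L + 5L + 1L + 5L)

  expect_error(enumerate_charge_swap(
    modern, tibble::tibble(position = 109L, expected_aa = "R")), "109")

  # a residue whose class is a singleton yields no variants
  lonely <- enumerate_charge_swap(
    "MW", tibble::tibble(position = 2L, expected_aa = "W"),
    charge_classes = list(a = "W", b = setdiff(bescreen:::AA20, "W")))
  expect_equal(lonely$variant_id, "WT")
})

test_that("back mutations follow the two-nearest-differences rule", {
  # the synthetic pair differs at 109/111/119/122/147/149/166/167
  bm1 <- enumerate_back_mutations("D110G", modern, ancestral)
  expect_setequal(bm1$variant_id,
                  c("S109A+D110G", "D110G+R111T", "S109A+D110G+R111T"))
  expect_equal(nrow(bm1), 3L)

  bm <- enumerate_back_mutations(c("D110G", "D120G", "W148G"),
                                 modern, ancestral)
  expect_equal(nrow(bm), 9L)
  expect_false(anyDuplicated(bm$variant_id) > 0)
  # each emitted variant contains its seed plus reversions toward ancestral
  anc <- strsplit(ancestral, "")[[1]]
  for (vid in bm$variant_id) {
    subs <- parse_variant_id(vid)
    revs <- subs[paste0(subs$from_aa, subs$position, subs$to_aa) %in%
                   c("S109A", "R111T", "N119D", "N122H", "D147Y", "Y149F"), ]
    expect_true(all(anc[revs$position] == revs$to_aa))
  }

  # seed in a region with no nearby differences -> nothing, with a warning
  expect_warning(
    none <- enumerate_back_mutations("Y4G", modern, ancestral, flank = 3),
    "0 modern/ancestral difference")
  expect_equal(nrow(none), 0L)
  expect_no_warning(enumerate_back_mutations("K35G", modern, ancestral,
                                             flank = 80))
})

test_that("candidate pool union deduplicates across sources", {
  hits <- paste0("H", 1:22)
  bm <- enumerate_back_mutations(c("D110G", "D120G", "W148G"),
                                 modern, ancestral)
  pool <- combine_candidates(screen_hits = hits, back_mutation = bm)
  expect_equal(nrow(pool), 31L)
  # overlapping ids collapse
  pool2 <- combine_candidates(a = c("X1Y", "X2Y"), b = c("X2Y", "X3Y"))
  expect_equal(nrow(pool2), 3L)
  expect_equal(pool2$source[pool2$variant_id == "X2Y"], "a")
})

test_that("oligos reproduce their variant proteins and avoid the forbidden site", {
  cds <- reverse_translate(modern)
  expect_equal(translate_cds(cds), modern)

  lib <- dplyr::bind_rows(
    enumerate_range_scan(modern, 106, 110),
    enumerate_back_mutations(c("D110G", "D120G", "W148G"), modern, ancestral))
  oligos <- emit_oligos(lib, cds)
  expect_equal(nrow(oligos), nrow(lib))
  ok <- oligos[oligos$status == "ok", ]
  # round trip: translating each oligo gives the variant protein exactly
  for (i in seq_len(nrow(ok))) {
    expect_equal(
      as.character(Biostrings::translate(Biostrings::DNAString(ok$dna[i]))),
      apply_variant(modern, ok$variant_id[i]))
  }
  # no internal BsmBI site on either strand
  expect_false(any(grepl("CGTCTC", ok$dna, fixed = TRUE)))
  expect_false(any(grepl("GAGACG", ok$dna, fixed = TRUE)))

  # identity oligo equals the parent CDS
  expect_equal(oligos$dna[oligos$variant_id == "WT"], cds)

  # single substitution touches at most one codon (<= 3 nt)
  single <- ok[ok$variant_id == "F106A", ]
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              single$dna, cds)
  expect_lte(unname(d), 3)

  # a substitution whose every codon creates the site is rejected, not dropped
  # context: parent ...CGT CTx...; placing S (e.g. AGC) cannot matter, but
  # placing any E codon (GAa/GAg) after GA GACG context can. Build it directly:
  toy_parent_cds <- paste0("ATG", "GAG", "ACG", "TAA")  # M E T *
  expect_error(translate_cds("ACGT"))
  res <- emit_oligos(tibble::tibble(variant_id = "T3R"), toy_parent_cds,
                     codon_ranks = modifyList(human_codon_ranks(),
                                              list(R = "AGA")))
  # ...GAG AGA... does not contain the site; force a conflict instead:
  res2 <- emit_oligos(tibble::tibble(variant_id = "E2V"), toy_parent_cds,
                      codon_ranks = modifyList(human_codon_ranks(),
                                               list(V = "GTC")))
  # ATG GTC ACG: fine too; a genuinely unavoidable case uses a single-codon
  # ranking that always recreates the site:
  res3 <- emit_oligos(tibble::tibble(variant_id = "T3R"),
                      paste0("ATG", "GAG", "ACG", "TAA"),
                      codon_ranks = modifyList(human_codon_ranks(),
                                               list(R = "CGT")),
                      forbidden_site = "GAGCGT")
  expect_equal(res3$status, "rejected")
  expect_match(res3$reason, "forbidden")
  expect_equal(res$status, "ok")
  expect_equal(res2$status, "ok")
})
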