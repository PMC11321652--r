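# Product-purity combinatorics and the precise / missense / wild-type rule.

test_that("combo_distribution projects onto position sets", {
  spec <- six_a_spec()
  at <- allele_table(c("", "6A>G", "6A>G;7A>G"), c(50L, 30L, 20L),
                     spec = test_spec())
  d <- combo_distribution(at, c(6, 7))
  expect_equal(d$fraction[d$combo == ""], 0.5)
  expect_equal(d$fraction[d$combo == "6A>G"], 0.3)
  expect_equal(d$fraction[d$combo == "6A>G;7A>G"], 0.2)
  expect_equal(d$multiplicity, c("none", "single", "dual"))
  expect_equal(sum(d$fraction), 1)

  # projection: an off-set edit is ignored, {6,9} projects to single{6}
  at2 <- allele_table(c("6A>G;9C>T"), 10L, spec = spec, window = c(1L, 12L))
  d2 <- combo_distribution(at2, c(6, 7))
  expect_equal(d2$combo, "6A>G")
  expect_equal(d2$multiplicity, "single")

  # property: distribution equals the brute-force projection oracle
  withr::with_seed(77, {
    for (i in 1:50) {
      tab <- random_allele_table()
      proj_on <- sort(sample(SIX_A_POSITIONS, 3))
      d3 <- combo_distribution(tab, proj_on)
      # oracle: project each combo by string surgery, aggregate counts
      key <- vapply(tab$combo, function(cm) {
        parts <- strsplit(cm, ";", fixed = TRUE)[[1]]
        pos <- as.integer(sub("A>G$", "", parts))
        paste(parts[pos %in% proj_on], collapse = ";")
      }, character(1))
      want <- tapply(tab$count, key, sum) / sum(tab$count)
      expect_equal(d3$fraction,
                   as.numeric(want[match(d3$combo, names(want))]))
    }
  })
})

test_that("projection onto more positions never increases the unedited fraction", {
  withr::with_seed(5, {
    for (i in 1:30) {
      tab <- random_allele_table()
      small <- sample(SIX_A_POSITIONS, 2)
      big <- union(small, sample(SIX_A_POSITIONS, 4))
      f_small <- combo_distribution(tab, small)
      f_big <- combo_distribution(tab, big)
      wt_small <- sum(f_small$fraction[f_small$combo == ""])
      wt_big <- sum(f_big$fraction[f_big$combo == ""])
      expect_lte(wt_big, wt_small + 1e-12)
    }
  })
})

test_that("purity ratio handles present, absent, and degenerate combos", {
  spec <- six_a_spec()
  at <- allele_table(c("", "6A>G", "6A>G;8A>G"), c(10L, 60L, 40L),
                     spec = spec)
  d <- combo_distribution(at, c(6, 8))
  expect_equal(purity_ratio(d, 6, c(6, 8)), 60 / 100)
  expect_equal(purity_ratio(d, 6, c(6, 10)), 1.0)       # competing absent
  expect_true(is.na(purity_ratio(d, 4, c(4, 10))))      # both absent
})

test_that("codon consequences follow the standard genetic code", {
  expect_equal(codon_consequence("ACG", "GCG"), "missense")   # Thr -> Ala
  expect_equal(codon_consequence("CAG", "CGG"), "missense")   # Gln -> Arg
  expect_equal(codon_consequence("TGA", "TGG"), "stop_loss")  # stop -> Trp
  expect_equal(codon_consequence("GCT", "GCC"), "synonymous")
  expect_equal(codon_consequence("TAC", "TAA"), "nonsense")
  expect_equal(codon_consequence("TAC", "TGC", is_target = TRUE),
               "corrective")
  expect_error(codon_consequence("AC", "ACG"), "triplet")
  expect_error(codon_consequence("ACG", "ACG"), "differ")
})

test_that("classification of the HFE fixture agrees with exhaustive enumeration", {
  fx <- make_locus_fixture("hfe_c282y")
  cons <- setNames(fx$target$consequences$consequence,
                   fx$target$consequences$position)
  expect_equal(unname(cons[c("1", "5", "8")]),
               c("missense", "corrective", "missense"))

  # all 2^3 combos over {1,5,8}: 1 precise, 6 missense-containing, 1 wild type
  subsets <- list(integer(), 1L, 5L, 8L, c(1L, 5L), c(1L, 8L), c(5L, 8L),
                  c(1L, 5L, 8L))
  combos <- vapply(subsets, function(ps) {
    if (!length(ps)) "" else paste0(ps, "A>G", collapse = ";")
  }, character(1))
  at <- allele_table(combos, rep(10L, 8L), spec = fx$spec)
  out <- classify_outcomes(at, fx$target)
  frac <- setNames(out$fractions$fraction, out$fractions$category)
  expect_equal(unname(frac["precise"]), 1 / 8)
  expect_equal(unname(frac["bystander_missense"]), 6 / 8)
  expect_equal(unname(frac["wild_type"]), 1 / 8)
  expect_equal(unname(frac["other_edited"]), 0)

  # combo-by-combo agreement with the rule oracle
  for (cm in combos) {
    single <- allele_table(cm, 1L, spec = fx$spec)
    got <- classify_outcomes(single, fx$target)
    got_cat <- got$fractions$category[got$fractions$fraction == 1]
    expect_equal(got_cat, oracle_classify(cm, 5L, cons))
  }
})

test_that("the four outcome fractions partition every random table", {
  hbb <- make_locus_fixture("hbb_s")
  withr::with_seed(303, {
    for (i in 1:50) {
      subsets <- unique(replicate(6, {
        s <- sample(c(7L, 9L, 12L), sample.int(3, 1))
        sort(s)
      }, simplify = FALSE))
      combos <- c("", vapply(subsets, function(ps)
        paste0(ps, "A>G", collapse = ";"), character(1)))
      at <- allele_table(combos, sample.int(100, length(combos),
                                            replace = TRUE),
                        spec = hbb$spec)
      out <- classify_outcomes(at, hbb$target)
      expect_equal(sum(out$fractions$fraction), 1, tolerance = 1e-12)
      expect_equal(sum(out$combo_distribution$fraction), 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("synonymous bystanders are other_edited unless folded", {
  hbb <- make_locus_fixture("hbb_s")
  at <- allele_table(c("", "7A>G", "7A>G;9A>G"), c(20L, 50L, 30L),
                     spec = hbb$spec)
  out <- classify_outcomes(at, hbb$target)
  frac <- setNames(out$fractions$fraction, out$fractions$category)
  expect_equal(unname(frac["precise"]), 0.5)
  expect_equal(unname(frac["other_edited"]), 0.3)  # +9 is synonymous
  expect_equal(unname(frac["bystander_missense"]), 0)

  folded <- classify_outcomes(at, hbb$target, fold_other = TRUE)
  ff <- setNames(folded$fractions$fraction, folded$fractions$category)
  expect_equal(unname(ff["bystander_missense"]), 0.3)
  expect_equal(unname(ff["other_edited"]), 0)
})

test_that("bystander report matches restricted per-position frequencies", {
  hbb <- make_locus_fixture("hbb_s")
  at <- allele_table(c("", "7A>G;9A>G", "7A>G;9A>G;12A>G"),
                     c(10L, 60L, 30L), spec = hbb$spec)
  rep <- bystander_report(at, hbb$target)
  expect_equal(rep$position, c(9L, 12L))
  expect_equal(rep$consequence, c("synonymous", "synonymous"))
  fv <- per_position_frequencies(at)
  expect_equal(rep$frequency,
               fv$frequency[match(c(9L, 12L), fv$position)])
  expect_equal(rep$frequency, c(0.9, 0.3))

  # all reads edited at {7,9}: bystander freq(+9) saturates at 1
  at2 <- allele_table("7A>G;9A>G", 5L, spec = hbb$spec)
  rep2 <- bystander_report(at2, hbb$target)
  expect_equal(rep2$frequency[rep2$position == 9], 1.0)
  # no bystander edits -> zeros
  at3 <- allele_table(c("", "7A>G"), c(5L, 5L), spec = hbb$spec)
  expect_true(all(bystander_report(at3, hbb$target)$frequency == 0))
})

test_that("pcsk9 fixture covers the -1 bystander", {
  fx <- make_locus_fixture("pcsk9_intron1")
  expect_equal(proto_base(fx$spec, -1L), "A")
  at <- allele_table(c("", "6A>G", "-1A>G;6A>G"), c(30L, 50L, 20L),
                     spec = fx$spec)
  out <- classify_outcomes(at, fx$target)
  frac <- setNames(out$fractions$fraction, out$fractions$category)
  expect_equal(unname(frac["precise"]), 0.5)
  expect_equal(unname(frac["bystander_missense"]), 0.2)
  rep <- bystander_report(at, fx$target)
  expect_equal(rep$position, -1L)
  expect_equal(rep$frequency, 0.2)
})

test_that("bundled target-spec YAML fixtures mirror the in-code fixtures", {
  for (nm in c("hfe_c282y", "hbb_s", "pcsk9_intron1")) {
    y <- read_target_spec(nm)
    fx <- make_locus_fixture(nm)
    expect_equal(y$editable_positions, fx$target$editable_positions)
    expect_equal(y$target_position, fx$target$target_position)
    expect_equal(y$consequences$consequence,
                 fx$target$consequences$consequence)
  }
})
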