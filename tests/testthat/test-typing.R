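panel <- reference_panel()
cfg <- match_config()

test_that("the bundled panel carries the eight expected signatures", {
  expect_setequal(names(panel), names(expected_signatures))
  for (sp in names(expected_signatures)) {
    ref <- expected_signatures[[sp]]
    expect_setequal(names(panel[[sp]]), names(ref))
    for (e in names(ref)) expect_equal(panel[[sp]][[e]], ref[[e]])
    expect_true(all(vapply(panel[[sp]], sum, integer(1)) == 357L))
  }
})

test_that("pattern comparison applies tolerances and the detection limit", {
  ref <- panel[["Thunnus thynnus"]]
  self <- compare_patterns(ref, ref, cfg)
  expect_true(self$overall)
  expect_true(all(self$per_enzyme))

  # bands within the 5-bp absolute tolerance match
  obs <- fragment_pattern(list(Eco147I = c(230, 127)), "observed")
  refp <- fragment_pattern(list(Eco147I = c(233, 124)))
  expect_true(compare_patterns(obs, refp, cfg)$overall)
  # beyond max(abs, rel * larger band) they do not
  tight <- match_config(abs_tolerance = 2, rel_tolerance = 0)
  expect_false(compare_patterns(obs, refp, tight)$overall)

  # the 10-bp reference band is below the 20-bp detection limit: a gel
  # showing only 150 and 197 still matches the bigeye HindII reference
  obs <- fragment_pattern(list(HindII = c(150, 197)), "observed")
  refp <- fragment_pattern(list(HindII = c(150, 10, 197)))
  expect_true(compare_patterns(obs, refp, cfg)$overall)
  expect_false(compare_patterns(obs, refp, exact_config())$overall)

  # enzymes absent from one side are excluded, but sharing none is an error
  obs <- fragment_pattern(list(HindII = 357), "observed")
  expect_error(compare_patterns(obs, fragment_pattern(list(MboI = 357)),
                                cfg), "share no enzymes")
})

test_that("each reference signature identifies exactly its own species", {
  for (sp in names(panel)) {
    res <- identify_species(panel[[sp]], panel, cfg)
    expect_equal(res$call, sp)
    expect_equal(res$ambiguity, sp)
  }
})

test_that("the staged key resolves bigeye vs skipjack through HindII only", {
  # core pattern shared by the pair, with each HindII outcome
  core <- expected_signatures[["Katsuwonus pelamis"]][
    c("Eco147I", "HinfI", "MboI", "XagI")]
  jy <- fragment_pattern(c(core, list(HindII = 357L)), "observed")
  dd <- fragment_pattern(c(core, list(HindII = c(150L, 10L, 197L))),
                         "observed")
  expect_equal(identify_species(jy, panel, cfg)$call, "Katsuwonus pelamis")
  expect_equal(identify_species(dd, panel, cfg)$call, "Thunnus obesus")

  # without HindII data the pair stays ambiguous, with a warning
  res <- identify_species(fragment_pattern(core, "observed"), panel, cfg)
  expect_true(is.na(res$call))
  expect_setequal(res$ambiguity, c("Thunnus obesus", "Katsuwonus pelamis"))
  expect_match(res$warnings, "tiebreak", all = FALSE)

  # southern bluefin is called from its core signature alone
  ms <- fragment_pattern(list(Eco147I = 357, HinfI = c(109, 248),
                              MboI = 357, XagI = 357), "observed")
  expect_equal(identify_species(ms, panel, cfg)$call, "Thunnus maccoyii")
  # swordfish, from its diagnostic Eco147I doublet
  ji <- fragment_pattern(list(Eco147I = c(283, 74), HinfI = c(196, 161),
                              MboI = 357, XagI = 357), "observed")
  expect_equal(identify_species(ji, panel, cfg)$call, "Xiphias gladius")

  res <- identify_species(fragment_pattern(list(Eco147I = c(50, 307)),
                                           "observed"), panel, cfg)
  expect_true(is.na(res$call))
  expect_length(res$ambiguity, 0)
})

test_that("enlarging tolerances never shrinks a match set", {
  set.seed(17)
  for (i in 1:20) {
    obs <- fragment_pattern(lapply(panel[[sample(8, 1)]], function(f) {
      pmax(1L, f + sample(-8:8, length(f), replace = TRUE))
    }), "observed")
    small <- identify_species(obs, panel,
                              match_config(abs_tolerance = 3))$ambiguity
    big <- identify_species(obs, panel,
                            match_config(abs_tolerance = 10))$ambiguity
    expect_true(all(small %in% big))
  }
})

test_that("all five enzymes are needed to separate the eight species", {
  mp <- minimal_panel(panel)
  expect_equal(mp$size, 5L)
  expect_true(mp$discriminating)
  expect_setequal(mp$enzymes, names(enzyme_catalogue()))
  expect_length(mp$partition, 8)
  # exhaustive: the best any 4-enzyme subset achieves is 7 classes
  expect_equal(mp$by_size$best_classes[mp$by_size$size == 4], 7L)
  # direct re-check that dropping any one enzyme merges some pair
  for (e in mp$enzymes) {
    sub <- setdiff(mp$enzymes, e)
    reduced <- lapply(panel, function(p) p[intersect(names(p), sub)])
    merged <- any(vapply(utils::combn(8, 2, simplify = FALSE), function(ij) {
      a <- reduced[[ij[1]]]; b <- reduced[[ij[2]]]
      shared <- intersect(names(a), names(b))
      length(shared) == 0 ||
        compare_patterns(a[shared], b[shared], exact_config())$overall
    }, logical(1)))
    expect_true(merged)
  }
})

test_that("restricted panels need fewer enzymes", {
  two <- panel[c("Thunnus thynnus", "Thunnus maccoyii")]
  attr(two, "meta") <- attr(panel, "meta")
  mp <- minimal_panel(two)
  expect_equal(mp$enzymes, "MboI")  # only their MboI rows differ
  expect_equal(mp$size, 1L)

  one <- panel["Thunnus thynnus"]
  mp1 <- minimal_panel(one)
  expect_equal(mp1$size, 0L)
  expect_true(mp1$discriminating)
})

test_that("fixture amplicons round-trip through digestion and identification", {
  for (sp in names(panel)) {
    for (seed in c(2, 9, 123)) {
      amp <- build_amplicon(sp, seed = seed)
      res <- identify_species(amp, panel, cfg)
      expect_equal(res$call, sp)
    }
  }
})

test_that("cohort classification flags mislabeled samples and handles edge cases", {
  empty <- classify_cohort(list())
  expect_equal(nrow(empty$results), 0)

  # pattern-only and amplicon samples work without amplification
  set.seed(55)
  samples <- list(
    list(id = "p1", label = "southern bluefin tuna",
         pattern = panel[["Thunnus maccoyii"]]),
    list(id = "p2", label = "yellowfin tuna",
         pattern = panel[["Thunnus obesus"]]),
    list(id = "a1", amplicon = build_amplicon("Xiphias gladius", seed = 6)),
    list(id = "t1", label = "bigeye tuna",
         template = dna_seq(random_seq(400), id = "t1"))
  )
  out <- classify_cohort(samples)
  expect_equal(out$results$call[1], "Thunnus maccoyii")
  expect_false(out$results$mislabeled[1])
  expect_true(out$results$mislabeled[2])       # obesus sold as yellowfin
  expect_equal(out$results$call[3], "Xiphias gladius")
  expect_true(is.na(out$results$mislabeled[3]))  # unlabeled
  expect_equal(out$results$call[4], "no amplification")
  # non-amplifying sample excluded from the concordance denominator
  expect_false("no amplification" %in% colnames(out$concordance))
})
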