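test_that("the chain fixture matches fully in WFO but only once in BGCI", {
  fx <- synonym_chain_fixture()
  wfo <- matching(fx$input, fx$db, backbone = "WFO")
  expect_true(all(wfo$direct_match))
  expect_true(all(wfo$matched))
  expect_identical(wfo$Matched.Genus, wfo$Orig.Genus)

  bgci <- matching(fx$input, fx$db, backbone = "BGCI")
  expect_identical(sum(bgci$matched), 1L)
  expect_identical(bgci$Matched.Genus[bgci$matched], "Maranthes")
  # a name present only in deselected backbones is not matched
  expect_false(bgci$matched[bgci$Orig.Genus == "Parinari"])
})

test_that("audit columns record which stage ran and which succeeded", {
  fx <- synonym_chain_fixture()
  res <- matching(fx$input, fx$db, backbone = "BGCI")
  row <- res[res$Orig.Genus == "Parinari", ]
  expect_false(row$direct_match)
  expect_false(row$genus_match)          # Parinari genus absent from BGCI
  expect_false(row$fuzzy_match_genus)
  expect_true(is.na(row$direct_match_species_within_genus))
  direct <- res[res$Orig.Genus == "Maranthes", ]
  expect_true(direct$direct_match)
  expect_true(all(is.na(direct[, setdiff(dendronym:::stage_columns(),
                                         "direct_match")])))
})

small_db <- function() {
  close_database(rbind(
    make_records("1", "WFO", "Quercus", "robur"),
    make_records("2", "WFO", "Picea", "glaucum"),
    make_records("3", "WFO", "Pinus", "sylvestre"),
    make_records("4", "WFO", "Acer", "platanodes"),
    make_records("5", "WFO", "Acer", "ruber"),
    make_records("6", "WFO", "Acer", "rubra"),
    make_records("7", "WFO", "Alnus", "incana"),
    make_records("8", "WFO", "Abnus", "incana")))
}

test_that("a transposed genus is rescued by fuzzy genus matching", {
  res <- matching(data.frame(Genus = "Quecrus", Species = "robur"), small_db())
  expect_true(res$matched)
  expect_identical(res$Matched.Genus, "Quercus")
  expect_true(res$fuzzy_match_genus)
  expect_true(res$direct_match_species_within_genus)
  expect_false(res$genus_match)
})

test_that("fuzzy genus candidates are ranked alphabetically and flagged", {
  res <- matching(data.frame(Genus = "Anus", Species = "incana"), small_db())
  expect_identical(res$Matched.Genus, "Abnus")  # Abnus < Alnus
  expect_match(res$ambiguity_note, "Abnus, Alnus")
  far <- matching(data.frame(Genus = "Xyzabc", Species = "robur"), small_db())
  expect_false(far$matched)
  expect_false(far$fuzzy_match_genus)
})

test_that("suffix substitution swaps gender endings but nothing else", {
  res <- matching(data.frame(Genus = "Picea", Species = "glauca"), small_db())
  expect_true(res$suffix_match_species_within_genus)
  expect_identical(res$Matched.Species, "glaucum")

  # "e" is not in the suffix set, so sylvestris -> sylvestre must fall
  # through to the fuzzy stage
  res2 <- matching(data.frame(Genus = "Pinus", Species = "sylvestris"),
                   small_db())
  expect_false(res2$suffix_match_species_within_genus)
  expect_true(res2$fuzzy_match_species_within_genus)
  expect_identical(res2$Matched.Species, "sylvestre")
})

test_that("fuzzy epithet matching prefers smaller distance, then alphabet", {
  res <- matching(data.frame(Genus = "Acer", Species = "platanoides"),
                  small_db())
  expect_true(res$fuzzy_match_species_within_genus)
  expect_identical(res$Matched.Species, "platanodes")

  tie <- matching(data.frame(Genus = "Acer", Species = "rubr"), small_db())
  expect_identical(tie$Matched.Species, "ruber")  # ruber < rubra at distance 1
  expect_match(tie$ambiguity_note, "ruber, rubra")

  none <- matching(data.frame(Genus = "Quercus", Species = "xxxxxxxx"),
                   small_db())
  expect_false(none$matched)
  expect_false(none$fuzzy_match_species_within_genus)
})

test_that("empty input yields an empty, well-formed result", {
  res <- matching(data.frame(Genus = character(0), Species = character(0)),
                  small_db())
  expect_identical(nrow(res), 0L)
  expect_true(all(c("Matched.Genus", "matched",
                    dendronym:::stage_columns()) %in% names(res)))
})

test_that("cascade invariants hold under fuzzing", {
  sim <- generate_synthetic_backbones(n_accepted = 60, misspelling_rate = 0.3,
                                      synonyms_per_accepted = 1, seed = 11)
  db <- suppressMessages(synthetic_unified_db(sim))
  res <- matching(sim$input, db)
  match_stages <- c("direct_match", "direct_match_species_within_genus",
                    "suffix_match_species_within_genus",
                    "fuzzy_match_species_within_genus")
  genus_stages <- c("genus_match", "fuzzy_match_genus")
  for (i in seq_len(nrow(res))) {
    expect_lte(sum(unlist(res[i, match_stages]), na.rm = TRUE), 1L)
    expect_lte(sum(unlist(res[i, genus_stages]), na.rm = TRUE), 1L)
    expect_identical(res$matched[i], !is.na(res$Matched.Genus[i]))
    # a stage column is non-NA only when the cascade actually got there
    if (isTRUE(res$direct_match[i]))
      expect_true(all(is.na(unlist(res[i, c(genus_stages, match_stages[-1])]))))
    if (!is.na(res$fuzzy_match_genus[i]))
      expect_false(res$genus_match[i])
    if (isTRUE(res$fuzzy_match_genus[i]))
      expect_lte(osa_distance(res$Orig.Genus[i], res$Matched.Genus[i]), 1L)
    if (isTRUE(res$fuzzy_match_species_within_genus[i]))
      expect_lte(osa_distance(res$Orig.Species[i], res$Matched.Species[i]), 2L)
    if (isTRUE(res$direct_match[i])) {
      expect_identical(res$Matched.Genus[i], res$Orig.Genus[i])
      expect_identical(res$Matched.Species[i], res$Orig.Species[i])
    }
  }
})

test_that("matching is deterministic and row-order equivariant", {
  sim <- generate_synthetic_backbones(n_accepted = 40, misspelling_rate = 0.2,
                                      seed = 3)
  db <- suppressMessages(synthetic_unified_db(sim))
  res1 <- matching(sim$input, db)
  res2 <- matching(sim$input, db)
  expect_identical(res1, res2)
  perm <- sample(nrow(sim$input))
  res3 <- matching(sim$input[perm, , drop = FALSE], db)
  rownames(res3) <- NULL
  expect_identical(res3, {
    r <- res1[perm, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
})

test_that("sequential matching honours the backbone order", {
  db <- close_database(rbind(
    make_records("w1", "WFO", "Acer", "rubrum"),
    make_records("b1", "BGCI", "Fagus", "sylvatica"),
    make_records("w2", "WFO", "Fagus", "sylvatica")))
  input <- data.frame(Genus = c("Acer", "Fagus", "Pinus"),
                      Species = c("rubrum", "sylvatica", "nigra"))

  res <- sequential_matching(input, db, c("BGCI", "WFO"))
  expect_identical(res$Matched.Backbone, c("WFO", "BGCI", NA))
  expect_identical(res$matched, c(TRUE, TRUE, FALSE))

  # a single-backbone order degenerates to plain matching
  seq1 <- sequential_matching(input, db, "WFO")
  one <- matching(input, db, backbone = "WFO")
  expect_identical(seq1[names(one)], one)
})
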