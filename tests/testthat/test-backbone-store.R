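dwc_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "taxonID,genus,specificEpithet,infraspecificEpithet,taxonRank,taxonomicStatus,acceptedNameUsageID,scientificNameAuthorship"
  writeLines(c(header, rows), path)
  path
}

test_that("reading a dump keeps accepted and synonym rows, drops the rest", {
  path <- dwc_csv(c(
    "t1,Acer,rubrum,,Species,Accepted,,L.",
    "t2,Acer,rubra,,Species,Homotypic Synonym,t1,auct.",
    "t3,Acer,dubium,,Species,Doubtful,,"))
  rec <- suppressMessages(read_backbone_table(path, "WFO"))
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$status, c("Accepted", "Synonym"))
  expect_identical(attr(rec, "dropped"), 1L)
})

test_that("an empty file with a header yields an empty record set", {
  path <- dwc_csv(character(0))
  rec <- read_backbone_table(path, "WCVP")
  expect_identical(nrow(rec), 0L)
})

test_that("BGCI binomial lists are read as accepted species names", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("TaxonName", "Maranthes corymbosa", "Acer rubrum"), path)
  rec <- read_backbone_table(path, "BGCI")
  expect_identical(nrow(rec), 2L)
  expect_true(all(rec$status == "Accepted"))
  expect_true(all(is.na(rec$accepted_source_id)))
})

test_that("a missing mandatory column is reported by name", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("taxonID,genus", "t1,Acer"), path)
  expect_error(read_backbone_table(path, "WFO"), "specificEpithet")
})

test_that("infraspecific rows are kept as such; other ranks are dropped", {
  path <- dwc_csv(c(
    "t1,Abies,magnifica,,Species,Accepted,,",
    "t2,Abies,magnifica,shastensis,variety,Accepted,,",
    "t3,Abies,,,Genus,Accepted,,"))
  rec <- suppressMessages(read_backbone_table(path, "WFO"))
  expect_identical(nrow(rec), 2L)
  expect_identical(sort(rec$rank), c("infraspecific", "species"))
  expect_identical(rec$infra_epithet[rec$rank == "infraspecific"], "shastensis")
})

test_that("genus filtering is a plain allow-list membership test", {
  rec <- make_records(c("1", "2"), "WFO", c("Acer", "Poa"),
                      c("rubrum", "annua"))
  expect_identical(filter_by_genera(rec, "Acer")$genus, "Acer")
  expect_identical(nrow(filter_by_genera(rec, c("Acer", "Poa"))), 2L)
  genera5 <- c("Acer", "Poa", "Abies", "Fagus", "Alnus")
  rec5 <- make_records(as.character(1:10), "WFO",
                       rep(genera5, 2), paste0("sp", 1:10))
  kept <- filter_by_genera(rec5, c("Abies", "Poa"))
  expect_setequal(unique(kept$genus), c("Abies", "Poa"))
  expect_identical(nrow(kept), 4L)
})

test_that("closure pulls cross-genus synonyms and accepted targets back in", {
  # rule 2: a kept synonym's accepted name outside the genus list is added
  wcvp <- make_records(c("c1", "c2"), "WCVP",
                       genus = c("Parinari", "Maranthes"),
                       epithet = c("racemosa", "corymbosa"),
                       status = c("Synonym", "Accepted"),
                       accepted_source_id = c("c2", NA))
  db <- close_database(filter_by_genera(wcvp, "Parinari"), wcvp)
  expect_true("Maranthes corymbosa" %in% db$names$binomial)

  # rule 1: a synonym in a non-listed genus pointing at a kept accepted name
  wfo <- make_records(c("w1", "w2"), "WFO",
                      genus = c("Acer", "Poa"),
                      epithet = c("rubrum", "fakeum"),
                      status = c("Accepted", "Synonym"),
                      accepted_source_id = c(NA, "w1"))
  db2 <- close_database(filter_by_genera(wfo, "Acer"), wfo)
  expect_true("Poa fakeum" %in% db2$names$binomial)
})

test_that("closure is idempotent and IDs ignore input row order", {
  for (seed in 1:5) {
    rec <- random_store_records(seed = seed)
    db <- close_database(rec)
    db2 <- close_database(db$records[, dendronym:::record_columns()])
    expect_identical(db2$names, db$names)
    expect_identical(nrow(db2$records), nrow(db$records))

    shuffled <- rec[sample(nrow(rec)), , drop = FALSE]
    db3 <- close_database(shuffled)
    expect_identical(db3$names$binomial, db$names$binomial)
    expect_identical(db3$names$id, db$names$id)
  }
})

test_that("IDs are the lexicographic rank of the binomial", {
  rec <- make_records(c("1", "2", "3"), "WFO",
                      c("Fagus", "Acer", "Acer"),
                      c("sylvatica", "rubrum", "campestre"))
  db <- close_database(rec)
  expect_identical(db$names$binomial,
                   c("Acer campestre", "Acer rubrum", "Fagus sylvatica"))
  expect_identical(db$names$id, 1:3)
})

test_that("dangling synonym pointers are dropped with a warning", {
  rec <- make_records(c("1", "2"), "WFO", "Acer", c("rubrum", "ghostum"),
                      status = c("Accepted", "Synonym"),
                      accepted_source_id = c(NA, "nonexistent"))
  expect_warning(db <- close_database(rec), "unresolvable")
  expect_false("Acer ghostum" %in% db$names$binomial)
})

test_that("the status crosstab counts each binomial once", {
  fx <- synonym_chain_fixture()
  ct <- status_crosstab(fx$db)
  expect_identical(sum(ct), nrow(fx$db$names))
  expect_identical(sum(ct), 4L)
  # Parinari racemosa: synonym-only in WCVP, accepted in WFO, absent in GBIF
  expect_identical(unname(ct["Accepted", "NotAccepted", "Missing"]), 1L)
  # Maranthes corymbosa: accepted in WFO and WCVP
  expect_identical(unname(ct["Accepted", "Accepted", "Missing"]), 1L)
  # the two Atuna synonyms live only in WFO
  expect_identical(unname(ct["NotAccepted", "Missing", "Missing"]), 2L)

  empty <- unified_db(dendronym:::empty_records())
  expect_identical(sum(status_crosstab(empty)), 0L)

  one <- close_database(rbind(
    make_records("w", "WFO", "Acer", "rubrum"),
    make_records("c", "WCVP", "Acer", "rubrum"),
    make_records("g", "GBIF", "Acer", "rubrum")))
  expect_identical(unname(status_crosstab(one)["Accepted", "Accepted", "Accepted"]), 1L)
})

test_that("a binomial with accepted and synonym homonyms indexes as Accepted", {
  rec <- rbind(
    make_records("1", "WFO", "Ilex", "subrotundifolia"),
    make_records("2", "WFO", "Ilex", "subrotundifolia",
                 status = "Synonym", accepted_source_id = "3"),
    make_records("3", "WFO", "Ilex", "crenata"))
  db <- close_database(rec)
  id <- match("Ilex subrotundifolia", db$names$binomial)
  expect_identical(unname(db$status[id, "WFO"]), "Accepted")
})

test_that("the store serializes and reloads byte-identically", {
  fx <- synonym_chain_fixture()
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_unified_db(fx$db, p1)
  db2 <- read_unified_db(p1)
  write_unified_db(db2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(db2$names, fx$db$names)
  expect_identical(db2$status, fx$db$status)
  expect_error(read_unified_db(dwc_csv("t1,Acer,rubrum,,Species,Accepted,,")),
               "format header")
})
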