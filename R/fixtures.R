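## Small built-in stores encoding fully-specified worked examples, so every
## stage of the pipeline is exercisable without any backbone download.

# terse record constructor for fixtures and tests
make_records <- function(source_id, backbone, genus, epithet,
                         status = "Accepted", accepted_source_id = NA,
                         rank = "species", infra_rank = NA,
                         infra_epithet = NA, authorship = NA) {
  n <- length(source_id)
  data.frame(source_id = as.character(source_id),
             backbone = rep_len(backbone, n),
             genus = rep_len(genus, n),
             epithet = rep_len(epithet, n),
             rank = rep_len(rank, n),
             infra_rank = rep_len(as.character(infra_rank), n),
             infra_epithet = rep_len(as.character(infra_epithet), n),
             authorship = rep_len(as.character(authorship), n),
             status = rep_len(status, n),
             accepted_source_id = rep_len(as.character(accepted_source_id), n),
             stringsAsFactors = FALSE)
}

#' Four-species synonym-chain fixture
#'
#' A minimal store exhibiting the canonical cross-backbone chain: WFO
#' links *Atuna racemosa* to *Atuna excelsa* to the accepted *Parinari
#' racemosa*; WCVP holds *Parinari racemosa* as a synonym of the accepted
#' *Maranthes corymbosa*; BGCI contains only *Maranthes corymbosa*. All
#' four names match WFO (and WCVP where present) directly, but only one is
#' in BGCI — forcing the other three into BGCI walks the synonym graph at
#' depths 1 (*Parinari racemosa*), 2 (*Atuna excelsa*) and 3 (*Atuna
#' racemosa*), all landing on *Maranthes corymbosa*.
#'
#' @return List with elements `db` (a `unified_db`) and `input` (the
#'   four-species query table).
#' @export
#' @examples
#' fx <- synonym_chain_fixture()
#' res <- matching(fx$input, fx$db, backbone = "BGCI")
#' enforce_matching(res, fx$db, "BGCI")
synonym_chain_fixture <- function() {
  wfo <- make_records(c("w1", "w2", "w3", "w4"), "WFO",
                      genus = c("Parinari", "Atuna", "Atuna", "Maranthes"),
                      epithet = c("racemosa", "excelsa", "racemosa", "corymbosa"),
                      status = c("Accepted", "Synonym", "Synonym", "Accepted"),
                      accepted_source_id = c(NA, "w1", "w2", NA),
                      authorship = c("Raddi", "(Jack) Kosterm.", "Raddi",
                                     "(Blume) Prance"))
  wcvp <- make_records(c("c1", "c2"), "WCVP",
                       genus = c("Maranthes", "Parinari"),
                       epithet = c("corymbosa", "racemosa"),
                       status = c("Accepted", "Synonym"),
                       accepted_source_id = c(NA, "c1"))
  bgci <- make_records("b1", "BGCI", "Maranthes", "corymbosa")
  input <- data.frame(
    Genus = c("Parinari", "Atuna", "Atuna", "Maranthes"),
    Species = c("racemosa", "racemosa", "excelsa", "corymbosa"),
    stringsAsFactors = FALSE)
  list(db = close_database(rbind(wfo, wcvp, bgci)), input = input)
}

#' Three-species translation fixture
#'
#' Encodes the relations behind the worked list-to-list translation:
#' WFO holds *Ardisia montana* as a synonym of *Ardisia japonica* (and
#' *Aria umbellata*, *Malus sylvestris*, *Sorbus umbellata* as accepted);
#' WCVP holds *Aria umbellata* as a synonym of *Sorbus umbellata*; GBIF
#' holds *Malus orientalis* as a synonym of *Malus sylvestris*. Resolving
#' input and target lists separately against WFO leaves them inconsistent,
#' while [translate_trees()] bridges all three pairs at graph depth 1.
#'
#' @return List with `db`, `input` and `target` elements.
#' @export
translation_fixture <- function() {
  wfo <- make_records(c("f1", "f2", "f3", "f4", "f5"), "WFO",
                      genus = c("Ardisia", "Ardisia", "Aria", "Malus", "Sorbus"),
                      epithet = c("japonica", "montana", "umbellata",
                                  "sylvestris", "umbellata"),
                      status = c("Accepted", "Synonym", "Accepted",
                                 "Accepted", "Accepted"),
                      accepted_source_id = c(NA, "f1", NA, NA, NA))
  wcvp <- make_records(c("v1", "v2"), "WCVP",
                       genus = c("Sorbus", "Aria"),
                       epithet = c("umbellata", "umbellata"),
                       status = c("Accepted", "Synonym"),
                       accepted_source_id = c(NA, "v1"))
  gbif <- make_records(c("g1", "g2"), "GBIF",
                       genus = c("Malus", "Malus"),
                       epithet = c("sylvestris", "orientalis"),
                       status = c("Accepted", "Synonym"),
                       accepted_source_id = c(NA, "g1"))
  input <- data.frame(Genus = c("Aria", "Ardisia", "Malus"),
                      Species = c("umbellata", "japonica", "sylvestris"),
                      stringsAsFactors = FALSE)
  target <- data.frame(Genus = c("Sorbus", "Ardisia", "Malus"),
                       Species = c("umbellata", "montana", "orientalis"),
                       stringsAsFactors = FALSE)
  list(db = close_database(rbind(wfo, wcvp, gbif)), input = input,
       target = target)
}

#' Infraspecific / homonym flag fixture
#'
#' A store with the metadata patterns that trigger each
#' [highlight_flags()] flag. In WFO, *Abies shastensis* is a synonym of
#' the variety *Abies magnifica* var. *shastensis* and so resolves to
#' *Abies magnifica* through a trinomial (`infraspecific_link`), while
#' *Abies balsamea* carries the variety *Abies balsamea* var. *fraseri*,
#' a synonym of *Abies fraseri* (`infraspecific_ambiguity`). In WCVP,
#' *Abies excelsa* exists as two homonymous synonym records resolving to
#' different species (`authorship_ambiguity`).
#'
#' @return List with `db` and `input` elements.
#' @export
flags_fixture <- function() {
  wfo <- rbind(
    make_records("a1", "WFO", "Abies", "magnifica", authorship = "Murray"),
    make_records("a2", "WFO", "Abies", "magnifica",
                 rank = "infraspecific", infra_rank = "variety",
                 infra_epithet = "shastensis", authorship = "Lemmon"),
    make_records("a3", "WFO", "Abies", "shastensis",
                 status = "Synonym", accepted_source_id = "a2",
                 authorship = "Lemmon"),
    make_records("a4", "WFO", "Abies", "balsamea", authorship = "Mill."),
    make_records("a5", "WFO", "Abies", "fraseri", authorship = "Poir."),
    make_records("a6", "WFO", "Abies", "balsamea",
                 rank = "infraspecific", infra_rank = "variety",
                 infra_epithet = "fraseri", status = "Synonym",
                 accepted_source_id = "a5", authorship = "Spach"))
  wcvp <- rbind(
    make_records("h1", "WCVP", "Abies", "excelsa",
                 status = "Synonym", accepted_source_id = "hA",
                 authorship = "Lam."),
    make_records("h2", "WCVP", "Abies", "excelsa",
                 status = "Synonym", accepted_source_id = "hB",
                 authorship = "Poir."),
    make_records("hA", "WCVP", "Picea", "abies", authorship = "Karst."),
    make_records("hB", "WCVP", "Abies", "alba", authorship = "Mill."))
  input <- data.frame(
    Genus = c("Abies", "Abies", "Abies"),
    Species = c("shastensis", "balsamea", "excelsa"),
    stringsAsFactors = FALSE)
  list(db = close_database(rbind(wfo, wcvp)), input = input)
}
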