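## Deterministic synthetic-backbone generator: emits per-backbone tables in
## the ingestion dialects together with a ground-truth mapping, so the whole
## pipeline can be validated against known answers.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# pseudo-Latin tokens from consonant-vowel syllables; distinct by rejection
make_latin_tokens <- function(n, n_syllables = 3L) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    need <- (n - length(out)) * 2L
    tk <- vapply(seq_len(need), function(i)
      paste0(sample(cons, n_syllables, TRUE), sample(vow, n_syllables, TRUE),
             collapse = ""), character(1))
    out <- unique(c(out, tk))
  }
  out[seq_len(n)]
}

# one random unit edit (substitution, insertion, deletion or adjacent
# transposition) on a lower-case token, guaranteed to change it
random_edit <- function(x) {
  letters_pool <- letters
  ch <- strsplit(x, "")[[1]]
  n <- length(ch)
  repeat {
    op <- sample(c("sub", "ins", "del", "tra"), 1L)
    y <- switch(op,
      sub = {
        i <- sample.int(n, 1L)
        ch2 <- ch; ch2[i] <- sample(setdiff(letters_pool, ch[i]), 1L)
        paste(ch2, collapse = "")
      },
      ins = {
        i <- sample.int(n + 1L, 1L)
        paste(c(ch[seq_len(i - 1L)], sample(letters_pool, 1L),
                ch[seq_len(n)[seq_len(n) >= i]]), collapse = "")
      },
      del = if (n >= 2L) {
        i <- sample.int(n, 1L)
        paste(ch[-i], collapse = "")
      } else x,
      tra = if (n >= 2L) {
        i <- sample.int(n - 1L, 1L)
        ch2 <- ch; ch2[c(i, i + 1L)] <- ch2[c(i + 1L, i)]
        paste(ch2, collapse = "")
      } else x)
    if (y != x) return(y)
  }
}

#' Generate synthetic backbones with known ground truth
#'
#' Simulates an accepted species pool shared (with partial overlap) across
#' WFO, WCVP, GBIF and BGCI, attaches synonym records with valid pointers,
#' optionally injects homonymous records and infraspecific varieties, and
#' emits a query list in which a fraction of epithets carry a single
#' random edit (substitution, insertion, deletion or transposition — one
#' unit of optimal string alignment distance). The true accepted name of
#' every query is returned alongside, so matching and resolution accuracy
#' can be measured exactly. Output is a pure function of the parameters
#' and `seed`.
#'
#' @param n_accepted Number of accepted species (default 150).
#' @param synonyms_per_accepted Mean number of synonym names per accepted
#'   species (Poisson; default 0.5, echoing the roughly 40\% disagreement
#'   between published checklists).
#' @param misspelling_rate Fraction of queries receiving one random edit.
#' @param homonym_rate Fraction of accepted binomials duplicated as a
#'   conflicting homonymous synonym record.
#' @param infraspecific_rate Fraction of accepted binomials given a
#'   variety record that resolves to a different species.
#' @param backbone_overlap Probability that an accepted species present in
#'   WFO is also present in each of WCVP, GBIF and BGCI (default 0.8).
#' @param seed Integer seed; identical calls yield identical output.
#' @return List with `tables` (named list of per-backbone data.frames in
#'   their ingestion dialect), `genera` (the genus allow-list), `input`
#'   (query table with `Genus`/`Species`), `truth` (queries plus
#'   `True.Genus`/`True.Species`), and `params`.
#' @export
generate_synthetic_backbones <- function(n_accepted = 150L,
                                         synonyms_per_accepted = 0.5,
                                         misspelling_rate = 0.1,
                                         homonym_rate = 0,
                                         infraspecific_rate = 0,
                                         backbone_overlap = 0.8,
                                         seed = 1L) {
  rates <- c(misspelling_rate, homonym_rate, infraspecific_rate,
             backbone_overlap)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (n_accepted < 2L || synonyms_per_accepted < 0)
    stop("need n_accepted >= 2 and synonyms_per_accepted >= 0", call. = FALSE)

  with_seed(seed, {
    n_genera <- max(3L, ceiling(n_accepted / 8))
    genera <- make_latin_tokens(n_genera, 2L)
    genera <- paste0(toupper(substr(genera, 1, 1)), substring(genera, 2))
    # pseudo-Latin gender endings so the suffix stage has work to do
    endings <- c("a", "um", "us", "is", "i", "ae", "")
    epithet_pool <- character(0)
    while (length(epithet_pool) < n_accepted * 4L) {
      base <- make_latin_tokens(n_accepted * 5L, 3L)
      epithet_pool <- unique(c(epithet_pool,
                               paste0(base, sample(endings, length(base), TRUE))))
    }

    acc <- data.frame(genus = sample(genera, n_accepted, TRUE),
                      epithet = epithet_pool[seq_len(n_accepted)],
                      stringsAsFactors = FALSE)
    pool_left <- epithet_pool[-seq_len(n_accepted)]
    in_wcvp <- runif(n_accepted) < backbone_overlap
    in_gbif <- runif(n_accepted) < backbone_overlap
    in_bgci <- runif(n_accepted) < backbone_overlap

    rec <- list()
    next_id <- 1L
    add <- function(backbone, genus, epithet, status = "Accepted",
                    acc_id = NA_character_, rank = "species",
                    infra_epithet = NA_character_, authorship = NA_character_) {
      id <- sprintf("%s%04d", tolower(substr(backbone, 1, 1)), next_id)
      next_id <<- next_id + 1L
      rec[[length(rec) + 1L]] <<- make_records(
        id, backbone, genus, epithet, status = status,
        accepted_source_id = acc_id, rank = rank,
        infra_rank = if (rank == "infraspecific") "variety" else NA,
        infra_epithet = infra_epithet, authorship = authorship)
      id
    }

    acc$wfo_id <- vapply(seq_len(n_accepted), function(i)
      add("WFO", acc$genus[i], acc$epithet[i], authorship = "L."),
      character(1))
    acc$wcvp_id <- NA_character_
    acc$gbif_id <- NA_character_
    for (i in which(in_wcvp))
      acc$wcvp_id[i] <- add("WCVP", acc$genus[i], acc$epithet[i])
    for (i in which(in_gbif))
      acc$gbif_id[i] <- add("GBIF", acc$genus[i], acc$epithet[i])
    for (i in which(in_bgci))
      add("BGCI", acc$genus[i], acc$epithet[i])

    n_syn <- rpois(n_accepted, synonyms_per_accepted)
    syn <- NULL
    k <- 0L
    for (i in seq_len(n_accepted)) {
      for (s in seq_len(n_syn[i])) {
        k <- k + 1L
        sg <- if (runif(1) < 0.7) acc$genus[i] else sample(genera, 1L)
        se <- pool_left[k]
        # the synonym lives in a backbone that also holds its accepted name
        bbs <- c("WFO", if (in_wcvp[i]) "WCVP", if (in_gbif[i]) "GBIF")
        bb <- sample(bbs, 1L)
        tid <- switch(bb, WFO = acc$wfo_id[i], WCVP = acc$wcvp_id[i],
                      GBIF = acc$gbif_id[i])
        add(bb, sg, se, status = "Synonym", acc_id = tid)
        syn <- rbind(syn, data.frame(genus = sg, epithet = se, target = i,
                                     stringsAsFactors = FALSE))
      }
    }

    for (i in which(runif(n_accepted) < homonym_rate)) {
      j <- sample(setdiff(seq_len(n_accepted), i), 1L)
      add("WFO", acc$genus[i], acc$epithet[i], status = "Synonym",
          acc_id = acc$wfo_id[j], authorship = "auct.")
    }
    for (i in which(runif(n_accepted) < infraspecific_rate)) {
      j <- sample(setdiff(seq_len(n_accepted), i), 1L)
      add("WFO", acc$genus[i], acc$epithet[i], status = "Synonym",
          acc_id = acc$wfo_id[j], rank = "infraspecific",
          infra_epithet = pool_left[k + i], authorship = "L.")
    }

    records <- do.call(rbind, rec)

    queries <- rbind(
      data.frame(genus = acc$genus, epithet = acc$epithet,
                 tg = acc$genus, te = acc$epithet, stringsAsFactors = FALSE),
      if (!is.null(syn))
        data.frame(genus = syn$genus, epithet = syn$epithet,
                   tg = acc$genus[syn$target], te = acc$epithet[syn$target],
                   stringsAsFactors = FALSE))
    mis <- runif(nrow(queries)) < misspelling_rate
    queries$epithet[mis] <- vapply(queries$epithet[mis], random_edit,
                                   character(1))

    tables <- lapply(setNames(backbone_names(), backbone_names()),
                     function(bb) records_to_dialect(
                       records[records$backbone == bb, , drop = FALSE], bb))
    list(tables = tables,
         genera = genera,
         input = data.frame(Genus = queries$genus, Species = queries$epithet,
                            stringsAsFactors = FALSE),
         truth = data.frame(Genus = queries$genus, Species = queries$epithet,
                            True.Genus = queries$tg, True.Species = queries$te,
                            stringsAsFactors = FALSE),
         params = list(n_accepted = n_accepted,
                       synonyms_per_accepted = synonyms_per_accepted,
                       misspelling_rate = misspelling_rate,
                       homonym_rate = homonym_rate,
                       infraspecific_rate = infraspecific_rate,
                       backbone_overlap = backbone_overlap, seed = seed))
  })
}

# canonical records -> the delimited dialect read_backbone_table() expects
records_to_dialect <- function(records, backbone) {
  if (backbone == "BGCI") {
    return(data.frame(TaxonName = binomial_of(records$genus, records$epithet),
                      stringsAsFactors = FALSE))
  }
  rank_out <- ifelse(records$rank == "species", "Species",
                     ifelse(is.na(records$infra_rank), "variety",
                            records$infra_rank))
  data.frame(taxonID = records$source_id,
             genus = records$genus,
             specificEpithet = records$epithet,
             infraspecificEpithet = ifelse(is.na(records$infra_epithet), "",
                                           records$infra_epithet),
             taxonRank = rank_out,
             taxonomicStatus = records$status,
             acceptedNameUsageID = ifelse(is.na(records$accepted_source_id), "",
                                          records$accepted_source_id),
             scientificNameAuthorship = ifelse(is.na(records$authorship), "",
                                               records$authorship),
             stringsAsFactors = FALSE)
}

#' Ingest a synthetic simulation into a unified database
#'
#' Round-trips the dialect tables of [generate_synthetic_backbones()]
#' through temporary files and [read_backbone_table()], applies the genus
#' filter and the self-containment closure, and returns the resulting
#' store — the exact pipeline a user would run on real dumps.
#'
#' @param sim Output of [generate_synthetic_backbones()].
#' @return A `unified_db`.
#' @export
synthetic_unified_db <- function(sim) {
  recs <- lapply(backbone_names(), function(bb) {
    tb <- sim$tables[[bb]]
    if (nrow(tb) == 0L) return(empty_records())
    path <- tempfile(fileext = ".csv")
    on.exit(unlink(path))
    write.csv(tb, path, row.names = FALSE)
    read_backbone_table(path, bb)
  })
  unfiltered <- do.call(rbind, recs)
  filtered <- filter_by_genera(unfiltered, sim$genera)
  close_database(filtered, unfiltered)
}
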