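## Ingestion of per-backbone taxon tables and construction of the unified,
## self-contained, deterministically-ID'd name store.

record_columns <- function() {
  c("source_id", "backbone", "genus", "epithet", "rank", "infra_rank",
    "infra_epithet", "authorship", "status", "accepted_source_id")
}

empty_records <- function() {
  as.data.frame(setNames(rep(list(character(0)), length(record_columns())),
                         record_columns()), stringsAsFactors = FALSE)
}

# statuses kept from the source dumps; everything else (doubtful, unplaced,
# misapplied, ...) is dropped
map_status <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x == "accepted"] <- "Accepted"
  out[x %in% c("synonym", "homotypic synonym", "heterotypic synonym",
               "homotypic_synonym", "heterotypic_synonym")] <- "Synonym"
  out
}

map_rank <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x == "species"] <- "species"
  out[x %in% c("variety", "var.", "var", "subspecies", "subsp.", "subsp",
               "ssp.", "form", "forma", "f.", "subvariety", "subvar.",
               "infraspecies", "infraspecific name")] <- "infraspecific"
  out
}

#' Default column mapping for a backbone dump
#'
#' Returns the named list mapping [read_backbone_table()] record fields to
#' the column headers of a backbone dump. WFO, WCVP and GBIF dumps share a
#' Darwin-Core-style header; the BGCI GlobalTreeSearch export is a plain
#' binomial list with a single `TaxonName` column.
#'
#' @param backbone One of `backbone_names()`.
#' @return Named list usable as the `dialect` argument of
#'   [read_backbone_table()].
#' @export
#' @examples
#' backbone_dialect("WFO")
#' backbone_dialect("BGCI")
backbone_dialect <- function(backbone) {
  backbone <- match.arg(backbone, backbone_names())
  if (backbone == "BGCI") {
    list(binomial = "TaxonName")
  } else {
    list(source_id = "taxonID",
         genus = "genus",
         epithet = "specificEpithet",
         infra_epithet = "infraspecificEpithet",
         rank = "taxonRank",
         status = "taxonomicStatus",
         accepted_source_id = "acceptedNameUsageID",
         authorship = "scientificNameAuthorship")
  }
}

clean_name_tokens <- function(genus, epithet) {
  genus <- fold_token(strip_hybrid(trimws(genus)))
  epithet <- fold_token(strip_hybrid(trimws(epithet)))
  ok <- nzchar(genus) & nzchar(epithet)
  genus <- paste0(toupper(substr(genus, 1L, 1L)),
                  tolower(substr(genus, 2L, nchar(genus))))
  list(genus = genus, epithet = tolower(epithet), ok = ok)
}

#' Read one backbone taxon table
#'
#' Parses a delimited dump of a single backbone into the canonical record
#' format. Rows whose taxonomic status is outside
#' `{Accepted, Synonym, Homotypic Synonym, Heterotypic Synonym}` or whose
#' rank is neither species-level nor a recognized infraspecific rank are
#' dropped (and counted in the `"dropped"` attribute of the result). BGCI
#' rows are always accepted species names. Names are normalized as by
#' [normalize_binomial()].
#'
#' @param path Path to a delimited text file.
#' @param backbone One of `backbone_names()`; stamped on every record.
#' @param dialect Column mapping, defaulting to
#'   [backbone_dialect]`(backbone)`. Must name at least the genus/epithet
#'   (or `binomial`) and, for pointer-bearing backbones, status columns.
#' @param sep Field separator of the file.
#' @return A `data.frame` of backbone records with attribute `"dropped"`
#'   giving the number of discarded rows.
#' @export
read_backbone_table <- function(path, backbone,
                                dialect = backbone_dialect(backbone),
                                sep = ",") {
  backbone <- match.arg(backbone, backbone_names())
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, na.strings = character(0))
  n_in <- nrow(raw)

  getcol <- function(field, required = FALSE) {
    cn <- dialect[[field]]
    if (is.null(cn)) {
      if (required)
        stop(sprintf("dialect for %s does not map required field '%s'",
                     backbone, field), call. = FALSE)
      return(rep("", n_in))
    }
    if (!cn %in% names(raw))
      stop(sprintf("backbone file is missing mandatory column '%s'", cn),
           call. = FALSE)
    trimws(raw[[cn]])
  }

  if (!is.null(dialect$binomial)) {
    bino <- getcol("binomial", required = TRUE)
    tokens <- strsplit(bino, "\\s+")
    ok2 <- lengths(tokens) == 2L
    genus <- vapply(tokens, function(t) if (length(t) >= 1) t[1] else "",
                    character(1))
    epithet <- vapply(tokens, function(t) if (length(t) >= 2) t[2] else "",
                      character(1))
    cl <- clean_name_tokens(genus, epithet)
    keep <- ok2 & cl$ok
    rec <- data.frame(
      source_id = if (!is.null(dialect$source_id))
        getcol("source_id") else as.character(seq_len(n_in)),
      backbone = rep(backbone, n_in),
      genus = cl$genus, epithet = cl$epithet,
      rank = rep("species", n_in),
      infra_rank = rep(NA_character_, n_in),
      infra_epithet = rep(NA_character_, n_in),
      authorship = rep(NA_character_, n_in),
      status = rep("Accepted", n_in),
      accepted_source_id = rep(NA_character_, n_in),
      stringsAsFactors = FALSE)
  } else {
    genus <- getcol("genus", required = TRUE)
    epithet <- getcol("epithet", required = TRUE)
    cl <- clean_name_tokens(genus, epithet)
    status <- map_status(getcol("status", required = TRUE))
    rank_raw <- getcol("rank", required = TRUE)
    rank <- map_rank(rank_raw)
    infra_ep <- tolower(fold_token(getcol("infra_epithet")))
    acc <- getcol("accepted_source_id")
    auth <- getcol("authorship")
    keep <- cl$ok & !is.na(status) & !is.na(rank)
    # infraspecific records need an infraspecific epithet to be usable
    keep <- keep & !(rank %in% "infraspecific" & !nzchar(infra_ep))
    rec <- data.frame(
      source_id = getcol("source_id", required = TRUE),
      backbone = rep(backbone, n_in),
      genus = cl$genus, epithet = cl$epithet,
      rank = rank,
      infra_rank = ifelse(rank %in% "infraspecific", tolower(rank_raw),
                          NA_character_),
      infra_epithet = ifelse(rank %in% "infraspecific" & nzchar(infra_ep),
                             infra_ep, NA_character_),
      authorship = ifelse(nzchar(auth), auth, NA_character_),
      status = status,
      accepted_source_id = ifelse(nzchar(acc), acc, NA_character_),
      stringsAsFactors = FALSE)
    # a synonym must say what it is a synonym of
    keep <- keep & !(rec$status %in% "Synonym" & is.na(rec$accepted_source_id))
  }

  keep[is.na(keep)] <- FALSE
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- n_in - nrow(out)
  if (dropped > 0L)
    message(sprintf("%s: dropped %d of %d rows (unmappable status/rank or malformed name)",
                    backbone, dropped, n_in))
  attr(out, "dropped") <- dropped
  out
}

#' Filter backbone records to an allow-list of genera
#'
#' Keeps records whose genus is in `genera` (compared on normalized
#' genus spelling). This is the tree-genus filter applied to the raw dumps
#' before the self-containment closure pulls cross-genus synonyms back in.
#'
#' @param records Record `data.frame` from [read_backbone_table()].
#' @param genera Non-empty character vector of genus names.
#' @return The filtered record `data.frame`.
#' @export
filter_by_genera <- function(records, genera) {
  if (length(genera) == 0L) stop("`genera` must be non-empty", call. = FALSE)
  genera <- unique(normalize_binomial(genera, "placeholder")$Genus)
  out <- records[records$genus %in% genera, , drop = FALSE]
  rownames(out) <- NULL
  out
}

record_key <- function(records) paste(records$backbone, records$source_id)

#' Build a self-contained unified database
#'
#' Merges genus-filtered per-backbone records and applies the
#' self-containment closure: (1) synonyms of retained accepted names whose
#' genus fell outside the allow-list are pulled back in from the unfiltered
#' records, and (2) accepted targets of retained synonyms are added even
#' when their genus is outside the allow-list. The two rules are iterated
#' to a fixed point, so re-closing a closed database changes nothing.
#' Synonyms whose pointer cannot be resolved even in the unfiltered source
#' are dropped with a warning.
#'
#' Every distinct binomial then receives a dense integer identifier,
#' `ID_matched`, equal to its 1-based rank in lexicographic
#' (genus, epithet) order (C collation). Identical record sets therefore
#' always yield identical identifiers, whatever the input row order — the
#' reproducible tie-break used by [enforce_matching()].
#'
#' @param records A record `data.frame` (or list of them, one per
#'   backbone) after genus filtering.
#' @param unfiltered Optional record `data.frame` (or list) giving access
#'   to the full, unfiltered dumps from which closure rules may pull
#'   additional records. Defaults to `records` itself.
#' @return A `unified_db` object.
#' @export
close_database <- function(records, unfiltered = NULL) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(unfiltered)) unfiltered <- records
  if (is.list(unfiltered) && !is.data.frame(unfiltered))
    unfiltered <- do.call(rbind, unfiltered)

  stopifnot(all(record_columns() %in% names(records)))
  pool <- unique(rbind(unfiltered[, record_columns()],
                       records[, record_columns()]))
  cur <- unique(records[, record_columns()])

  repeat {
    key_cur <- record_key(cur)
    pool_new <- pool[!(record_key(pool) %in% key_cur), , drop = FALSE]
    add <- NULL

    # rule 1: synonyms (anywhere in the source) pointing at a retained record
    syn <- pool_new[pool_new$status == "Synonym" &
                      !is.na(pool_new$accepted_source_id), , drop = FALSE]
    tgt_key <- paste(syn$backbone, syn$accepted_source_id)
    add1 <- syn[tgt_key %in% key_cur, , drop = FALSE]

    # rule 2: accepted targets of retained synonyms
    need <- cur[cur$status == "Synonym" & !is.na(cur$accepted_source_id), ,
                drop = FALSE]
    need_key <- unique(paste(need$backbone, need$accepted_source_id))
    missing_key <- setdiff(need_key, key_cur)
    add2 <- pool_new[record_key(pool_new) %in% missing_key, , drop = FALSE]

    add <- unique(rbind(add1, add2))
    if (nrow(add) == 0L) break
    cur <- rbind(cur, add)
  }

  # drop synonyms whose pointer is unresolvable even in the source pool
  key_cur <- record_key(cur)
  dangling <- cur$status == "Synonym" & !is.na(cur$accepted_source_id) &
    !(paste(cur$backbone, cur$accepted_source_id) %in% key_cur)
  if (any(dangling)) {
    warning(sprintf("dropped %d synonym record(s) with unresolvable accepted-name pointers",
                    sum(dangling)), call. = FALSE)
    cur <- cur[!dangling, , drop = FALSE]
  }
  unified_db(cur)
}

#' Construct a unified database from canonical records
#'
#' Low-level constructor: indexes an already-closed record set. Most users
#' should call [close_database()] instead, which also applies the
#' self-containment closure.
#'
#' @param records Record `data.frame` in canonical form.
#' @return A `unified_db` object with components `records` (the records,
#'   augmented with `binomial_id` and resolved pointer row `target_row`),
#'   `names` (one row per distinct binomial with its `id`), and `status`
#'   (binomial x backbone matrix over `Accepted`/`NotAccepted`/`Missing`).
#' @export
unified_db <- function(records) {
  records <- unique(records[, record_columns()])
  # one record per (backbone, source_id): keep the first occurrence
  records <- records[!duplicated(record_key(records)), , drop = FALSE]
  rownames(records) <- NULL

  bino <- binomial_of(records$genus, records$epithet)
  uniq <- !duplicated(bino)
  nm <- data.frame(genus = records$genus[uniq], epithet = records$epithet[uniq],
                   stringsAsFactors = FALSE)
  ord <- order(nm$genus, nm$epithet, method = "radix")
  nm <- nm[ord, , drop = FALSE]
  nm$binomial <- binomial_of(nm$genus, nm$epithet)
  nm$id <- seq_len(nrow(nm))
  rownames(nm) <- NULL

  records$binomial_id <- nm$id[match(bino, nm$binomial)]
  tr <- match(paste(records$backbone, records$accepted_source_id),
              record_key(records))
  tr[is.na(records$accepted_source_id)] <- NA_integer_
  records$target_row <- tr

  status <- matrix("Missing", nrow = nrow(nm), ncol = 4L,
                   dimnames = list(NULL, backbone_names()))
  sp <- records$rank == "species"
  for (bb in backbone_names()) {
    rows <- sp & records$backbone == bb
    syn_ids <- unique(records$binomial_id[rows & records$status == "Synonym"])
    acc_ids <- unique(records$binomial_id[rows & records$status == "Accepted"])
    status[syn_ids, bb] <- "NotAccepted"
    status[acc_ids, bb] <- "Accepted"  # accepted wins over synonym homonyms
  }

  structure(list(records = records, names = nm, status = status),
            class = "unified_db")
}

#' @export
print.unified_db <- function(x, ...) {
  cat(sprintf("Unified taxonomic name store: %d records, %d distinct binomials\n",
              nrow(x$records), nrow(x$names)))
  for (bb in backbone_names()) {
    n <- sum(x$records$backbone == bb)
    if (n > 0L)
      cat(sprintf("  %s: %d records (%d accepted binomials)\n", bb, n,
                  sum(x$status[, bb] == "Accepted")))
  }
  invisible(x)
}

# ids of binomials with a species-rank record in any of `backbones`
present_ids <- function(db, backbones) {
  st <- db$status[, backbones, drop = FALSE]
  which(rowSums(st != "Missing") > 0L)
}

#' Cross-tabulate binomial status across WFO, WCVP and GBIF
#'
#' Counts every distinct binomial in the database exactly once into a
#' 3x3x3 table of its status (`Accepted`, `NotAccepted`, `Missing`) in
#' each of the three pointer-bearing backbones. A binomial with both an
#' accepted and a synonym record in a backbone counts as `Accepted` there.
#'
#' @param db A `unified_db`.
#' @return A 3-dimensional contingency table with dimensions WFO, WCVP,
#'   GBIF.
#' @export
status_crosstab <- function(db) {
  lv <- c("Accepted", "NotAccepted", "Missing")
  f <- function(bb) factor(db$status[, bb], levels = lv)
  table(WFO = f("WFO"), WCVP = f("WCVP"), GBIF = f("GBIF"))
}

db_format_version <- "dendronym-db v1"

#' Serialize / reload a unified database
#'
#' The store is written as a single CSV with a metadata comment header
#' (format version and record count), and reloads byte-identically:
#' writing a reloaded store reproduces the original file.
#'
#' @param db A `unified_db`.
#' @param path Output (or input) file path.
#' @return `write_unified_db` returns `path` invisibly; `read_unified_db`
#'   returns the reconstructed `unified_db`.
#' @export
write_unified_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", db_format_version),
               sprintf("# records: %d", nrow(db$records))), con)
  write.csv(db$records[, record_columns()], con, row.names = FALSE,
            na = "")
  invisible(path)
}

#' @rdname write_unified_db
#' @export
read_unified_db <- function(path) {
  head <- readLines(path, n = 1L)
  if (!identical(head, paste0("# ", db_format_version)))
    stop("not a dendronym database file (missing format header)",
         call. = FALSE)
  rec <- read.csv(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE, na.strings = character(0))
  for (cn in record_columns())
    rec[[cn]][!nzchar(rec[[cn]])] <- NA_character_
  unified_db(rec)
}
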