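## Resolution of matched names to accepted names under a user-defined
## backbone priority order.

# Resolve one binomial inside one backbone.
#
# Returns NULL when the backbone has no usable species-rank record for the
# binomial or every pointer chain is dangling. Otherwise a list:
#   id         chosen accepted binomial id
#   via_infra  TRUE when some chain to the chosen id passes through an
#              infraspecific (trinomial) record
#   ambiguous  TRUE when distinct species-rank records resolved to
#              different binomials
#   candidates all distinct terminal ids
# A binomial that has its own accepted record resolves to itself (homonym
# synonym records notwithstanding: the accepted name is kept). Pointer
# chains whose target is itself a synonym are followed transitively, with
# a visited-set cycle guard capped at 10 hops; a cycle resolves to its
# lowest-ID member.
resolve_in_backbone <- function(db, bid, bb) {
  rec <- db$records
  rows <- which(rec$binomial_id == bid & rec$backbone == bb &
                  rec$rank == "species")
  if (length(rows) == 0L) return(NULL)
  if (bb == "BGCI" || any(rec$status[rows] == "Accepted"))
    return(list(id = bid, via_infra = FALSE, ambiguous = FALSE,
                candidates = bid))

  term <- integer(0)
  via <- logical(0)
  for (r in rows) {
    ch <- walk_chain(db, r)
    if (is.null(ch)) next
    term <- c(term, ch$id)
    via <- c(via, ch$via_infra)
  }
  if (length(term) == 0L) return(NULL)
  cand <- sort(unique(term))
  id <- cand[1L]
  list(id = id, via_infra = any(via[term == id]),
       ambiguous = length(cand) > 1L, candidates = cand)
}

# follow one synonym record's pointer chain to an accepted record
walk_chain <- function(db, row) {
  rec <- db$records
  via <- FALSE
  visited <- row
  cur <- row
  for (hop in seq_len(10L)) {
    tgt <- rec$target_row[cur]
    if (is.na(tgt)) return(NULL)  # dangling pointer
    if (rec$rank[tgt] == "infraspecific") via <- TRUE
    if (rec$status[tgt] == "Accepted")
      return(list(id = rec$binomial_id[tgt], via_infra = via))
    if (tgt %in% visited) {
      # pointer cycle: keep the lowest-ID member
      ids <- rec$binomial_id[visited]
      return(list(id = min(ids), via_infra = via))
    }
    visited <- c(visited, tgt)
    cur <- tgt
  }
  list(id = min(rec$binomial_id[visited]), via_infra = via)
}

#' Resolve matched names to accepted names
#'
#' Replaces every matched binomial by the accepted name of the first
#' backbone, in the user-given priority order, in which the binomial
#' occurs. BGCI names are accepted by definition; in the other backbones
#' an accepted record resolves to itself, and a synonym record is followed
#' along its pointer (chains through further synonyms or trinomial records
#' are traversed transitively). When several homonymous records resolve to
#' different binomials, the accepted one is kept if present, otherwise the
#' lowest-`ID_matched` candidate, and the ambiguity is noted; run
#' [highlight_flags()] to inspect such rows. A backbone in which the
#' binomial occurs but cannot be resolved is skipped in favour of the next
#' one in the order.
#'
#' @param results Result table from [matching()], [sequential_matching()]
#'   or [enforce_matching()].
#' @param db The `unified_db` used for matching.
#' @param backbones Priority order, default `c("BGCI","WFO","WCVP","GBIF")`.
#' @return `results` with columns `Accepted.Genus`, `Accepted.Species` and
#'   `Accepted.Backbone` appended (NA for unmatched rows).
#' @export
resolve_synonyms <- function(results, db,
                             backbones = c("BGCI", "WFO", "WCVP", "GBIF")) {
  stopifnot(inherits(db, "unified_db"))
  order_bb <- check_backbones(backbones)
  if (!all(c("Matched.Genus", "Matched.Species", "matched") %in% names(results)))
    stop("`results` must come from a matching function", call. = FALSE)

  n <- nrow(results)
  ag <- as_ <- ab <- rep(NA_character_, n)
  note <- if ("ambiguity_note" %in% names(results)) results$ambiguity_note
          else rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (!isTRUE(results$matched[i])) next
    bid <- match(binomial_of(results$Matched.Genus[i],
                             results$Matched.Species[i]),
                 db$names$binomial)
    if (is.na(bid))
      stop(sprintf("row %d: matched name '%s %s' is not present in the database",
                   i, results$Matched.Genus[i], results$Matched.Species[i]),
           call. = FALSE)
    for (bb in order_bb) {
      if (db$status[bid, bb] == "Missing") next
      res <- resolve_in_backbone(db, bid, bb)
      if (is.null(res)) next  # unresolvable here, try the next backbone
      ag[i] <- db$names$genus[res$id]
      as_[i] <- db$names$epithet[res$id]
      ab[i] <- bb
      if (res$ambiguous) {
        alt <- db$names$binomial[res$candidates]
        msg <- sprintf("resolve_synonyms: multiple accepted candidates in %s (%s)",
                       bb, paste(alt, collapse = ", "))
        note[i] <- if (is.na(note[i])) msg else paste(note[i], msg, sep = "; ")
      }
      break
    }
  }

  results$Accepted.Genus <- ag
  results$Accepted.Species <- as_
  results$Accepted.Backbone <- ab
  results$ambiguity_note <- note
  message("Please consider calling highlight_flags() to investigate potential ambiguities upon resolving synonyms to accepted names")
  results
}
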