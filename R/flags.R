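## Post-resolution ambiguity flags: homonyms and trinomial linkages that
## make a binomial-level resolution questionable.

# terminal binomial of one species-rank record: itself if accepted, else
# the end of its pointer chain
record_resolution <- function(db, row) {
  rec <- db$records
  if (rec$status[row] == "Accepted") return(rec$binomial_id[row])
  ch <- walk_chain(db, row)
  if (is.null(ch)) NA_integer_ else ch$id
}

#' Flag ambiguous or trinomial-linked resolutions
#'
#' Inspects each resolved row against the metadata of one backbone and
#' raises three per-backbone flags:
#'
#' * `infraspecific_link` — the accepted binomial was reached through a
#'   chain passing a trinomial (rank-infraspecific) record, e.g. a name
#'   whose synonym pointer targets a variety that projects onto a
#'   different binomial.
#' * `infraspecific_ambiguity` — the backbone holds a trinomial attached
#'   to the matched binomial (sharing its epithet or carrying it as
#'   infraspecific epithet) that resolves to a *different* binomial; if
#'   the input was ever truncated from a trinomial, the resolution may be
#'   wrong.
#' * `authorship_ambiguity` — the backbone holds several species-rank
#'   records (homonyms, distinguished only by authorship) for the matched
#'   binomial that resolve to different binomials; the kept result is the
#'   accepted record if one exists and is otherwise taxonomically
#'   arbitrary.
#'
#' Only rows raising at least one flag are returned. A summary line
#' reporting the number of flagged rows is emitted as a message. If the
#' backbone carries neither infraspecific nor authorship metadata, all
#' flags are false and a warning is issued.
#'
#' @param resolved Result table from [resolve_synonyms()].
#' @param db The `unified_db` used throughout.
#' @param backbone Single backbone whose metadata is inspected.
#' @return The flagged subset of `resolved`, with logical columns
#'   `<BACKBONE>_authorship_ambiguity`, `<BACKBONE>_infraspecific_ambiguity`
#'   and `<BACKBONE>_infraspecific_link` appended.
#' @export
highlight_flags <- function(resolved, db, backbone) {
  stopifnot(inherits(db, "unified_db"))
  backbone <- match.arg(backbone, backbone_names())
  if (!all(c("Matched.Genus", "Matched.Species", "matched") %in% names(resolved)))
    stop("`resolved` must come from resolve_synonyms()", call. = FALSE)

  rec <- db$records
  bb_rows <- rec$backbone == backbone
  has_meta <- any(bb_rows & (rec$rank == "infraspecific" |
                               !is.na(rec$authorship)))
  n <- nrow(resolved)
  auth <- infra_amb <- infra_link <- rep(FALSE, n)

  if (!has_meta) {
    warning(sprintf("backbone %s carries no infraspecific or authorship metadata; all flags are FALSE",
                    backbone), call. = FALSE)
  } else {
    infra_rows <- which(bb_rows & rec$rank == "infraspecific")
    for (i in seq_len(n)) {
      if (!isTRUE(resolved$matched[i])) next
      g <- resolved$Matched.Genus[i]
      e <- resolved$Matched.Species[i]
      bid <- match(binomial_of(g, e), db$names$binomial)
      if (is.na(bid)) next

      own <- resolve_in_backbone(db, bid, backbone)
      own_id <- if (is.null(own)) bid else own$id
      if (!is.null(own)) infra_link[i] <- own$via_infra

      # homonyms: several species-rank records resolving differently
      sp_rows <- which(bb_rows & rec$rank == "species" &
                         rec$binomial_id == bid)
      if (length(sp_rows) > 1L) {
        term <- vapply(sp_rows, function(r) record_resolution(db, r),
                       integer(1))
        term <- term[!is.na(term)]
        if (length(unique(term)) > 1L) auth[i] <- TRUE
      }

      # trinomials attached to this binomial resolving elsewhere
      att <- infra_rows[rec$genus[infra_rows] == g &
                          (rec$epithet[infra_rows] == e |
                             rec$infra_epithet[infra_rows] %in% e)]
      if (length(att) > 0L) {
        term <- vapply(att, function(r) record_resolution(db, r), integer(1))
        term <- term[!is.na(term)]
        if (any(term != own_id)) infra_amb[i] <- TRUE
      }
    }
  }

  pre <- function(what) paste0(backbone, "_", what)
  resolved[[pre("authorship_ambiguity")]] <- auth
  resolved[[pre("infraspecific_ambiguity")]] <- infra_amb
  resolved[[pre("infraspecific_link")]] <- infra_link

  any_flag <- auth | infra_amb | infra_link
  message(sprintf("In summary, %d out of %d matched species have raised a flag.",
                  sum(any_flag), n))
  out <- resolved[any_flag, , drop = FALSE]
  rownames(out) <- NULL
  out
}
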