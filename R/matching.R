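## The matching cascade: exact binomial, genus, fuzzy genus, then exact /
## suffix / fuzzy epithet within the resolved genus. Each stage leaves a
## logical audit column; NA means the stage was never reached for that row.

stage_columns <- function() {
  c("direct_match", "genus_match", "fuzzy_match_genus",
    "direct_match_species_within_genus", "suffix_match_species_within_genus",
    "fuzzy_match_species_within_genus")
}

#' Default matching and enforcement parameters
#'
#' The fixed defaults of the pipeline: genera are fuzzy-matched at optimal
#' string alignment distance at most 1 (genus names are short and rarely
#' mistyped), epithets at distance at most 2, the suffix stage substitutes
#' the six endings `a, i, is, um, us, ae` for one another, and
#' [enforce_matching()] searches the synonym graph to a default depth of
#' 3 steps.
#'
#' @return Named list with elements `genus_fuzzy_max_dist`,
#'   `epithet_fuzzy_max_dist`, `suffixes` and `enforce_max_depth`.
#' @export
#' @examples
#' matching_defaults()
matching_defaults <- function() {
  list(genus_fuzzy_max_dist = 1L,
       epithet_fuzzy_max_dist = 2L,
       suffixes = c("a", "i", "is", "um", "us", "ae"),
       enforce_max_depth = 3L)
}

# gender endings and other common epithet suffixes that are substituted for
# one another at the suffix-matching stage
epithet_suffixes <- function() matching_defaults()$suffixes

# search space over the species-rank records of the selected backbones
match_space <- function(db, backbones) {
  rec <- db$records
  keep <- rec$rank == "species" & rec$backbone %in% backbones
  genus <- rec$genus[keep]
  epithet <- rec$epithet[keep]
  bino <- binomial_of(genus, epithet)
  uniq <- !duplicated(bino)
  genus <- genus[uniq]
  epithet <- epithet[uniq]
  ord <- order(genus, epithet, method = "radix")
  genus <- genus[ord]
  epithet <- epithet[ord]
  list(binomials = binomial_of(genus, epithet),
       genera = sort(unique(genus), method = "radix"),
       by_genus = split(epithet, genus))
}

empty_result <- function(extra = character(0)) {
  cols <- c("Orig.Genus", "Orig.Species", "Matched.Genus", "Matched.Species",
            "matched", stage_columns(), "ambiguity_note", extra)
  out <- setNames(vector("list", length(cols)), cols)
  for (cn in cols)
    out[[cn]] <- if (cn %in% c("matched", stage_columns())) logical(0)
                 else character(0)
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

matching_core <- function(input, space) {
  n <- nrow(input)
  if (n == 0L) return(empty_result())
  mg <- ms <- note <- rep(NA_character_, n)
  st <- matrix(NA, nrow = n, ncol = length(stage_columns()),
               dimnames = list(NULL, stage_columns()))
  defs <- matching_defaults()
  sufs <- defs$suffixes

  for (i in seq_len(n)) {
    g <- input$Genus[i]
    e <- input$Species[i]
    notes <- character(0)

    if (binomial_of(g, e) %in% space$binomials) {
      st[i, "direct_match"] <- TRUE
      mg[i] <- g; ms[i] <- e
      next
    }
    st[i, "direct_match"] <- FALSE

    # resolve the genus
    if (g %in% space$genera) {
      st[i, "genus_match"] <- TRUE
      rg <- g
    } else {
      st[i, "genus_match"] <- FALSE
      cand <- space$genera[osa_distance(g, space$genera) <=
                             defs$genus_fuzzy_max_dist]
      if (length(cand) == 0L) {
        st[i, "fuzzy_match_genus"] <- FALSE
        next
      }
      st[i, "fuzzy_match_genus"] <- TRUE
      rg <- cand[1L]  # space$genera is sorted: alphabetical first
      if (length(cand) > 1L)
        notes <- c(notes, sprintf("fuzzy_match_genus: multiple candidates (%s)",
                                  paste(cand, collapse = ", ")))
    }

    eps <- sort(unique(space$by_genus[[rg]]), method = "radix")

    if (e %in% eps) {
      st[i, "direct_match_species_within_genus"] <- TRUE
      mg[i] <- rg; ms[i] <- e
      if (length(notes)) note[i] <- paste(notes, collapse = "; ")
      next
    }
    st[i, "direct_match_species_within_genus"] <- FALSE

    # suffix substitution: only when the input epithet itself carries one
    # of the interchangeable endings
    suf <- sufs[vapply(sufs, function(s)
      nchar(e) > nchar(s) && endsWith(e, s), logical(1))]
    hit <- character(0)
    if (length(suf) == 1L) {
      stem <- substr(e, 1L, nchar(e) - nchar(suf))
      cand <- paste0(stem, setdiff(sufs, suf))
      hit <- sort(intersect(cand, eps), method = "radix")
    }
    if (length(hit) > 0L) {
      st[i, "suffix_match_species_within_genus"] <- TRUE
      mg[i] <- rg; ms[i] <- hit[1L]
      if (length(hit) > 1L)
        notes <- c(notes, sprintf("suffix_match: multiple candidates (%s)",
                                  paste(hit, collapse = ", ")))
      if (length(notes)) note[i] <- paste(notes, collapse = "; ")
      next
    }
    st[i, "suffix_match_species_within_genus"] <- FALSE

    dmax <- defs$epithet_fuzzy_max_dist
    d <- osa_distance(e, eps)
    cand <- eps[d <= dmax]
    if (length(cand) > 0L) {
      st[i, "fuzzy_match_species_within_genus"] <- TRUE
      dmin <- min(d[d <= dmax])
      best <- cand[d[d <= dmax] == dmin]  # already alphabetical
      mg[i] <- rg; ms[i] <- best[1L]
      if (length(best) > 1L)
        notes <- c(notes, sprintf("fuzzy_match_species: multiple candidates at distance %d (%s)",
                                  dmin, paste(best, collapse = ", ")))
    } else {
      st[i, "fuzzy_match_species_within_genus"] <- FALSE
    }
    if (length(notes)) note[i] <- paste(notes, collapse = "; ")
  }

  out <- data.frame(Orig.Genus = input$Genus, Orig.Species = input$Species,
                    Matched.Genus = mg, Matched.Species = ms,
                    matched = !is.na(mg), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (cn in stage_columns()) out[[cn]] <- st[, cn]
  out$ambiguity_note <- note
  out
}

#' Match a species list against the unified database
#'
#' Runs the six-stage matching cascade for every input binomial against the
#' species-rank names of the selected backbones: exact binomial match;
#' genus presence; fuzzy genus match (optimal string alignment distance at
#' most 1, alphabetical first on ties); then, within the resolved genus,
#' exact epithet, suffix substitution over the endings
#' `a, i, is, um, us, ae`, and fuzzy epithet match (distance at most 2,
#' smallest distance first, alphabetical on ties). Later stages run only
#' when every earlier stage has failed, and each stage that ran leaves a
#' logical audit column (`NA` = stage not reached). Ambiguous fuzzy or
#' suffix matches return the deterministic first candidate and record the
#' alternatives in `ambiguity_note`.
#'
#' Matches are reported whatever their status in the backbone; run
#' [resolve_synonyms()] afterwards to obtain accepted names only.
#'
#' @param df `data.frame` with character columns `Genus` and `Species`.
#' @param db A `unified_db` (see [close_database()]).
#' @param backbone Subset of `backbone_names()` restricting the search
#'   space; `NULL` (default) searches all four backbones.
#' @param distinct Drop duplicate input binomials before matching?
#' @return A `data.frame` with columns `Orig.Genus`, `Orig.Species`,
#'   `Matched.Genus`, `Matched.Species`, `matched`, one logical column per
#'   cascade stage, and `ambiguity_note`.
#' @seealso [sequential_matching()], [enforce_matching()],
#'   [summarize_output()]
#' @export
matching <- function(df, db, backbone = NULL, distinct = FALSE) {
  stopifnot(inherits(db, "unified_db"))
  input <- prepare_input(df)
  if (distinct) input <- unique(input)
  backbones <- check_backbones(backbone, "backbone")
  matching_core(input, match_space(db, backbones))
}

#' Match sequentially against an ordered list of backbones
#'
#' Calls [matching()] once per backbone in `sequential_backbones`, keeping
#' for every input row the first backbone (in the given order) that
#' produced a match; `Matched.Backbone` records which one. Rows unmatched
#' in every listed backbone get their audit columns from a final
#' bookkeeping pass against the whole database (all four backbones), so
#' the stage information does not merely reflect the last backbone tried;
#' such rows remain unmatched.
#'
#' @param df `data.frame` with columns `Genus` and `Species`.
#' @param db A `unified_db`.
#' @param sequential_backbones Character vector, an ordered subset of
#'   `backbone_names()`.
#' @inheritParams matching
#' @return As [matching()], plus a `Matched.Backbone` column.
#' @export
sequential_matching <- function(df, db, sequential_backbones,
                                distinct = FALSE) {
  stopifnot(inherits(db, "unified_db"))
  order_bb <- check_backbones(sequential_backbones, "sequential_backbones")
  input <- prepare_input(df)
  if (distinct) input <- unique(input)
  n <- nrow(input)
  if (n == 0L) {
    out <- empty_result()
    out$Matched.Backbone <- character(0)
    return(out)
  }

  bb_used <- rep(NA_character_, n)
  res <- matching_core(input, match_space(db, order_bb[1L]))
  bb_used[res$matched] <- order_bb[1L]
  todo <- !res$matched
  for (bb in order_bb[-1L]) {
    if (!any(todo)) break
    part <- matching_core(input[todo, , drop = FALSE], match_space(db, bb))
    res[todo, ] <- part
    bb_used[todo][part$matched] <- bb
    todo[todo] <- !part$matched
  }
  if (any(todo)) {
    # bookkeeping pass over the full database for still-unmatched rows
    final <- matching_core(input[todo, , drop = FALSE],
                           match_space(db, backbone_names()))
    final$Matched.Genus <- NA_character_
    final$Matched.Species <- NA_character_
    final$matched <- FALSE
    res[todo, ] <- final
  }
  res$matched <- as.logical(res$matched)
  res$Matched.Backbone <- bb_used
  res
}
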