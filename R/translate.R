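## List-to-list translation: match an input species list onto an arbitrary
## target list, using the cross-backbone synonym graph for names the
## cascade alone cannot bridge.

# all database vertices a target-list name can stand for: exact binomial,
# otherwise every epithet candidate (exact / suffix / fuzzy <= 2) within
# every exactly- or fuzzily- (distance 1) resolved genus
target_vertex_ids <- function(g, e, db, space) {
  id <- match(binomial_of(g, e), db$names$binomial)
  if (!is.na(id)) return(id)
  genera <- if (g %in% space$genera) g
            else space$genera[osa_distance(g, space$genera) <= 1L]
  if (length(genera) == 0L) return(integer(0))
  sufs <- epithet_suffixes()
  suf <- sufs[vapply(sufs, function(s)
    nchar(e) > nchar(s) && endsWith(e, s), logical(1))]
  out <- integer(0)
  for (rg in genera) {
    eps <- unique(space$by_genus[[rg]])
    cand <- eps[eps == e]
    if (length(cand) == 0L && length(suf) == 1L) {
      stem <- substr(e, 1L, nchar(e) - nchar(suf))
      cand <- intersect(paste0(stem, setdiff(sufs, suf)), eps)
    }
    if (length(cand) == 0L)
      cand <- eps[osa_distance(e, eps) <= 2L]
    if (length(cand) > 0L)
      out <- c(out, match(binomial_of(rg, cand), db$names$binomial))
  }
  sort(unique(out[!is.na(out)]))
}

#' Translate a species list into a custom target list
#'
#' Maps every input binomial onto a binomial of `target`, a user-supplied
#' species list that need not be consistent with any backbone. Stage 1
#' runs the full matching cascade with the target list itself as the only
#' search space. Names still unmatched are then bridged through the
#' database: the input name is matched into the database to find its entry
#' vertex, every target name is matched (including suffix and fuzzy
#' matching) onto its candidate database vertices, and a breadth-first
#' search over the synonym graph connects entry to target vertices within
#' `max_depth` steps (lowest-`ID_matched` vertex on ties, alternatives
#' noted in `ambiguity_note`). Matched output names are always drawn
#' verbatim from the target list.
#'
#' @param df Input species list (`Genus`, `Species` columns).
#' @param target Target species list (same shape, non-empty).
#' @param db A `unified_db` supplying the synonym relations.
#' @param max_depth Maximum graph depth for the bridging stage.
#' @return A `data.frame` with `Orig.*` and `Matched.*` columns, the
#'   cascade audit columns of stage 1, and `enforced_matching_dist` for
#'   rows translated through the graph.
#' @export
translate_trees <- function(df, target, db,
                            max_depth = matching_defaults()$enforce_max_depth) {
  stopifnot(inherits(db, "unified_db"))
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1L)
    stop("`max_depth` must be a single integer >= 1", call. = FALSE)
  max_depth <- as.integer(max_depth)
  input <- prepare_input(df)
  tgt <- prepare_input(target)
  if (nrow(tgt) == 0L) stop("`target` must be non-empty", call. = FALSE)

  # stage 1: cascade against the target list itself
  tgt_bino <- binomial_of(tgt$Genus, tgt$Species)
  ord <- order(tgt$Genus, tgt$Species, method = "radix")
  tspace <- list(binomials = tgt_bino[ord],
                 genera = sort(unique(tgt$Genus), method = "radix"),
                 by_genus = split(tgt$Species[ord], tgt$Genus[ord]))
  res <- matching_core(input, tspace)
  res$enforced_matching_dist <- NA_integer_
  todo <- which(!res$matched)
  if (length(todo) == 0L) return(res)

  # stage 2: bridge through the synonym graph
  graph <- build_synonym_graph(db)
  space <- match_space(db, backbone_names())
  is_target <- logical(nrow(db$names))
  vert_of_target <- rep(NA_integer_, nrow(db$names))  # vertex -> target row
  for (j in rev(seq_len(nrow(tgt)))) {  # earlier target rows win collisions
    ids <- target_vertex_ids(tgt$Genus[j], tgt$Species[j], db, space)
    is_target[ids] <- TRUE
    vert_of_target[ids] <- j
  }

  for (i in todo) {
    entry <- matching_core(input[i, , drop = FALSE], space)
    if (!entry$matched[1L]) next
    source <- match(binomial_of(entry$Matched.Genus[1L],
                                entry$Matched.Species[1L]),
                    db$names$binomial)
    if (is_target[source]) {
      hit <- list(id = source, dist = 0L, hits = source)
    } else {
      hit <- bfs_first_hit(graph, source, is_target, max_depth)
      if (is.null(hit)) next
    }
    j <- vert_of_target[hit$id]
    res$Matched.Genus[i] <- tgt$Genus[j]
    res$Matched.Species[i] <- tgt$Species[j]
    res$matched[i] <- TRUE
    res$enforced_matching_dist[i] <- hit$dist
    alt_j <- setdiff(unique(vert_of_target[hit$hits]), j)
    if (length(alt_j) > 0L) {
      msg <- sprintf("translate: equally near target alternatives (%s)",
                     paste(binomial_of(tgt$Genus[alt_j], tgt$Species[alt_j]),
                           collapse = ", "))
      res$ambiguity_note[i] <- if (is.na(res$ambiguity_note[i])) msg
                               else paste(res$ambiguity_note[i], msg, sep = "; ")
    }
  }
  res
}
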