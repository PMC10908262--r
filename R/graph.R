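## The cross-backbone synonym graph: undirected, one vertex per distinct
## binomial (ID_matched), synonym edges from the pointer-bearing backbones
## plus fuzzy edges between binomials one edit apart.

#' Build the cross-backbone synonym graph
#'
#' Vertices are the distinct binomials of the database, identified by
#' `ID_matched`. Two binomials are connected when (a) some backbone links
#' them through a synonym-to-accepted pointer (trinomial records are
#' projected onto their binomial), or (b) their full binomial strings are
#' at optimal string alignment distance 1 ("fuzzy" edges). Fuzzy-edge
#' candidates are generated by blocking — same genus, same epithet, or
#' same genus initial with equal total length — a scheme that provably
#' covers every pair one edit apart, since a single edit either leaves one
#' of the two tokens intact or is a transposition across the token
#' boundary, which preserves the genus initial and the total length.
#'
#' @param db A `unified_db`.
#' @return A `synonym_graph`: list with the vertex count `n`, an `edges`
#'   data.frame (`from`, `to`, `provenance`), and an adjacency list `adj`.
#' @export
build_synonym_graph <- function(db) {
  rec <- db$records
  n <- nrow(db$names)

  syn <- which(rec$status == "Synonym" & rec$backbone %in% pointer_backbones() &
                 !is.na(rec$target_row))
  from <- rec$binomial_id[syn]
  to <- rec$binomial_id[rec$target_row[syn]]
  prov <- paste0("synonym:", rec$backbone[syn])
  keep <- from != to  # trinomial synonyms of their own binomial
  from <- from[keep]; to <- to[keep]; prov <- prov[keep]

  fz <- fuzzy_pairs(db$names)
  from <- c(from, fz$from)
  to <- c(to, fz$to)
  prov <- c(prov, rep("fuzzy", length(fz$from)))

  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(paste(lo, hi, prov))
  edges <- data.frame(from = lo[keep], to = hi[keep],
                      provenance = prov[keep], stringsAsFactors = FALSE)

  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    ends <- c(edges$from, edges$to)
    other <- c(edges$to, edges$from)
    pairs <- !duplicated(paste(ends, other))
    sp <- split(other[pairs], factor(ends[pairs], levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unique(v)))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  structure(list(n = n, edges = edges, adj = adj, names = db$names),
            class = "synonym_graph")
}

#' @export
print.synonym_graph <- function(x, ...) {
  cat(sprintf("Synonym graph: %d binomial vertices, %d edges (%d synonym, %d fuzzy)\n",
              x$n, nrow(x$edges), sum(x$edges$provenance != "fuzzy"),
              sum(x$edges$provenance == "fuzzy")))
  invisible(x)
}

# all unordered pairs of binomials at full-string OSA distance exactly 1,
# found within blocks rather than by the quadratic all-pairs scan
fuzzy_pairs <- function(nm) {
  n <- nrow(nm)
  if (n < 2L) return(list(from = integer(0), to = integer(0)))
  bino <- nm$binomial
  len <- nchar(bino)
  keys <- list(nm$genus,
               nm$epithet,
               paste0(substr(nm$genus, 1L, 1L), ":", len))
  from <- integer(0); to <- integer(0)
  for (k in keys) {
    for (ids in split(seq_len(n), k)) {
      m <- length(ids)
      if (m < 2L) next
      cmb <- utils::combn(ids, 2L)
      a <- cmb[1L, ]; b <- cmb[2L, ]
      ok <- abs(len[a] - len[b]) <= 1L
      a <- a[ok]; b <- b[ok]
      if (length(a) == 0L) next
      d <- .osa_distance_impl(bino[a], bino[b])
      hit <- d == 1L
      from <- c(from, a[hit])
      to <- c(to, b[hit])
    }
  }
  keep <- !duplicated(paste(pmin(from, to), pmax(from, to)))
  list(from = from[keep], to = to[keep])
}

# frontier-by-frontier BFS from `source`; at the first depth whose frontier
# contains a target vertex, stop and return the minimum-ID hit. Depth 0
# (source itself a target) is the caller's business.
bfs_first_hit <- function(graph, source, is_target, max_depth) {
  visited <- logical(graph$n)
  visited[source] <- TRUE
  frontier <- source
  for (d in seq_len(max_depth)) {
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) return(NULL)
    hits <- nxt[is_target[nxt]]
    if (length(hits) > 0L)
      return(list(id = min(hits), dist = d, hits = sort(hits)))
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  NULL
}

#' Force matches into a target backbone via the synonym graph
#'
#' For every row of a [matching()] / [sequential_matching()] result that is
#' not already matched into the target backbone, searches the synonym
#' graph breadth-first (up to `max_depth` steps, default 3) for the
#' nearest binomial present in the target backbone. Rows whose matched
#' name is already in the target are untouched. Rows unmatched anywhere
#' are first re-matched against the whole database to locate their entry
#' vertex; rows absent from the database entirely pass through unchanged.
#'
#' The search stops at the first depth containing any target vertex, and
#' among equally-near targets always selects the vertex with the lowest
#' `ID_matched`, making results reproducible. The depth of each re-homed
#' match is recorded in `enforced_matching_dist` (0 in the corner case
#' where the whole-database re-match itself lands in the target backbone).
#' Audit columns downstream of `direct_match` are cleared for re-homed
#' rows, since they no longer describe the final match.
#'
#' @param results Result table from [matching()] or
#'   [sequential_matching()].
#' @param db The `unified_db` the results were matched against.
#' @param backbone Single target backbone name.
#' @param max_depth Maximum number of graph steps (at least 1).
#' @param graph Optional pre-built [build_synonym_graph()] result, to
#'   amortize graph construction over repeated calls.
#' @return `results` with re-homed `Matched.*` names and an
#'   `enforced_matching_dist` integer column.
#' @export
enforce_matching <- function(results, db, backbone,
                             max_depth = matching_defaults()$enforce_max_depth,
                             graph = NULL) {
  stopifnot(inherits(db, "unified_db"))
  backbone <- match.arg(backbone, backbone_names())
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1L)
    stop("`max_depth` must be a single integer >= 1", call. = FALSE)
  max_depth <- as.integer(max_depth)
  if (!all(c("Matched.Genus", "Matched.Species", "matched") %in% names(results)))
    stop("`results` must come from matching() or sequential_matching()",
         call. = FALSE)
  if (is.null(graph)) graph <- build_synonym_graph(db)

  is_target <- logical(nrow(db$names))
  is_target[present_ids(db, backbone)] <- TRUE

  if (!"enforced_matching_dist" %in% names(results))
    results$enforced_matching_dist <- NA_integer_

  full_space <- match_space(db, backbone_names())
  sub_stages <- setdiff(stage_columns(), "direct_match")

  for (i in seq_len(nrow(results))) {
    if (isTRUE(results$matched[i])) {
      bid <- match(binomial_of(results$Matched.Genus[i],
                               results$Matched.Species[i]),
                   db$names$binomial)
      if (is.na(bid))
        stop(sprintf("row %d: matched name is not in the database", i),
             call. = FALSE)
      if (is_target[bid]) next  # already home
      source <- bid
      d0 <- NA_integer_
    } else {
      # locate an entry vertex for names unmatched in the target
      re <- matching_core(data.frame(Genus = results$Orig.Genus[i],
                                     Species = results$Orig.Species[i],
                                     stringsAsFactors = FALSE), full_space)
      if (!re$matched[1L]) next  # not in the database at all
      source <- match(binomial_of(re$Matched.Genus[1L], re$Matched.Species[1L]),
                      db$names$binomial)
      d0 <- 0L
    }

    if (!is.na(d0) && is_target[source]) {
      hit <- list(id = source, dist = 0L)
    } else {
      hit <- bfs_first_hit(graph, source, is_target, max_depth)
    }
    if (is.null(hit)) next
    results$Matched.Genus[i] <- db$names$genus[hit$id]
    results$Matched.Species[i] <- db$names$epithet[hit$id]
    results$matched[i] <- TRUE
    results$enforced_matching_dist[i] <- hit$dist
    for (cn in intersect(sub_stages, names(results)))
      results[[cn]][i] <- NA
  }
  results
}
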