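## Process summary in the format printed by the matching workflow.

#' Summarize a matching result table
#'
#' Produces the textual overview of a matching run: overall matched
#' fraction and number of distinct matched names, the direct-match count,
#' the indirectly matched count (rows rescued by the within-genus stages,
#' over all rows that missed the direct match), one line per cascade stage
#' (successes over rows where the stage actually ran), and — when an
#' `enforced_matching_dist` column is present — the number of names
#' re-homed by [enforce_matching()] over the number it attempted.
#'
#' @param results Result table from any of the matching functions.
#' @return Character vector of summary lines.
#' @export
summarize_output <- function(results) {
  stopifnot(is.data.frame(results), "matched" %in% names(results))
  n <- nrow(results)
  matched <- sum(results$matched, na.rm = TRUE)
  distinct <- length(unique(stats::na.omit(
    binomial_of(results$Matched.Genus, results$Matched.Species)[results$matched])))
  lines <- sprintf("matched: %d / %d were matched with %d distinct matched names.",
                   matched, n, distinct)

  st <- intersect(stage_columns(), names(results))
  if ("direct_match" %in% st) {
    lines <- c(lines, sprintf("direct_match: %d / %d",
                              sum(results$direct_match, na.rm = TRUE),
                              sum(!is.na(results$direct_match))))
    within <- intersect(c("direct_match_species_within_genus",
                          "suffix_match_species_within_genus",
                          "fuzzy_match_species_within_genus"), st)
    if (length(within) > 0L) {
      ind <- sum(vapply(within, function(cn)
        sum(results[[cn]], na.rm = TRUE), numeric(1)))
      lines <- c(lines, sprintf("indirectly matched: %d / %d", ind,
                                sum(!results$direct_match, na.rm = TRUE)))
    }
    for (cn in setdiff(st, "direct_match")) {
      att <- sum(!is.na(results[[cn]]))
      lines <- c(lines, sprintf("    %s: %d / %d", cn,
                                sum(results[[cn]], na.rm = TRUE), att))
    }
  }
  if ("enforced_matching_dist" %in% names(results)) {
    k <- sum(!is.na(results$enforced_matching_dist))
    attempted <- k + sum(!results$matched, na.rm = TRUE)
    lines <- c(lines,
               sprintf("number of species matched via enforce_matching(): %d / %d",
                       k, attempted))
  }
  lines
}
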