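#' Optimal string alignment distance
#'
#' Restricted Damerau-Levenshtein edit distance: insertions, deletions,
#' substitutions and transpositions of adjacent characters all count one
#' operation, and no substring is edited more than once. Unlike the
#' unrestricted Damerau-Levenshtein distance, `osa_distance("ca", "abc")`
#' is 3, not 2. A transposed genus such as `"Quecrus"` is at distance 1
#' from `"Quercus"`, which is what makes the metric suitable for catching
#' typographic errors in Latin names.
#'
#' Comparison is byte-wise and case-sensitive; the matching functions only
#' ever call it on already-normalized tokens.
#'
#' @param a,b Character vectors, recycled to a common length.
#' @return Integer vector of distances; `NA` where either input is `NA`.
#' @export
#' @examples
#' osa_distance("Quercus", "Quecrus")  # transposition: 1
#' osa_distance("ca", "abc")           # 3 (restricted metric)
osa_distance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  if (length(a) == 0L || length(b) == 0L) return(integer(0))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  .osa_distance_impl(a, b)
}

# rank markers that betray a trinomial crammed into the epithet column
.rank_markers <- c("var.", "var", "subsp.", "subsp", "ssp.", "ssp",
                   "f.", "fo.", "forma", "subvar.", "subvar", "cv.")

# fold to plain ASCII letters and hyphens; hybrid sign dropped first so the
# glibc transliteration cannot turn it into a stray "x"
fold_token <- function(x) {
  x <- gsub("×", "", x)
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- ""
  gsub("[^A-Za-z-]", "", x)
}

# strip a leading hybrid "x " token, e.g. "x Cupressocyparis"
strip_hybrid <- function(x) sub("^[xX]\\s+", "", x)

#' Normalize a Latin binomial
#'
#' Trims and case-folds a genus / specific-epithet pair into the canonical
#' form used throughout the package: genus capitalized, epithet lower-case,
#' diacritics folded to ASCII, hybrid markers (`"×"`, leading `"x "`)
#' removed. Inputs whose epithet still contains whitespace or an
#' infraspecific rank marker (`var.`, `subsp.`, `f.`, ...) are rejected:
#' truncating trinomials silently is a common source of resolution errors,
#' so it is left to the user to handle such names deliberately.
#'
#' @param genus,species Character vectors of equal length (or length 1,
#'   recycled) holding the raw genus and specific epithet.
#' @return A `data.frame` with character columns `Genus` and `Species`.
#' @export
#' @examples
#' normalize_binomial("acer ", "PLATANOIDES")
#' normalize_binomial(c("Fagus", "Quercus"), c("sylvatica", "robur"))
normalize_binomial <- function(genus, species) {
  genus <- as.character(genus)
  species <- as.character(species)
  n <- max(length(genus), length(species))
  genus <- rep_len(genus, n)
  species <- rep_len(species, n)
  if (anyNA(genus) || anyNA(species))
    stop_invalid_name("Genus/Species may not be NA")

  genus <- trimws(genus)
  species <- trimws(species)

  # reject trinomials before whitespace is touched any further
  sp_tokens <- strsplit(species, "\\s+")
  multi <- lengths(sp_tokens) > 1L
  has_marker <- vapply(sp_tokens, function(tk)
    any(tolower(tk) %in% .rank_markers), logical(1))
  # a leading hybrid marker on the epithet is allowed and stripped
  hybrid_ep <- multi & vapply(sp_tokens, function(tk)
    length(tk) == 2L && tolower(tk[1]) == "x", logical(1))
  bad <- (multi | has_marker) & !hybrid_ep
  if (any(bad)) {
    stop_trinomial(sprintf(
      "input looks like a trinomial or multi-token epithet (e.g. '%s'): split infraspecific names upstream, do not truncate them",
      species[which(bad)[1]]))
  }

  genus <- fold_token(strip_hybrid(genus))
  species <- fold_token(strip_hybrid(species))

  empty <- !nzchar(genus) | !nzchar(species)
  if (any(empty))
    stop_invalid_name("empty genus or specific epithet after normalization")

  genus <- paste0(toupper(substr(genus, 1L, 1L)),
                  tolower(substr(genus, 2L, nchar(genus))))
  species <- tolower(species)
  data.frame(Genus = genus, Species = species, stringsAsFactors = FALSE)
}

stop_invalid_name <- function(msg) {
  stop(errorCondition(msg, class = c("dendronym_invalid_name", "error")))
}

stop_trinomial <- function(msg) {
  stop(errorCondition(msg, class = c("dendronym_trinomial_input", "error")))
}

# normalize a user species list (data.frame with Genus/Species columns)
prepare_input <- function(df) {
  if (!is.data.frame(df) || !all(c("Genus", "Species") %in% names(df)))
    stop("input must be a data.frame with columns 'Genus' and 'Species'",
         call. = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(Genus = character(0), Species = character(0),
                      stringsAsFactors = FALSE))
  normalize_binomial(df$Genus, df$Species)
}

binomial_of <- function(genus, species) paste(genus, species)
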