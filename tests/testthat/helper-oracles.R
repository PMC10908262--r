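# Independent oracles used across the suite.

# pure-R memoized recursive OSA distance, written against the textbook
# recurrence and independent of the package's compiled implementation
osa_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- min(rec(i - 1L, j) + 1L,
                rec(i, j - 1L) + 1L,
                rec(i - 1L, j - 1L) + (A[i] != B[j]))
    if (i > 1L && j > 1L && A[i] == B[j - 1L] && A[i - 1L] == B[j])
      best <- min(best, rec(i - 2L, j - 2L) + 1L)
    memo[[key]] <- best
    best
  }
  rec(length(A), length(B))
}

random_token <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive quadratic scan for binomial pairs one edit apart (fuzzy-edge
# oracle for the blocking scheme)
fuzzy_pairs_exhaustive <- function(binomials) {
  n <- length(binomials)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (osa_distance(binomials[i], binomials[j]) == 1L)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

# shortest distance from `source` to the nearest TRUE entry of `is_target`
# (excluding the source itself), via igraph; Inf when unreachable
igraph_nearest <- function(edges, n, source, is_target) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  d <- as.numeric(igraph::distances(g, v = source))
  d[source] <- Inf  # depth-0 handled separately by the package
  tgt <- which(is_target)
  if (length(tgt) == 0L) return(list(dist = Inf, ids = integer(0)))
  dmin <- min(d[tgt])
  list(dist = dmin, ids = sort(tgt[d[tgt] == dmin & is.finite(d[tgt])]))
}

# small random store with misspelling-style near-duplicates, for closure
# and fuzzy-edge fuzz tests
random_store_records <- function(n_acc = 12L, seed = 1L) {
  set.seed(seed)
  genera <- c("Abies", "Acer", "Alnus", "Quercus", "Fagus")
  eps <- unique(replicate(n_acc * 3L, random_token(sample(4:8, 1L))))
  acc_g <- sample(genera, n_acc, TRUE)
  acc_e <- eps[seq_len(n_acc)]
  rec <- make_records(sprintf("w%03d", seq_len(n_acc)), "WFO", acc_g, acc_e)
  # synonyms pointing at random accepted records
  n_syn <- max(1L, rpois(1L, n_acc / 2))
  tgt <- sample(n_acc, n_syn, TRUE)
  rec <- rbind(rec, make_records(
    sprintf("s%03d", seq_len(n_syn)), "WFO",
    sample(genera, n_syn, TRUE), eps[n_acc + seq_len(n_syn)],
    status = "Synonym", accepted_source_id = sprintf("w%03d", tgt)))
  rec
}

make_records <- dendronym:::make_records
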