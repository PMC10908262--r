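test_that("the synonym graph encodes the cross-backbone chain", {
  fx <- synonym_chain_fixture()
  g <- build_synonym_graph(fx$db)
  nm <- fx$db$names
  id <- function(x) match(x, nm$binomial)
  pair <- function(a, b) {
    any((g$edges$from == min(id(a), id(b))) &
          (g$edges$to == max(id(a), id(b))))
  }
  expect_true(pair("Atuna racemosa", "Atuna excelsa"))
  expect_true(pair("Atuna excelsa", "Parinari racemosa"))
  expect_true(pair("Parinari racemosa", "Maranthes corymbosa"))
  expect_identical(nrow(g$edges), 3L)
  expect_true(all(g$edges$provenance %in% c("synonym:WFO", "synonym:WCVP")))
})

test_that("stores without synonyms or near-duplicates give edgeless graphs", {
  db <- close_database(make_records(c("1", "2"), "WFO",
                                    c("Acer", "Fagus"),
                                    c("rubrum", "sylvatica")))
  g <- build_synonym_graph(db)
  expect_identical(nrow(g$edges), 0L)
})

test_that("binomials one edit apart are joined by fuzzy edges", {
  db <- close_database(make_records(c("1", "2"), "WFO",
                                    c("Quercus", "Quecrus"),
                                    c("robur", "robur")))
  g <- build_synonym_graph(db)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$provenance, "fuzzy")
})

test_that("blocked fuzzy-pair search equals the exhaustive scan", {
  for (seed in 1:8) {
    set.seed(seed)
    base <- unique(replicate(15, paste(
      random_token(1, LETTERS[1:3]),
      random_token(sample(3:6, 1), letters[1:4]))))
    # inject near-duplicates, including token-boundary edits
    variants <- unique(unlist(lapply(base, function(b) {
      ch <- strsplit(b, "")[[1]]
      i <- sample(seq_along(ch), 1)
      c(paste(ch[-i], collapse = ""),
        paste(c(ch[seq_len(i)], "x", ch[-seq_len(i)]), collapse = ""))
    })))
    variants <- variants[grepl("^[A-Za-z]+ [a-z]+$", variants)]
    # a transposition straddling the token boundary, the hardest case for
    # any blocking scheme
    all_b <- unique(c(base, variants, "Quercus robur", "Quercu srobur"))
    parts <- strsplit(all_b, " ")
    nm <- data.frame(genus = vapply(parts, `[`, "", 1),
                     epithet = vapply(parts, `[`, "", 2),
                     binomial = all_b, id = seq_along(all_b),
                     stringsAsFactors = FALSE)
    got <- dendronym:::fuzzy_pairs(nm)
    got <- unique(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
    want <- fuzzy_pairs_exhaustive(all_b)
    want <- if (is.null(want)) character(0) else paste(want[, 1], want[, 2])
    expect_setequal(got, want)
  }
})

test_that("enforced matching walks the chain at depths 1, 2 and 3", {
  fx <- synonym_chain_fixture()
  res <- matching(fx$input, fx$db, backbone = "BGCI")
  enf <- enforce_matching(res, fx$db, "BGCI")
  dist_of <- function(g, s)
    enf$enforced_matching_dist[enf$Orig.Genus == g & enf$Orig.Species == s]
  expect_identical(dist_of("Parinari", "racemosa"), 1L)
  expect_identical(dist_of("Atuna", "excelsa"), 2L)
  expect_identical(dist_of("Atuna", "racemosa"), 3L)
  expect_true(all(enf$Matched.Genus == "Maranthes" &
                    enf$Matched.Species == "corymbosa"))
  expect_true(all(enf$matched))
  # the row already in BGCI is untouched
  expect_true(is.na(dist_of("Maranthes", "corymbosa")))
  expect_identical(enf[enf$Orig.Genus == "Maranthes", names(res)],
                   res[res$Orig.Genus == "Maranthes", ])
})

test_that("the depth limit truncates the search", {
  fx <- synonym_chain_fixture()
  res <- matching(fx$input, fx$db, backbone = "BGCI")
  enf2 <- enforce_matching(res, fx$db, "BGCI", max_depth = 2)
  expect_false(enf2$matched[enf2$Orig.Genus == "Atuna" &
                              enf2$Orig.Species == "racemosa"])
  expect_identical(sum(enf2$matched), 3L)
  enf1 <- enforce_matching(res, fx$db, "BGCI", max_depth = 1)
  expect_identical(sum(enf1$matched), 2L)
  expect_error(enforce_matching(res, fx$db, "BGCI", max_depth = 0),
               "max_depth")
})

test_that("matched rows gain monotonically with depth", {
  sim <- generate_synthetic_backbones(n_accepted = 50, misspelling_rate = 0.2,
                                      synonyms_per_accepted = 1.5,
                                      backbone_overlap = 0.5, seed = 21)
  db <- suppressMessages(synthetic_unified_db(sim))
  res <- matching(sim$input, db, backbone = "BGCI")
  g <- build_synonym_graph(db)
  prev <- NULL
  for (depth in 1:4) {
    enf <- enforce_matching(res, db, "BGCI", max_depth = depth, graph = g)
    cur <- which(enf$matched)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the BFS agrees with an independent shortest-path oracle", {
  set.seed(99)
  for (k in 1:60) {
    n <- sample(4:14, 1)
    m <- sample(0:(n * 2), 1)
    edges <- unique(data.frame(from = sample(n, m, TRUE),
                               to = sample(n, m, TRUE)))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    adj <- rep(list(integer(0)), n)
    for (r in seq_len(nrow(edges))) {
      adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
      adj[[edges$to[r]]] <- c(adj[[edges$to[r]]], edges$from[r])
    }
    graph <- list(n = n, adj = lapply(adj, unique))
    is_target <- runif(n) < 0.3
    source <- sample(n, 1)
    max_depth <- sample(1:4, 1)

    hit <- dendronym:::bfs_first_hit(graph, source, is_target, max_depth)
    oracle <- igraph_nearest(edges, n, source, is_target)
    if (is.finite(oracle$dist) && oracle$dist <= max_depth) {
      expect_false(is.null(hit))
      expect_identical(hit$dist, as.integer(oracle$dist))
      expect_identical(hit$id, min(oracle$ids))
      expect_identical(hit$hits, oracle$ids)
    } else {
      expect_null(hit)
    }
  }
})
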