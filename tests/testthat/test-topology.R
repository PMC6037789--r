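test_that("the contact cutoff separates 5.4 from 5.6 Angstrom", {
  mk <- function(gap) {
    a <- data.frame(chain = c(1L, 2L), res = 0L, atom = "CA",
                    x = c(0, gap), y = 0, z = 0)
    new_frame(a, c("G", "G"))
  }
  expect_equal(igraph::ecount(build_contact_graph(mk(5.4))), 1)
  expect_equal(igraph::ecount(build_contact_graph(mk(5.6))), 0)
  # hydrogens never create contacts
  a <- data.frame(chain = c(1L, 1L, 2L), res = 0L,
                  atom = c("CA", "H", "CA"),
                  x = c(0, 3, 7), y = 0, z = 0)
  expect_equal(igraph::ecount(build_contact_graph(new_frame(a, c("G", "G")))),
               0)
})

test_that("contact graph equals the brute-force pair scan", {
  for (s in 1:6) {
    fr <- build_coil_frame(8, "NFGAILS", seed = 200 + s,
                           arrangement = "packed")$frame
    g <- build_contact_graph(fr)
    got <- igraph::as_edgelist(g)
    ref <- brute_force_contacts(fr)
    key <- function(m) if (is.null(m) || nrow(m) == 0) character(0)
    else sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(ref))
  }
})

test_that("minimum-image contacts wrap across the box", {
  a <- data.frame(chain = c(1L, 2L), res = 0L, atom = "CA",
                  x = c(1, 39), y = 1, z = 1)
  fr <- new_frame(a, c("G", "G"), box = 40)
  expect_equal(igraph::ecount(build_contact_graph(fr)), 1)  # 2 A via image
  fr2 <- new_frame(a, c("G", "G"))
  expect_equal(igraph::ecount(build_contact_graph(fr2)), 0)  # 38 A direct
})

test_that("oligomers are connected components (oracle equivalence)", {
  g0 <- igraph::make_empty_graph(8, directed = FALSE)
  ol <- oligomers(g0)
  expect_equal(ol$sizes, rep(1L, 8))
  path6 <- igraph::make_graph(c(1,2, 2,3, 3,4, 4,5, 5,6), directed = FALSE)
  expect_equal(oligomers(path6)$sizes, 6L)
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    pairs <- t(combn(n, 2))
    edges <- pairs[stats::runif(nrow(pairs)) < 0.2, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    got <- oligomers(g)
    memb_ref <- closure_components(n, edges)
    expect_equal(sort(got$sizes), sort(as.integer(table(memb_ref))))
    expect_equal(sum(got$sizes), n)  # partition property
  }
})

test_that("adding contacts never increases the oligomer count", {
  set.seed(5)
  n <- 12
  full <- t(combn(n, 2))
  edges <- full[sample(nrow(full), 14), ]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  counts <- igraph::components(g)$no
  for (k in seq_len(nrow(edges))) {
    g <- igraph::add_edges(g, edges[k, ])
    counts <- c(counts, igraph::components(g)$no)
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("strand pairing needs two bonds and two consecutive E residues", {
  built <- build_sheet(2, motif = "antiparallel_sheet")
  fr <- built$frame
  hb <- detect_hbonds(fr)
  ss <- assign_secondary_structure(fr, hb)
  pg <- pair_strands(fr, ss, hb)
  expect_equal(igraph::ecount(pg), 1)
  expect_equal(igraph::E(pg)$orientation, "antiparallel")
  # with a single bond left, the pairing disappears
  pg1 <- pair_strands(fr, ss, hb[1, , drop = FALSE])
  expect_equal(igraph::ecount(pg1), 0)
  # parallel six-strand sheet: a path of five parallel edges
  par <- build_sheet(6, motif = "parallel_sheet")
  tp <- frame_topology(par$frame)
  ed <- igraph::as_data_frame(tp$pairing_graph, what = "edges")
  expect_equal(nrow(ed), 5)
  expect_true(all(ed$orientation == "parallel"))
  expect_true(all(ed$hbonds >= 2))
})

test_that("sheets are pairing components with induced adjacency", {
  path6 <- build_sheet(6, motif = "antiparallel_sheet")
  tp <- frame_topology(path6$frame)
  expect_length(tp$sheets, 1)
  expect_equal(tp$sheets[[1]]$size, 6L)
  expect_false(tp$sheets[[1]]$is_barrel)
  dbl <- build_sheet(3, motif = "double_layer")
  tp2 <- frame_topology(dbl$frame)
  expect_equal(sort(vapply(tp2$sheets, `[[`, integer(1), "size")), c(3L, 3L))
  # both layers share one oligomer
  expect_equal(tp2$oligomers$sizes, 6L)
})

test_that("barrel closure requires a 2-edge-connected cycle of >= 4 strands", {
  cyc <- function(n) cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))
  pat <- function(n) cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  res <- detect_barrels(list(graph_as_sheet(6, cyc(6))))
  expect_true(res$sheets[[1]]$is_barrel)
  expect_equal(res$total_barrel_size, 6L)
  expect_false(detect_barrels(list(graph_as_sheet(6, pat(6))))$
                 sheets[[1]]$is_barrel)
  expect_false(detect_barrels(list(graph_as_sheet(3, cyc(3))))$
                 sheets[[1]]$is_barrel)  # triangle below minimum size
  # a path with one doubled region is not closed
  theta <- rbind(pat(6), c(2, 5))
  expect_false(detect_barrels(list(graph_as_sheet(6, theta)))$
                 sheets[[1]]$is_barrel)
})

test_that("barrel closure matches the exhaustive brute-force check", {
  # every labeled graph on up to 5 nodes
  for (n in 2:5) {
    pairs <- t(combn(n, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      edges <- pairs[bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0, ,
                     drop = FALSE]
      got <- detect_barrels(list(graph_as_sheet(n, edges)))$
        sheets[[1]]$is_barrel
      expect_identical(got, brute_force_barrel(n, edges))
    }
  }
  # seeded random graphs on 6-8 nodes
  set.seed(77)
  for (rep in 1:150) {
    n <- sample(6:8, 1)
    pairs <- t(combn(n, 2))
    edges <- pairs[stats::runif(nrow(pairs)) < stats::runif(1, 0.2, 0.7), ,
                   drop = FALSE]
    got <- detect_barrels(list(graph_as_sheet(n, edges)))$
      sheets[[1]]$is_barrel
    expect_identical(got, brute_force_barrel(n, edges))
  }
})

test_that("beta-sheet oligomers group contacted sheets and exclude coils", {
  dbl <- build_sheet(5, motif = "double_layer")
  tp <- frame_topology(dbl$frame)
  expect_equal(tp$beta_sheet_oligomers$sizes, 10L)
  # sheet plus a detached coil: the beta-sheet oligomer excludes the coil
  sc <- build_scene(list(list(motif = "antiparallel_sheet", n_strands = 4),
                         list(motif = "coil", n_peptides = 1)), seed = 2)
  tp2 <- frame_topology(sc$frame)
  expect_equal(tp2$beta_sheet_oligomers$sizes, 4L)
  expect_equal(sort(tp2$oligomers$sizes), c(1L, 4L))
})

test_that("sheet membership partitions within oligomers", {
  built <- build_scene(list(list(motif = "barrel", n_strands = 6),
                            list(motif = "double_layer", n_strands = 3),
                            list(motif = "coil", n_peptides = 3)), seed = 8)
  tp <- frame_topology(built$frame)
  expect_equal(sum(tp$oligomers$sizes), tp$n_peptides)
  all_members <- unlist(lapply(tp$sheets, `[[`, "members"))
  expect_false(any(duplicated(all_members)))  # sheets vertex-disjoint
  # every sheet inside one oligomer
  memb <- igraph::components(tp$contact_graph)$membership
  for (s in tp$sheets)
    expect_length(unique(memb[s$members]), 1)
  # barrels are sheets
  expect_true(all(vapply(tp$sheets, function(s)
    !s$is_barrel || s$size >= 4, logical(1))))
})

test_that("frame topology serializes to JSON", {
  tp <- frame_topology(build_barrel(5)$frame)
  js <- topology_json(tp)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(parsed$total_barrel_size, 5)
  expect_length(parsed$oligomers, 1)
  expect_true(parsed$sheets[[1]]$is_barrel)
})
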