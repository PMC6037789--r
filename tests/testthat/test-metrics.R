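test_that("mass-weighted mean follows the size-squared formula", {
  expect_equal(mass_weighted_mean(4), 4.0)
  expect_equal(mass_weighted_mean(c(4, 4)), 4.0)
  expect_equal(mass_weighted_mean(c(6, 2)), 5.0)
  expect_error(mass_weighted_mean(integer(0)), "at least one")
  expect_error(mass_weighted_mean(c(3, 0)), "positive")
  set.seed(19)
  for (rep in 1:50) {
    sizes <- sample(1:20, sample(1:30, 1), replace = TRUE)
    expect_equal(mass_weighted_mean(sizes),
                 stats::weighted.mean(sizes, w = sizes))
  }
})

test_that("mass-weighted distributions normalize and weight by size", {
  d1 <- mass_weighted_distribution(list(8L, 8L, 8L))
  expect_equal(d1$size, 8L)
  expect_equal(d1$probability, 1)
  d2 <- mass_weighted_distribution(list(c(6L, 2L)))
  expect_equal(d2$probability[d2$size == 6], 0.75)
  expect_equal(d2$probability[d2$size == 2], 0.25)
  set.seed(23)
  for (rep in 1:20) {
    sizes <- replicate(5, sample(1:15, sample(1:8, 1), replace = TRUE),
                       simplify = FALSE)
    d <- mass_weighted_distribution(sizes)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
    expect_equal(attr(d, "mw_mean"), mass_weighted_mean(unlist(sizes)))
  }
  empty <- mass_weighted_distribution(list())
  expect_equal(nrow(empty), 0L)
})

test_that("beta propensity counts E observations per position", {
  mk <- function(...) {
    m <- rbind(...)
    rownames(m) <- LETTERS[seq_len(nrow(m))]
    class(m) <- c("agg_ss", class(m))
    m
  }
  allE5 <- mk(c("C", "C", "C", "C", "E"), c("C", "C", "C", "C", "E"))
  res <- residue_beta_propensity(list(allE5, allE5))
  expect_equal(res$per_residue, c(0, 0, 0, 0, 1))
  allC <- mk(rep("C", 5), rep("C", 5))
  expect_equal(residue_beta_propensity(list(allC))$per_residue, rep(0, 5))
  expect_equal(residue_beta_propensity(list(allC))$coil_content, 1)
  # residue 3 E in half the observations
  half <- residue_beta_propensity(list(
    mk(c("C", "C", "E", "C", "C")), mk(rep("C", 5))))
  expect_equal(half$per_residue[3], 0.5)
})

test_that("alignment ratio weights orientations by bond counts", {
  mkg <- function(ori, hb) {
    g <- igraph::make_empty_graph(2 * length(ori), directed = FALSE)
    igraph::add_edges(g, rbind(seq_along(ori) * 2 - 1, seq_along(ori) * 2),
                      orientation = ori, hbonds = hb)
  }
  expect_equal(alignment_ratio(mkg(c("parallel", "parallel"), c(3, 5))),
               c(antiparallel = 0, parallel = 1))
  expect_equal(alignment_ratio(mkg(c("parallel", "antiparallel"), c(4, 4))),
               c(antiparallel = 0.5, parallel = 0.5))
  expect_equal(alignment_ratio(mkg(c("parallel", "antiparallel"), c(2, 6))),
               c(antiparallel = 0.75, parallel = 0.25))
  none <- alignment_ratio(igraph::make_empty_graph(4, directed = FALSE))
  expect_true(all(is.na(none)))
  # generated frames: orientation shares follow the generated seams
  anti <- frame_topology(build_sheet(5, motif = "antiparallel_sheet")$frame)
  expect_equal(unname(alignment_ratio(anti$pairing_graph)["antiparallel"]),
               1)
  mixed <- frame_topology(build_barrel(5)$frame)  # odd: one parallel seam
  r <- alignment_ratio(mixed$pairing_graph)
  expect_gt(r[["antiparallel"]], r[["parallel"]])
  expect_gt(r[["parallel"]], 0)
  expect_equal(sum(r), 1)
})

test_that("strand length distribution histograms maximal runs", {
  mk <- function(states) {
    m <- matrix(states, nrow = 1)
    rownames(m) <- "A"
    class(m) <- c("agg_ss", class(m))
    m
  }
  d <- strand_length_distribution(list(mk(c("C", "E", "E", "E", "E", "C"))))
  expect_equal(d$length, 4L)
  expect_equal(d$probability, 1)
  expect_equal(nrow(strand_length_distribution(list(mk(rep("C", 4))))), 0L)
  mix <- strand_length_distribution(list(
    mk(c("E", "E", "C", "E", "E", "C", rep("E", 8)))))
  expect_equal(mix$probability[mix$length == 2], 2 / 3)
  expect_equal(mix$probability[mix$length == 8], 1 / 3)
})

test_that("barrel statistics count peptides inside barrels", {
  barrel6 <- frame_topology(build_barrel(6)$frame)
  expect_equal(barrel_statistics(list(barrel6))$probability, 1.0)
  coil <- frame_topology(build_coil_frame(6, seed = 4)$frame)
  none <- barrel_statistics(list(coil))
  expect_equal(none$probability, 0.0)
  expect_equal(nrow(none$size_distribution), 0L)
  # hexamer barrel among 8 peptides in half the frames: 6 / 16
  with8 <- frame_topology(build_scene(
    list(list(motif = "barrel", n_strands = 6),
         list(motif = "coil", n_peptides = 2)), seed = 1)$frame)
  without8 <- frame_topology(build_coil_frame(8, seed = 2)$frame)
  bs <- barrel_statistics(list(with8, without8))
  expect_equal(bs$probability, 6 / 16)
  expect_equal(bs$size_distribution$size, 6L)
})

test_that("time series traces track the frame topology", {
  mono <- frame_topology(build_coil_frame(8, seed = 3)$frame)
  ts1 <- aggregation_timeseries(list(mono))
  expect_equal(ts1$largest_oligomer, 1L)
  expect_equal(ts1$largest_beta_sheet_oligomer, 0L)
  expect_true(is.na(ts1$mass_weighted_mean_sheet_size))
  expect_equal(ts1$total_barrel_size, 0L)
  hex <- frame_topology(build_scene(
    list(list(motif = "barrel", n_strands = 6),
         list(motif = "coil", n_peptides = 2)), seed = 6)$frame)
  ts2 <- aggregation_timeseries(list(hex))
  expect_gte(ts2$largest_oligomer, 6)
  expect_equal(ts2$total_barrel_size, 6L)
  expect_lte(ts2$largest_beta_sheet_oligomer, ts2$largest_oligomer)
})

test_that("contact maps are symmetric, bounded and register-aware", {
  # two chains far apart: zero maps
  far <- build_scene(list(list(motif = "coil", n_peptides = 2)), seed = 12)
  maps0 <- contact_frequency_maps(list(far$frame))
  expect_true(all(maps0$backbone == 0))
  expect_true(all(maps0$sidechain == 0))
  # in-register parallel dimer: backbone map maximal on the diagonal
  par <- build_sheet(2, motif = "parallel_sheet")
  maps <- contact_frequency_maps(list(par$frame))
  expect_identical(maps$backbone, t(maps$backbone))
  expect_true(all(diag(maps$backbone)[2:10] == 1))
  expect_true(all(maps$backbone >= 0 & maps$backbone <= 1))
  # glycine row uses CA as the side-chain proxy: G at position 3 of the
  # default sequence still registers side-chain contacts
  expect_gt(max(maps$sidechain[5, ]), 0)  # position 5 is G in SNNFGAILSST
})
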