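three_seq_library <- function(d_a1a2, d_a1b1, d_a2b1 = 0.05) {
  ids <- c("a1", "a2", "b1")
  list(dm = make_dist(sym_from_upper(ids, c(d_a1a2, d_a1b1, d_a2b1))),
       labels = setNames(c("spA", "spA", "spB"), ids))
}

test_that("criterion definitions behave on the three-sequence library", {
  # close conspecific, distant heterospecific
  fx <- three_seq_library(0.003, 0.05)
  bcm <- simulate_identifications(fx$dm, fx$labels, "BCM", 0.01)
  expect_equal(bcm$outcomes$outcome[bcm$outcomes$query_id == "a1"], "correct")
  # conspecific beyond the threshold: BCM fails, BM does not
  fx2 <- three_seq_library(0.02, 0.05)
  bcm2 <- simulate_identifications(fx2$dm, fx2$labels, "BCM", 0.01)
  expect_equal(bcm2$outcomes$outcome[bcm2$outcomes$query_id == "a1"],
               "no_identification")
  bm2 <- simulate_identifications(fx2$dm, fx2$labels, "BM")
  expect_equal(bm2$outcomes$outcome[bm2$outcomes$query_id == "a1"], "correct")
  # both species inside the threshold: BIC ambiguous, BCM still correct
  fx3 <- three_seq_library(0.003, 0.008)
  bic3 <- simulate_identifications(fx3$dm, fx3$labels, "BIC", 0.01)
  expect_equal(bic3$outcomes$outcome[bic3$outcomes$query_id == "a1"],
               "ambiguous")
  bcm3 <- simulate_identifications(fx3$dm, fx3$labels, "BCM", 0.01)
  expect_equal(bcm3$outcomes$outcome[bcm3$outcomes$query_id == "a1"],
               "correct")
  # threshold comparisons are inclusive and thresholds are mandatory
  fxe <- three_seq_library(0.01, 0.05)
  bcme <- simulate_identifications(fxe$dm, fxe$labels, "BCM", 0.01)
  expect_equal(bcme$outcomes$outcome[bcme$outcomes$query_id == "a1"],
               "correct")
  expect_error(simulate_identifications(fxe$dm, fxe$labels, "BCM"),
               "threshold")
})

test_that("singletons match but never query; unlabeled records do neither", {
  ids <- c("a1", "a2", "s1", "u1")
  d <- sym_from_upper(ids, c(0.02, 0.001, 0.0005,
                             0.001, 0.0005, 0.0005))
  labels <- setNames(c("spA", "spA", "spS", ""), ids)
  bm <- simulate_identifications(make_dist(d), labels, "BM")
  expect_setequal(bm$outcomes$query_id, c("a1", "a2"))
  # closest labeled match for a1 is the singleton (0.001), not u1 (0.0005)
  expect_equal(bm$outcomes$outcome[bm$outcomes$query_id == "a1"], "incorrect")
  expect_equal(bm$outcomes$match_ids[bm$outcomes$query_id == "a1"], "s1")
})

test_that("BM ties among conspecifics stay correct, across species go ambiguous", {
  ids <- c("a1", "a2", "a3", "b1")
  d <- sym_from_upper(ids, c(0.002, 0.002, 0.002, 0.05, 0.05, 0.05))
  labels <- setNames(c("A", "A", "A", "B"), ids)
  bm <- simulate_identifications(make_dist(d), labels, "BM")
  expect_equal(bm$outcomes$outcome[bm$outcomes$query_id == "a1"], "correct")
  d2 <- sym_from_upper(ids, c(0.002, 0.05, 0.002, 0.05, 0.05, 0.002))
  bm2 <- simulate_identifications(make_dist(d2), labels, "BM")
  expect_equal(bm2$outcomes$outcome[bm2$outcomes$query_id == "a3"],
               "ambiguous")
})

test_that("outcomes always conserve the query count and respect monotonicity", {
  fx <- random_library(8, 3, seed = 77)
  for (t in c(0.001, 0.006, 0.03)) {
    for (cr in c("BCM", "BIC")) {
      res <- simulate_identifications(make_dist(fx$d), fx$labels, cr, t)
      expect_equal(sum(res$summary$count), res$n_queries)
      expect_equal(sum(res$summary$pct), 100)
    }
  }
  # raising the threshold never increases the unidentified count
  noid <- vapply(c(0.001, 0.004, 0.009, 0.03, 0.1), function(t) {
    res <- simulate_identifications(make_dist(fx$d), fx$labels, "BCM", t)
    res$summary$count[res$summary$outcome == "no_identification"]
  }, 0L)
  expect_true(all(diff(noid) <= 0))
})

test_that("cumulative-error curve counts false positives and negatives", {
  # intra <= 0.2%, inter >= 5%: any threshold between is error free
  ids <- c("a1", "a2", "b1", "b2")
  d <- sym_from_upper(ids, c(0.002, 0.05, 0.06, 0.06, 0.05, 0.001))
  labels <- setNames(c("A", "A", "B", "B"), ids)
  ce <- threshold_cumulative_error(make_dist(d), labels,
                                   grid = c(0.0005, 0.01, 0.03, 0.2))
  curve <- ce$curve
  expect_equal(curve$cumulative[curve$threshold == 0.01], 0)
  expect_equal(curve$cumulative[curve$threshold == 0.03], 0)
  # below every distance each query is a false negative
  expect_equal(curve$false_neg[curve$threshold == 0.0005], 4)
  expect_equal(curve$false_pos[curve$threshold == 0.0005], 0)
  # above every distance each query is a false positive
  expect_equal(curve$false_pos[curve$threshold == 0.2], 4)
  expect_true(all(ce$minimizers > 0.002 & ce$minimizers < 0.05))
})

test_that("density minimum lands between the modes of a bimodal pool", {
  set.seed(4)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  groups <- rep(1:3, each = 10)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (groups[i] == groups[j])
      abs(rnorm(1, 0.005, 0.001)) else abs(rnorm(1, 0.07, 0.008))
  }
  res <- threshold_density_minimum(make_dist(d))
  expect_gt(res$threshold, 0.005)
  expect_lt(res$threshold, 0.07)
  # unimodal pool: explicit no-minimum signal
  du <- matrix(0, 10, 10, dimnames = list(ids[1:10], ids[1:10]))
  du[upper.tri(du)] <- abs(rnorm(45, 0.05, 0.005))
  du[lower.tri(du)] <- t(du)[lower.tri(du)]
  # with a bandwidth at the pool's spread the density is unimodal
  expect_warning(resu <- threshold_density_minimum(make_dist(du), bw = 0.01),
                 "no interior local minimum")
  expect_true(is.na(resu$threshold))
})

test_that("the identification panel covers BM plus BCM/BIC at four thresholds", {
  sim <- generate_dataset(simulation_spec(n_species = 10, n_genera = 4,
                                          seed = 31))
  dm <- distance_matrix(sim$dataset)
  labels <- taxon_maps(sim$dataset)$species
  panel <- run_identification_panel(dm, labels)
  expect_setequal(unique(panel$criterion), c("BM", "BCM", "BIC"))
  expect_setequal(unique(panel$threshold_name),
                  c("none", "q95_intra", "bold_1pct", "cumulative_error",
                    "density_minimum"))
  # percentages in each panel column sum to 100% of queries
  cols <- split(panel, paste(panel$criterion, panel$threshold_name))
  for (cell in cols) {
    expect_equal(sum(cell$pct), 100)
    expect_equal(sum(cell$count), cell$n_queries[1])
  }
  # clean-gap library: everything correct at sensible thresholds
  bm <- panel[panel$criterion == "BM", ]
  expect_equal(bm$pct[bm$outcome == "correct"], 100)
})
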