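# group A: two sub-lineages 3% apart (0.2% within); group C: an evenly
# spaced distance continuum over [0.08%, 2.95%] that masks A's secondary
# gap in the global distribution; 8% between groups
recursive_fixture <- function() {
  ids <- c(paste0("a", 1:4), paste0("c", 1:10))
  d <- matrix(0.08, 14, 14, dimnames = list(ids, ids))
  d[1:4, 1:4] <- 0.03
  d[1:2, 1:2] <- 0.002
  d[3:4, 3:4] <- 0.002
  fill <- matrix(0, 10, 10)
  fill[upper.tri(fill)] <- seq(0.0008, 0.0295, length.out = 45)
  d[5:14, 5:14] <- fill + t(fill)
  diag(d) <- 0
  make_dist(d)
}

test_that("barcode-gap discovery separates clean clusters and flags no-gap cases", {
  sim <- generate_dataset(simulation_spec(n_species = 2, n_genera = 2,
                                          singleton_fraction = 0,
                                          target_intergeneric_divergence = 0.08,
                                          seed = 21))
  dm <- distance_matrix(sim$dataset)
  part <- abgd_partition(dm, P = 0.01, X = 1.5)
  expect_equal(part$n_motus, 2)
  expect_true(same_partition(part$assignment,
                             taxon_maps(sim$dataset)$species))
  # all sequences identical -> one MOTU, flagged
  ids <- c("x1", "x2", "x3")
  same <- make_dist(sym_from_upper(ids, c(0, 0, 0)))
  p0 <- abgd_partition(same, P = 0.01)
  expect_equal(p0$n_motus, 1)
  expect_true(p0$no_gap)
  # prior above the largest distance -> one MOTU, flagged
  phigh <- abgd_partition(dm, P = 0.5)
  expect_equal(phigh$n_motus, 1)
  expect_true(phigh$no_gap)
})

test_that("recursion re-splits groups on their own sub-distribution", {
  dm <- recursive_fixture()
  init <- abgd_partition(dm, P = 0.005, X = 1.5)
  rec <- abgd_recursive(dm, P = 0.005, X = 1.5)
  expect_equal(init$n_motus, 2)
  expect_equal(rec$n_motus, 3)
  blocks <- split(names(rec$assignment), rec$assignment)
  expect_true(all(vapply(blocks, function(b)
    setequal(b, c("a1", "a2")) || setequal(b, c("a3", "a4")) ||
      setequal(b, paste0("c", 1:10)), TRUE)))
  # a single clean gap: recursive equals initial
  ids <- c("x1", "x2", "y1", "y2")
  d2 <- make_dist(sym_from_upper(ids, c(0.002, 0.08, 0.08, 0.08, 0.08,
                                        0.002)))
  expect_equal(abgd_recursive(d2, P = 0.01)$n_motus,
               abgd_partition(d2, P = 0.01)$n_motus)
  # pairs are never re-split (minimum group size 3)
  dpair <- make_dist(sym_from_upper(c("p1", "p2"), 0.04))
  expect_equal(abgd_recursive(dpair, P = 0.001)$n_motus, 1)
})

test_that("scanning the prior grid is monotone and reports stability windows", {
  sim <- generate_dataset(simulation_spec(n_species = 8, n_genera = 3,
                                          seed = 55))
  dm <- distance_matrix(sim$dataset)
  scan <- abgd_scan(dm, P_grid = c(0.002, 0.005, 0.01, 0.02, 0.05),
                    X_values = 1.5)
  init <- scan[scan$mode == "initial", ]
  expect_true(all(diff(init$n_motus[order(init$P)]) <= 0))
  rec <- scan[scan$mode == "recursive", ]
  expect_true(all(rec$n_motus >= init$n_motus))
  expect_true(all(diff(init$stable_window[order(init$P)]) %in% 0:1))
  expect_error(abgd_scan(dm, P_grid = numeric()), "empty")
})

test_that("the parsimony connection limit matches the frozen oracle and is monotone", {
  # frozen before the implementation: straight-line evaluation of the
  # same published-intent probability model
  expect_identical(parsimony_connection_limit(658, 0.95),
                   as.integer(ref_parsimony_J(658, 0.95)))
  expect_identical(parsimony_connection_limit(360, 0.95),
                   as.integer(ref_parsimony_J(360, 0.95)))
  limits <- seq(0.90, 0.99, by = 0.01)
  J <- vapply(limits, function(l) parsimony_connection_limit(658, l), 1L)
  expect_true(all(diff(J) <= 0))
  # a limit close to 1 forces the floor
  expect_identical(parsimony_connection_limit(658, 0.999999), 1L)
})

test_that("parsimony clustering links at the step boundary and chains", {
  L <- 658
  J <- parsimony_connection_limit(L, 0.95)
  base <- strrep("A", L)
  flip <- function(s, k, from = 1) {
    ch <- strsplit(s, "")[[1]]
    ch[from:(from + k - 1)] <- "G"
    paste(ch, collapse = "")
  }
  md <- function(ids) data.frame(specimen_id = ids, species = ids,
                                 genus = "g", family = "f", latitude = 0,
                                 longitude = 0, locality = "")
  dsJ <- barcode_dataset(c(h1 = base, h2 = flip(base, J)), md(c("h1", "h2")))
  expect_equal(tcs_cluster(dsJ, 0.95)$n_motus, 1)
  dsJ1 <- barcode_dataset(c(h1 = base, h2 = flip(base, J + 1)),
                          md(c("h1", "h2")))
  expect_equal(tcs_cluster(dsJ1, 0.95)$n_motus, 2)
  # chain a-b-c: a,c differ by 2J but connect through b
  chain <- barcode_dataset(c(a = base, b = flip(base, J),
                             c = flip(base, 2 * J)),
                           md(c("a", "b", "c")))
  expect_equal(tcs_cluster(chain, 0.95)$n_motus, 1)
  # stricter limits can only split further
  sim <- generate_dataset(simulation_spec(n_species = 8, n_genera = 3,
                                          seed = 14))
  expect_lte(tcs_cluster(sim$dataset, 0.90)$n_motus,
             tcs_cluster(sim$dataset, 0.99)$n_motus)
})

test_that("stricter parsimony partitions refine looser ones", {
  sim <- generate_dataset(simulation_spec(n_species = 6, n_genera = 2,
                                          seed = 77))
  loose <- tcs_cluster(sim$dataset, 0.90)$assignment
  strict <- tcs_cluster(sim$dataset, 0.99)$assignment
  for (blk in split(names(strict), strict))
    expect_length(unique(loose[blk]), 1)
})

test_that("refined single linkage splits sub-lineages but not uniform components", {
  # two tight clusters 5% apart separate already at the seed threshold
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.002
  d[4:6, 4:6] <- 0.002
  diag(d) <- 0
  expect_equal(resl_cluster(make_dist(d))$n_motus, 2)
  # one seed component holding two sub-lineages 1.8% apart
  d2 <- matrix(0.018, 6, 6, dimnames = list(ids, ids))
  d2[1:3, 1:3] <- 0.003
  d2[4:6, 4:6] <- 0.003
  diag(d2) <- 0
  p2 <- resl_cluster(make_dist(d2))
  expect_equal(p2$n_motus, 2)
  expect_true(same_partition(p2$assignment,
                             setNames(c(1, 1, 1, 2, 2, 2), ids)))
  # uniform within-component distances: nothing to improve, no split
  d3 <- matrix(0.01, 6, 6, dimnames = list(ids, ids))
  diag(d3) <- 0
  expect_equal(resl_cluster(make_dist(d3))$n_motus, 1)
})

test_that("every partition is a total, disjoint assignment", {
  sim <- generate_dataset(simulation_spec(n_species = 8, n_genera = 3,
                                          seed = 4))
  dm <- distance_matrix(sim$dataset)
  parts <- list(abgd_partition(dm, 0.01), abgd_recursive(dm, 0.01),
                tcs_cluster(sim$dataset), resl_cluster(dm))
  for (p in parts) {
    expect_setequal(names(p$assignment), dm$ids)
    expect_false(anyNA(p$assignment))
    expect_equal(p$n_motus, length(unique(p$assignment)))
  }
})
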