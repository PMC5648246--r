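two_genus_fixture <- function() {
  # two species x two identical individuals each, 5% apart, same genus
  ids <- c("a1", "a2", "b1", "b2")
  d <- sym_from_upper(ids, c(0, 0.05, 0.05, 0.05, 0.05, 0))
  labels <- setNames(c("A", "A", "B", "B"), ids)
  genera <- c(A = "G", B = "G")
  list(dm = make_dist(d), labels = labels, genera = genera)
}

test_that("divergence summaries enumerate the pools correctly", {
  fx <- two_genus_fixture()
  sm <- divergence_summaries(fx$dm, fx$labels, fx$genera)
  expect_equal(sm$intraspecific$mean, 0)
  expect_equal(sm$intraspecific$n_comparisons, 2)
  expect_equal(sm$congeneric$mean, 0.05)
  expect_equal(sm$congeneric$n_comparisons, 4)
  expect_equal(sm$intraspecific$n_species, 2)
  # a single-species data set has no congeneric summary, not a zero one
  ids <- c("a1", "a2")
  one <- make_dist(sym_from_upper(ids, 0.01))
  sm1 <- divergence_summaries(one, setNames(c("A", "A"), ids), c(A = "G"))
  expect_null(sm1$congeneric)
  expect_equal(sm1$intraspecific$n_comparisons, 1)
})

test_that("gap profile captures furthest conspecific, nearest neighbour and sharing", {
  toy <- generate_worked_toy()
  dm <- distance_matrix(toy$dataset)
  maps <- taxon_maps(toy$dataset)
  gp <- gap_profile(dm, maps$species)
  ps <- gp$per_sequence
  row <- function(id) ps[ps$specimen_id == id, ]
  # AL01-1 and AL02-3 share a haplotype across species
  expect_equal(row("AL01-1")$nn_distance, 0)
  expect_equal(row("AL02-3")$nn_distance, 0)
  spv <- gp$per_species
  expect_false(spv$gap_present[spv$species == "Alpha una"])
  expect_false(spv$gap_present[spv$species == "Alpha dua"])
  # singleton: no conspecific distance, NN defined
  expect_true(is.na(row("BE01-1")$max_conspecific))
  expect_gt(row("BE01-1")$nn_distance, 0)
  expect_true(is.na(spv$gap_present[spv$species == "Beta sola"]))
  expect_true(all(ps$nn_taxon != ps$species))
})

test_that("nearest-neighbour distances equal the brute-force row minima", {
  sim <- generate_dataset(simulation_spec(n_species = 12, n_genera = 4,
                                          seed = 9))
  dm <- distance_matrix(sim$dataset)
  labels <- taxon_maps(sim$dataset)$species
  gp <- gap_profile(dm, labels)
  for (k in sample(nrow(gp$per_sequence), 20)) {
    id <- gp$per_sequence$specimen_id[k]
    i <- match(id, dm$ids)
    het <- labels[dm$ids] != labels[[id]]
    expect_equal(gp$per_sequence$nn_distance[k], min(dm$d[i, het]))
  }
  # removing a species can only raise the remaining NN distances
  drop_sp <- gp$per_sequence$species[1]
  keep <- names(labels)[labels != drop_sp]
  dm2 <- make_dist(dm$d[match(keep, dm$ids), match(keep, dm$ids)])
  gp2 <- gap_profile(dm2, labels[keep])
  shared <- intersect(gp$per_sequence$specimen_id,
                      gp2$per_sequence$specimen_id)
  before <- setNames(gp$per_sequence$nn_distance,
                     gp$per_sequence$specimen_id)[shared]
  after <- setNames(gp2$per_sequence$nn_distance,
                    gp2$per_sequence$specimen_id)[shared]
  expect_true(all(after >= before - 1e-15))
})

test_that("generator-separated species all show the barcode gap", {
  for (s in 1:3) {
    sim <- generate_dataset(simulation_spec(n_species = 10, n_genera = 4,
                                            seed = 200 + s))
    dm <- distance_matrix(sim$dataset)
    gp <- gap_profile(dm, taxon_maps(sim$dataset)$species)
    multi <- !is.na(gp$per_species$gap_present)
    expect_true(all(gp$per_species$gap_present[multi]))
  }
})

test_that("empirical thresholds follow the declared percentile rule", {
  ids <- c("a1", "a2", "a3", "a4", "b1", "b2")
  d <- matrix(0.06, 6, 6, dimnames = list(ids, ids))
  d[1:4, 1:4] <- 0
  d[3, 4] <- d[4, 3] <- 0.01
  d[5, 6] <- d[6, 5] <- 0
  diag(d) <- 0
  labels <- setNames(c("A", "A", "A", "A", "B", "B"), ids)
  genera <- c(A = "G", B = "G")
  dm <- make_dist(d)
  # intra pool sorted: {0 x6, 0.01}; linear interpolation between closest
  # ranks puts the 95th percentile at rank 6.7 -> 0.7 * 0.01
  th <- empirical_thresholds(dm, labels, genera)
  expect_equal(th$q95_intra, 0.007)
  expect_equal(th$q05_congeneric, 0.06)
  # all-equal pool: the percentile is that constant
  dc <- make_dist(sym_from_upper(c("x1", "x2", "y1"), c(0.004, 0.05, 0.05)))
  thc <- empirical_thresholds(dc, setNames(c("X", "X", "Y"), c("x1", "x2", "y1")),
                              c(X = "G", Y = "G"))
  expect_equal(thc$q95_intra, 0.004)
  expect_error(empirical_thresholds(dc, setNames(c("X", "Y", "Z"),
                                                 c("x1", "x2", "y1")),
                                    c(X = "G", Y = "G", Z = "G")),
               "empty intraspecific")
})

test_that("singleton distinctiveness combines sharing and tree nesting", {
  toy <- generate_worked_toy()
  dm <- distance_matrix(toy$dataset)
  labels <- taxon_maps(toy$dataset)$species
  tree <- suppressMessages(nj_build(dm))
  res <- assess_singletons(dm, labels, tree)
  expect_equal(res$specimen_id, "BE01-1")
  expect_true(res$distinguishable)
  # a singleton identical to a non-conspecific is never distinguishable
  ids <- c("a1", "a2", "a3", "s1")
  d <- sym_from_upper(ids, c(0.002, 0.002, 0.002, 0.002, 0.002, 0))
  labels2 <- setNames(c("A", "A", "A", "S"), ids)
  tree2 <- suppressMessages(nj_build(make_dist(sym_from_upper(
    ids, c(0.002, 0.002, 0.05, 0.002, 0.05, 0.05)))))
  res2 <- assess_singletons(make_dist(d), labels2, tree2)
  expect_true(res2$shares_barcode)
  expect_false(res2$distinguishable)
  # a singleton attached inside another species' clade is nested
  t5 <- ape::read.tree(text = "(out:1,(b1:0.1,((s1:0.05,b2:0.05):0.05,b3:0.1):0.02):0.5);")
  ids5 <- c("out", "b1", "b2", "b3", "s1")
  d5 <- tree_metric(t5)[ids5, ids5]
  labels5 <- setNames(c("O", "B", "B", "B", "S"), ids5)
  res5 <- assess_singletons(make_dist(d5), labels5, t5)
  s_row <- res5[res5$specimen_id == "s1", ]
  expect_true(s_row$nested)
  expect_false(s_row$distinguishable)
  expect_error(assess_singletons(make_dist(d5), labels5,
                                 ape::drop.tip(t5, "s1")),
               "absent from tree")
})
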