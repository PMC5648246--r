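# Independent brute-force oracles and tiny fixture builders. Everything
# here is deliberately written as plain enumeration, separate from the
# package's implementation paths.

# barcode_dist object from a hand-built symmetric matrix
make_dist <- function(m, ids = rownames(m), model = "K2P") {
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, d = m, sites = matrix(100, nrow(m), ncol(m)),
                 model = model, deletion = "pairwise"),
            class = "barcode_dist")
}

# symmetric matrix from the upper-triangle values given row by row
sym_from_upper <- function(ids, values) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# literal re-statement of the identification criteria, one query at a time
bf_identify <- function(d, labels, query, criterion, threshold = NULL) {
  others <- setdiff(names(labels), query)
  dq <- d[query, others]
  sp <- labels[query]
  if (criterion == "BM") {
    best <- min(dq)
    best_sp <- unique(labels[others[dq == best]])
    if (length(best_sp) >= 2) return("ambiguous")
    return(if (best_sp == sp) "correct" else "incorrect")
  }
  inside <- others[dq <= threshold]
  if (length(inside) == 0) return("no_identification")
  if (criterion == "BCM") {
    best <- min(dq[dq <= threshold])
    best_sp <- unique(labels[others[dq == best & dq <= threshold]])
    if (length(best_sp) >= 2) return("ambiguous")
    return(if (best_sp == sp) "correct" else "incorrect")
  }
  # BIC: every candidate inside the threshold must agree
  sps <- unique(labels[inside])
  if (length(sps) >= 2) return("ambiguous")
  if (sps == sp) "correct" else "incorrect"
}

# connected components by breadth-first search over an adjacency matrix
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  setNames(comp, rownames(adj))
}

# do two cluster assignments describe the same set partition?
same_partition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(a))]
  blocks <- function(x) unname(lapply(split(names(x), x), sort))
  setequal(blocks(a), blocks(b))
}

# concordance categories by direct set analysis
bf_classify <- function(assignment, labels) {
  labels <- labels[names(labels) %in% names(assignment)]
  out <- character()
  for (sp in unique(labels)) {
    ids <- names(labels)[labels == sp]
    motus <- unique(assignment[ids])
    pure <- vapply(motus, function(m) {
      members <- names(assignment)[assignment == m]
      all(labels[members] == sp)
    }, TRUE)
    out[sp] <- if (length(motus) == 1 && all(pure)) "MATCH"
      else if (length(motus) > 1 && all(pure)) "SPLIT"
      else if (length(motus) == 1) "MERGE"
      else "MIXTURE"
  }
  out
}

# Straight-line evaluation of the parsimony-probability model used for
# the connection limit: per-site Poisson hits at the Jukes-Cantor
# corrected rate; parsimony = one hit per differing site, none per
# identical site. Written as explicit loops, frozen as the oracle.
ref_parsimony_prob <- function(j, m) {
  p <- j / m
  lambda <- -0.75 * log(1 - 4 * p / 3)
  pk <- function(k) exp(-lambda) * lambda^k / factorial(k)
  same_after <- function(k) 0.25 + 0.75 * (-1 / 3)^k
  p_same <- 0
  p_diff <- 0
  for (k in 0:50) {
    p_same <- p_same + pk(k) * same_after(k)
    p_diff <- p_diff + pk(k) * (1 - same_after(k))
  }
  (pk(1) / p_diff)^j * (pk(0) / p_same)^(m - j)
}

ref_parsimony_J <- function(m, limit) {
  J <- 1
  for (j in 2:m) {
    if (ref_parsimony_prob(j, m) < limit) break
    J <- j
  }
  J
}

# random small library with deliberate ties for identification tests
random_library <- function(n, n_species, seed) {
  set.seed(seed)
  ids <- sprintf("q%02d", seq_len(n))
  pool <- c(0, 0.002, 0.005, 0.008, 0.01, 0.02, 0.05, 0.08)
  d <- sym_from_upper(ids, sample(pool, n * (n - 1) / 2, replace = TRUE))
  labels <- setNames(sample(paste0("sp", seq_len(n_species)), n,
                            replace = TRUE), ids)
  # guarantee at least two species with >= 2 members
  labels[1:2] <- "sp1"
  labels[3:4] <- "sp2"
  list(d = d, labels = labels)
}

# additive distance matrix from a phylo tree (independent of nj_build)
tree_metric <- function(phy) {
  ape::cophenetic.phylo(phy)
}
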