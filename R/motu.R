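# ---- partition container -------------------------------------------------

new_partition <- function(method, params, assignment, ...) {
  assignment <- setNames(as.integer(factor(assignment)), names(assignment))
  structure(c(list(method = method, params = params,
                   assignment = assignment,
                   n_motus = length(unique(assignment))),
              list(...)),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("motu_partition:", x$method, "-", x$n_motus, "MOTUs over",
      length(x$assignment), "sequences\n")
  if (isTRUE(x$no_gap)) cat("  (no significant gap found)\n")
  invisible(x)
}

# single-linkage components at threshold h: clusters of the graph linking
# every pair with distance <= h
.single_linkage_cut <- function(d, h) {
  n <- nrow(d)
  if (n == 1L) return(setNames(1L, rownames(d)))
  cutree(hclust(stats::as.dist(d), method = "single"), h = h)
}

.check_complete <- function(d) {
  if (anyNA(d[upper.tri(d)]))
    stop("distance matrix contains inestimable (NA) pairs; ",
         "filter or impute before clustering")
}

# ---- barcode-gap discovery ----------------------------------------------

# Locate the first significant gap above the prior P in a set of
# distances. Detection runs on sorted unique values (tie handling);
# local slope = mean of up to `window` preceding unique-value gaps; a
# gap is significant when wider than X times that slope. A candidate
# with no preceding gaps carries no slope information and must instead
# be at least `min_gap` wide. Returns the distance at which to cut (the
# gap's lower edge) or NULL.
.find_gap <- function(dvals, P, X, window = 10, min_gap = P) {
  dv <- sort(unique(dvals[!is.na(dvals)]))
  if (length(dv) < 2) return(NULL)
  g <- diff(dv)
  for (i in seq_along(g)) {
    if (dv[i + 1] <= P) next
    prev <- g[seq(max(1, i - window), length.out = min(window, i - 1))]
    if (length(prev) == 0) {
      if (g[i] >= min_gap) return(dv[i])
      next
    }
    if (g[i] > X * mean(prev)) return(dv[i])
  }
  NULL
}

#' ABGD-style initial partition
#'
#' Automatic barcode-gap discovery: sorts all pairwise distances, finds
#' the first gap above the prior intraspecific divergence `P` whose width
#' exceeds `X` times a local slope measure of the ranked-distance
#' distribution, and partitions the sequences into the connected
#' components of the graph linking every pair below the gap. When no
#' significant gap exists (e.g. `P` above the largest distance) the
#' result is a single MOTU flagged `no_gap`.
#'
#' Internals left open by the method description are fixed and exposed
#' here: detection runs on the sorted unique distance values; the local
#' slope is the mean of up to `window` preceding unique-value gaps; a
#' candidate gap with no preceding gaps (nothing below it but ties)
#' carries no slope information and must instead reach `min_gap`
#' (default: the prior itself, so such a gap is never narrower than the
#' assumed intraspecific divergence).
#'
#' @param dm a `barcode_dist` (K2P by default in this package; p-distance
#'   matrices work identically).
#' @param P prior intraspecific divergence (fraction).
#' @param X relative gap width.
#' @param window unique-value gaps entering the local slope.
#' @param min_gap minimum absolute width for a gap detected without
#'   local slope information.
#' @return a `motu_partition` with the detected `gap` (lower edge, `NA`
#'   when none) and `no_gap` flag.
#' @export
abgd_partition <- function(dm, P = 0.01, X = 1.5, window = 10,
                           min_gap = P) {
  stopifnot(P > 0, X > 0)
  .check_complete(dm$d)
  d <- dm$d
  dimnames(d) <- list(dm$ids, dm$ids)
  cut_at <- .find_gap(d[upper.tri(d)], P, X, window, min_gap)
  params <- list(P = P, X = X, window = window, min_gap = min_gap)
  if (is.null(cut_at))
    return(new_partition("ABGD_initial", params,
                         setNames(rep(1L, length(dm$ids)), dm$ids),
                         gap = NA_real_, no_gap = TRUE))
  new_partition("ABGD_initial", params, .single_linkage_cut(d, cut_at),
                gap = cut_at, no_gap = FALSE)
}

#' ABGD-style recursive partition
#'
#' Applies [abgd_partition()] and then re-runs gap detection inside each
#' resulting group using that group's own distance sub-distribution,
#' recursing until no group splits further. Groups with fewer than
#' `min_group` sequences are never re-split. Recursive MOTU counts are
#' therefore always >= the initial count.
#'
#' @inheritParams abgd_partition
#' @param min_group smallest group eligible for re-splitting.
#' @return a `motu_partition` of method `ABGD_recursive`.
#' @export
abgd_recursive <- function(dm, P = 0.01, X = 1.5, window = 10,
                           min_gap = P, min_group = 3) {
  init <- abgd_partition(dm, P, X, window, min_gap)
  d <- dm$d
  dimnames(d) <- list(dm$ids, dm$ids)
  final <- list()
  queue <- split(names(init$assignment), init$assignment)
  while (length(queue)) {
    grp <- queue[[1]]
    queue <- queue[-1]
    if (length(grp) < min_group) {
      final[[length(final) + 1]] <- grp
      next
    }
    sub <- d[grp, grp, drop = FALSE]
    cut_at <- .find_gap(sub[upper.tri(sub)], P, X, window, min_gap)
    if (is.null(cut_at)) {
      final[[length(final) + 1]] <- grp
      next
    }
    parts <- .single_linkage_cut(sub, cut_at)
    if (length(unique(parts)) == 1L) {
      final[[length(final) + 1]] <- grp
    } else {
      queue <- c(queue, split(grp, parts))
    }
  }
  assignment <- integer(0)
  for (k in seq_along(final))
    assignment[final[[k]]] <- k
  new_partition("ABGD_recursive",
                c(init$params, list(min_group = min_group)),
                assignment[dm$ids],
                gap = init$gap, no_gap = isTRUE(init$no_gap))
}

#' Scan ABGD partitions over a grid of priors and gap widths
#'
#' One initial and one recursive partition per `(P, X)` combination.
#' Adjacent priors yielding an identical initial partition form a
#' stability window, reported via the `stable_window` column (runs share
#' an integer id per `X` and mode).
#'
#' @inheritParams abgd_partition
#' @param P_grid prior values (fractions), non-empty.
#' @param X_values relative gap widths.
#' @return data frame: `P`, `X`, `mode` (initial/recursive), `n_motus`,
#'   `gap`, `stable_window`.
#' @export
abgd_scan <- function(dm, P_grid = exp(seq(log(0.001), log(0.1),
                                           length.out = 15)),
                      X_values = c(1, 1.5), window = 10) {
  if (length(P_grid) == 0) stop("empty P grid")
  rows <- list()
  for (X in X_values) {
    sig_prev <- list(initial = NULL, recursive = NULL)
    win <- setNames(c(0L, 0L), c("initial", "recursive"))
    for (P in sort(P_grid)) {
      parts <- list(initial = abgd_partition(dm, P, X, window),
                    recursive = abgd_recursive(dm, P, X, window))
      for (mode in names(parts)) {
        sig <- unname(parts[[mode]]$assignment)
        if (is.null(sig_prev[[mode]]) || !identical(sig, sig_prev[[mode]]))
          win[[mode]] <- win[[mode]] + 1L
        sig_prev[[mode]] <- sig
        rows[[length(rows) + 1]] <-
          data.frame(P = P, X = X, mode = mode,
                     n_motus = parts[[mode]]$n_motus,
                     gap = parts[[mode]]$gap,
                     stable_window = win[[mode]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- statistical parsimony ----------------------------------------------

# Probability that parsimony holds for two sequences of length m
# differing at j sites: no site carries a superimposed substitution.
# Hits per site are Poisson with per-site expectation estimated from the
# observed difference count through the Jukes-Cantor correction; the
# chance that a differing site saw exactly one hit and an identical site
# none is combined over all m sites. Truncation at 50 hits per site is
# far beyond barcode-scale divergence.
.parsimony_probability <- function(j, m, kmax = 50) {
  if (j == 0) return(1)
  p <- j / m
  if (p >= 0.75) return(0)
  lambda <- -0.75 * log(1 - 4 * p / 3)
  k <- 0:kmax
  pois <- stats::dpois(k, lambda)
  same_k <- 0.25 + 0.75 * (-1 / 3)^k       # P(base unchanged after k hits)
  p_same <- sum(pois * same_k)
  p_diff <- sum(pois * (1 - same_k))
  term_diff <- (pois[2] * 1) / p_diff       # one hit always changes the base
  term_same <- pois[1] / p_same
  term_diff^j * term_same^(m - j)
}

#' Connection limit for statistical-parsimony clustering
#'
#' The largest number of mutational steps `J` for which the probability
#' of parsimony (no superimposed change at any site, estimated from the
#' sequence length) still reaches `limit`. `J` is floored at 1 and is
#' non-increasing in `limit`.
#'
#' @param aligned_length alignment length in positions.
#' @param limit parsimony limit in (0, 1), conventionally 0.90-0.99.
#' @return integer number of steps.
#' @export
parsimony_connection_limit <- function(aligned_length, limit = 0.95) {
  stopifnot(aligned_length > 0, limit > 0, limit < 1)
  j <- 1
  while (j < aligned_length &&
         .parsimony_probability(j + 1, aligned_length) >= limit)
    j <- j + 1
  as.integer(j)
}

#' Statistical-parsimony clustering of a barcode data set
#'
#' Computes absolute pairwise mutational differences (count of differing
#' comparable sites) and links every pair differing by at most `J` steps,
#' where `J` comes from [parsimony_connection_limit()]; MOTUs are the
#' connected components, so networks chain like single linkage.
#'
#' @param ds a [barcode_dataset()].
#' @param limit parsimony limit.
#' @return a `motu_partition` of method `TCS` with params `limit` and the
#'   derived `J`.
#' @export
tcs_cluster <- function(ds, limit = 0.95) {
  J <- parsimony_connection_limit(ds$alignment_length, limit)
  diffs <- pairwise_diff_counts(ds)$diff
  new_partition("TCS", list(limit = limit, J = J),
                .single_linkage_cut(diffs, J))
}

# ---- refined single linkage ---------------------------------------------

# mean silhouette width of a clustering over a distance submatrix;
# singleton clusters contribute 0 by convention
.mean_silhouette <- function(d, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(d[i, cl == k]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Refined single-linkage clustering
#'
#' A locally reproducible, simplified take on refined single linkage:
#' stage one forms single-linkage components at `seed_threshold`; stage
#' two evaluates, inside each component, every candidate split threshold
#' across `refine_range` (the component's own merge heights) and keeps
#' the split maximising the mean silhouette width over the component's
#' distance submatrix. A component is split only when that best
#' silhouette exceeds `accept_silhouette`; an unsplit component carries
#' no silhouette, so the acceptance mark plays the role of "improves on
#' the unsplit component". This is not the database-wide BOLD
#' implementation; counts against it are a soft check only.
#'
#' @param dm a `barcode_dist`.
#' @param seed_threshold single-linkage seed threshold (fraction).
#' @param refine_range interval of candidate split thresholds; its upper
#'   bound must be at least `seed_threshold`'s refinement floor.
#' @param accept_silhouette minimum mean silhouette width for accepting a
#'   split.
#' @return a `motu_partition` of method `RESL`.
#' @export
resl_cluster <- function(dm, seed_threshold = 0.022,
                         refine_range = c(0.007, 0.022),
                         accept_silhouette = 0.5) {
  stopifnot(length(refine_range) == 2, refine_range[1] < refine_range[2],
            seed_threshold <= refine_range[2] + 1e-12)
  .check_complete(dm$d)
  d <- dm$d
  dimnames(d) <- list(dm$ids, dm$ids)
  seeds <- .single_linkage_cut(d, seed_threshold)
  final <- list()
  for (comp in split(names(seeds), seeds)) {
    if (length(comp) < 3) {
      final[[length(final) + 1]] <- comp
      next
    }
    sub <- d[comp, comp]
    hc <- hclust(stats::as.dist(sub), method = "single")
    cand <- unique(hc$height)
    cand <- cand[cand >= refine_range[1] & cand <= refine_range[2]]
    best <- NULL
    best_sil <- -Inf
    for (h in cand) {
      cl <- cutree(hc, h = h - 1e-12)
      if (length(unique(cl)) < 2) next
      sil <- .mean_silhouette(sub, cl)
      if (sil > best_sil) {
        best_sil <- sil
        best <- cl
      }
    }
    if (!is.null(best) && best_sil > accept_silhouette) {
      final <- c(final, split(comp, best))
    } else {
      final[[length(final) + 1]] <- comp
    }
  }
  assignment <- integer(0)
  for (k in seq_along(final)) assignment[final[[k]]] <- k
  new_partition("RESL",
                list(seed_threshold = seed_threshold,
                     refine_range = refine_range,
                     accept_silhouette = accept_silhouette),
                assignment[dm$ids])
}

#' Export a partition as a TSV table
#'
#' @param partition a `motu_partition`.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(specimen_id = names(partition$assignment),
                   motu = unname(partition$assignment),
                   method = partition$method,
                   params = paste(names(partition$params),
                                  vapply(partition$params, function(p)
                                    paste(format(p), collapse = ";"),
                                    character(1)),
                                  sep = "=", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
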