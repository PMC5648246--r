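# queries: labeled members of species with >= 2 sequences; candidates:
# every labeled sequence except the query itself (singletons can match,
# unlabeled records can neither query nor match).
.query_sets <- function(dm, labels) {
  labels <- .labeled(dm, labels)
  tab <- table(labels)
  list(labels = labels,
       queries = names(labels)[labels %in% names(tab)[tab >= 2]])
}

.outcome_levels <- c("correct", "incorrect", "ambiguous", "no_identification")

# species-set -> outcome, given the query's species
.score_species_set <- function(sps, sp_q) {
  if (length(sps) > 1) "ambiguous"
  else if (sps == sp_q) "correct"
  else "incorrect"
}

#' Simulate sequence-based identification of every eligible query
#'
#' Leave-one-out simulation: each member of a species with two or more
#' sequences is treated as an unknown and matched against the rest of the
#' library (its own record removed; singletons stay in as potential
#' matches). Criteria: Best Match (`BM`) names the query after the
#' closest match regardless of divergence; Best Close Match (`BCM`) does
#' the same but only considers matches within the threshold (none inside
#' -> no identification); the BOLD-style criterion (`BIC`) requires every
#' candidate within the threshold to agree (all conspecific -> correct,
#' several species -> ambiguous, all one other species -> incorrect).
#' Ties spanning two or more species are ambiguous; ties among
#' conspecifics only are correct. "Within the threshold" is inclusive
#' (`<=`).
#'
#' @param dm a `barcode_dist`.
#' @param labels named character vector: specimen id -> species.
#' @param criterion `"BM"`, `"BCM"` or `"BIC"`.
#' @param threshold distance fraction; required for BCM/BIC, ignored by BM.
#' @return list with `outcomes` (one row per query: outcome and the
#'   contributing match ids) and `summary` (counts and percentages per
#'   outcome; categories always sum to the query count).
#' @export
simulate_identifications <- function(dm, labels,
                                     criterion = c("BM", "BCM", "BIC"),
                                     threshold = NULL) {
  criterion <- match.arg(criterion)
  if (criterion != "BM" && is.null(threshold))
    stop(criterion, " requires a threshold")
  qs <- .query_sets(dm, labels)
  labels <- qs$labels
  idx <- setNames(match(names(labels), dm$ids), names(labels))
  rows <- lapply(qs$queries, function(q) {
    cand <- setdiff(names(labels), q)
    dq <- dm$d[idx[[q]], idx[cand]]
    keep <- !is.na(dq)
    cand <- cand[keep]; dq <- dq[keep]
    sp_q <- labels[[q]]
    if (criterion == "BM") {
      tied <- cand[dq == min(dq)]
      outcome <- .score_species_set(unique(labels[tied]), sp_q)
      match_ids <- tied
    } else {
      within <- dq <= threshold
      if (!any(within)) {
        outcome <- "no_identification"
        match_ids <- character()
      } else if (criterion == "BCM") {
        dc <- dq[within]; cc <- cand[within]
        tied <- cc[dc == min(dc)]
        outcome <- .score_species_set(unique(labels[tied]), sp_q)
        match_ids <- tied
      } else {
        match_ids <- cand[within]
        outcome <- .score_species_set(unique(labels[match_ids]), sp_q)
      }
    }
    data.frame(query_id = q, species = sp_q, criterion = criterion,
               threshold = if (is.null(threshold)) NA_real_ else threshold,
               outcome = outcome,
               match_ids = paste(match_ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  counts <- table(factor(outcomes$outcome, levels = .outcome_levels))
  list(outcomes = outcomes,
       summary = data.frame(outcome = .outcome_levels,
                            count = as.integer(counts),
                            pct = 100 * as.integer(counts) / length(qs$queries)),
       n_queries = length(qs$queries))
}

#' Cumulative-error threshold optimisation
#'
#' For each candidate threshold `t`, a query is a false negative when its
#' nearest conspecific lies beyond `t` (it would go unidentified) and a
#' false positive when at least one non-conspecific lies within `t`. The
#' cumulative error is their sum over all queries; the error curve is
#' piecewise constant between observed distances, so the default grid is
#' every observed distinct distance plus the midpoints between
#' consecutive ones.
#'
#' @inheritParams simulate_identifications
#' @param grid candidate thresholds (fractions); default as described.
#' @return list with `curve` (data frame `threshold`, `false_neg`,
#'   `false_pos`, `cumulative`), `minimizers` (all thresholds attaining
#'   the minimum), `band` (their range) and `threshold` (the band
#'   midpoint, the value the identification panel uses).
#' @export
threshold_cumulative_error <- function(dm, labels, grid = NULL) {
  qs <- .query_sets(dm, labels)
  labels <- qs$labels
  idx <- setNames(match(names(labels), dm$ids), names(labels))
  nearest <- vapply(qs$queries, function(q) {
    con <- names(labels)[labels == labels[[q]]]
    con <- setdiff(con, q)
    het <- names(labels)[labels != labels[[q]]]
    c(con = min(dm$d[idx[[q]], idx[con]], na.rm = TRUE),
      het = min(dm$d[idx[[q]], idx[het]], na.rm = TRUE))
  }, c(con = 0, het = 0))
  if (is.null(grid)) {
    obs <- sort(unique(c(nearest["con", ], nearest["het", ])))
    grid <- sort(unique(c(obs, obs[-length(obs)] + diff(obs) / 2)))
  }
  if (length(grid) == 0) stop("empty threshold grid")
  fn <- vapply(grid, function(t) sum(nearest["con", ] > t), 0)
  fp <- vapply(grid, function(t) sum(nearest["het", ] <= t), 0)
  cum <- fn + fp
  minimizers <- grid[cum == min(cum)]
  list(curve = data.frame(threshold = grid, false_neg = fn,
                          false_pos = fp, cumulative = cum),
       minimizers = minimizers,
       band = range(minimizers),
       threshold = mean(range(minimizers)))
}

#' Density-minimum threshold
#'
#' Gaussian kernel density over all pairwise distances (bandwidth by
#' `bw.nrd0`, 512-point grid spanning `[0, max]`); the threshold is the
#' first interior local minimum — the dip where the density leaves the
#' intraspecific peak, taken as the transition between intra- and
#' interspecific distances (sparse far-tail regions also produce local
#' minima, which is why the first, not the deepest, is used). A unimodal
#' pool has no interior minimum: the function warns and returns `NA`,
#' and the caller falls back to a configured default.
#'
#' @param dm a `barcode_dist`.
#' @param bw bandwidth rule or value, passed to [stats::density()].
#' @param n_grid grid size.
#' @return list with `threshold` (`NA` when no interior minimum),
#'   `density` (the `density` object) and `minima` (all interior minima).
#' @export
threshold_density_minimum <- function(dm, bw = "nrd0", n_grid = 512) {
  x <- dm$d[upper.tri(dm$d)]
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2) stop("need at least 2 distinct distances")
  dens <- density(x, bw = bw, n = n_grid, from = 0, to = max(x))
  y <- dens$y
  interior <- 2:(length(y) - 1)
  is_min <- y[interior] < y[interior - 1] & y[interior] < y[interior + 1]
  minima <- dens$x[interior][is_min]
  if (length(minima) == 0) {
    warning("no interior local minimum in the distance density")
    return(list(threshold = NA_real_, density = dens, minima = numeric()))
  }
  list(threshold = minima[1], density = dens, minima = minima)
}

#' Identification panel over all criteria and thresholds
#'
#' Runs BM once and BCM/BIC at four thresholds: the 95th percentile of
#' intraspecific distances, the fixed 1% convention, the
#' cumulative-error optimum and the density minimum. Emits counts and
#' percentages per cell; percentages in every column sum to 100% of the
#' queries.
#'
#' @inheritParams simulate_identifications
#' @param thresholds optional named numeric vector replacing the four
#'   defaults.
#' @param density_fallback threshold to use when the distance density has
#'   no interior minimum (default: drop that column with a warning).
#' @return data frame: `criterion`, `threshold_name`, `threshold`,
#'   `outcome`, `count`, `pct`, `n_queries`.
#' @export
run_identification_panel <- function(dm, labels, thresholds = NULL,
                                     density_fallback = NULL) {
  if (is.null(thresholds)) {
    labs <- .labeled(dm, labels)
    idx <- match(names(labs), dm$ids)
    d <- dm$d[idx, idx, drop = FALSE]
    same <- outer(labs, labs, "==") & upper.tri(d)
    intra <- d[same]
    intra <- intra[!is.na(intra)]
    if (length(intra) == 0) stop("empty intraspecific pool")
    q95 <- unname(quantile(intra, 0.95, type = 7))
    t_opt <- threshold_cumulative_error(dm, labels)$threshold
    t_dens <- threshold_density_minimum(dm)$threshold
    if (is.na(t_dens)) t_dens <- if (is.null(density_fallback)) NA_real_ else density_fallback
    thresholds <- c(q95_intra = q95, bold_1pct = 0.01,
                    cumulative_error = t_opt, density_minimum = t_dens)
    if (anyNA(thresholds)) {
      warning("dropping threshold(s) without a value: ",
              paste(names(thresholds)[is.na(thresholds)], collapse = ", "))
      thresholds <- thresholds[!is.na(thresholds)]
    }
  }
  cells <- list()
  bm <- simulate_identifications(dm, labels, "BM")
  cells[[1]] <- cbind(criterion = "BM", threshold_name = "none",
                      threshold = NA_real_, bm$summary,
                      n_queries = bm$n_queries)
  for (tn in names(thresholds)) {
    for (cr in c("BCM", "BIC")) {
      res <- simulate_identifications(dm, labels, cr, thresholds[[tn]])
      cells[[length(cells) + 1]] <-
        cbind(criterion = cr, threshold_name = tn,
              threshold = thresholds[[tn]], res$summary,
              n_queries = res$n_queries)
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
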