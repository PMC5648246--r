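#' Classify the comparable sites of a sequence pair
#'
#' Pairwise deletion: only positions where both sequences carry an
#' unambiguous A, C, G or T are compared. Gaps and every IUPAC ambiguity
#' code (including partial codes such as R or Y) are excluded outright.
#'
#' @param a,b aligned sequences of equal length, as strings or character
#'   vectors.
#' @return list with `n` (comparable sites), `P` (transition fraction,
#'   A<->G and C<->T) and `Q` (transversion fraction). `P` and `Q` are
#'   `NA` when `n == 0`.
#' @export
pairwise_site_classes <- function(a, b) {
  av <- .base_codes(a)
  bv <- .base_codes(b)
  if (length(av) != length(bv)) stop("sequences are not the same length")
  ok <- !is.na(av) & !is.na(bv)
  n <- sum(ok)
  if (n == 0L) return(list(n = 0L, P = NA_real_, Q = NA_real_))
  da <- av[ok]; db <- bv[ok]
  diff <- da != db
  ts <- sum(diff & ((da == 1L | da == 3L) == (db == 1L | db == 3L)))
  list(n = n, P = ts / n, Q = (sum(diff) - ts) / n)
}

.base_codes <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) x <- strsplit(x, "")[[1]]
  match(toupper(x), c("A", "C", "G", "T"))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, with `P` and `Q` the
#' transition and transversion fractions over the comparable sites.
#' When a logarithm argument is non-positive (saturation) the distance is
#' inestimable and returned as `NA` with a warning; the same happens when
#' no sites are comparable.
#'
#' @inheritParams pairwise_site_classes
#' @return divergence as a fraction (multiply by 100 for percent).
#' @export
k2p_distance <- function(a, b) {
  cl <- pairwise_site_classes(a, b)
  if (cl$n == 0L) {
    warning("no comparable sites; distance inestimable")
    return(NA_real_)
  }
  .k2p(cl$P, cl$Q)
}

.k2p <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated pair: K2P distance inestimable")
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Uncorrected (p) distance between two aligned sequences
#'
#' Proportion of differing comparable sites, `P + Q`.
#'
#' @inheritParams pairwise_site_classes
#' @return divergence fraction in `[0, 1]`; `NA` with a warning when no
#'   sites are comparable.
#' @export
p_distance <- function(a, b) {
  cl <- pairwise_site_classes(a, b)
  if (cl$n == 0L) {
    warning("no comparable sites; distance inestimable")
    return(NA_real_)
  }
  cl$P + cl$Q
}

# integer-coded alignment matrix (rows = sequences, NA = gap/ambiguity)
.code_matrix <- function(ds) {
  ch <- strsplit(ds$sequences, "")
  m <- matrix(match(unlist(ch), c("A", "C", "G", "T")),
              nrow = length(ch), byrow = TRUE,
              dimnames = list(names(ds$sequences), NULL))
  m
}

# Shared pairwise tallies via BLAS: comparable sites, mismatches,
# transitions. Used by the distance matrix and by the mutational-step
# counts of the parsimony clusterer.
.pair_tallies <- function(codes) {
  V <- (!is.na(codes)) * 1
  I <- lapply(1:4, function(b) (!is.na(codes) & codes == b) * 1)
  nn <- V %*% t(V)
  eq <- Reduce(`+`, lapply(I, function(M) M %*% t(M)))
  ag <- I[[1]] %*% t(I[[3]])
  ct <- I[[2]] %*% t(I[[4]])
  ts <- ag + t(ag) + ct + t(ct)
  list(n = nn, mismatch = nn - eq, ts = ts)
}

#' Pairwise distance matrix for a barcode data set
#'
#' Full symmetric matrix of K2P or p distances under pairwise deletion,
#' with the per-pair comparable-site counts kept alongside. Saturated
#' K2P pairs (log argument <= 0) and pairs with no comparable sites are
#' recorded as `NA` with a warning, never silently zero.
#'
#' @param ds a [barcode_dataset()].
#' @param model `"K2P"` (default) or `"p"`.
#' @return an object of class `barcode_dist`: list with `ids`, `d`
#'   (symmetric numeric matrix, fractions), `sites` (comparable-site
#'   counts), `model` and `deletion = "pairwise"`.
#' @export
distance_matrix <- function(ds, model = c("K2P", "p")) {
  model <- match.arg(model)
  if (length(ds$sequences) < 2L) stop("need at least 2 sequences")
  codes <- .code_matrix(ds)
  .dist_from_codes(codes, model)
}

.dist_from_codes <- function(codes, model) {
  tl <- .pair_tallies(codes)
  n <- tl$n
  no_sites <- n == 0
  n_safe <- ifelse(no_sites, 1, n)
  if (model == "p") {
    d <- tl$mismatch / n_safe
    d[no_sites] <- NA_real_
  } else {
    P <- tl$ts / n_safe
    Q <- (tl$mismatch - tl$ts) / n_safe
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    sat <- w1 <= 0 | w2 <= 0
    d <- -0.5 * log(pmax(w1, 1e-300)) - 0.25 * log(pmax(w2, 1e-300))
    d[sat | no_sites] <- NA_real_
  }
  d[!is.na(d) & d == 0] <- 0  # normalise IEEE negative zeros
  diag(d) <- 0
  bad <- sum(is.na(d[upper.tri(d)]))
  if (bad > 0)
    warning(bad, " pair(s) with inestimable distance recorded as NA")
  structure(list(ids = rownames(codes), d = d, sites = tl$n,
                 model = model, deletion = "pairwise"),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  v <- x$d[upper.tri(x$d)]
  cat("barcode_dist:", length(x$ids), "sequences, model", x$model,
      "(pairwise deletion)\n")
  cat(sprintf("  range %.2f%% - %.2f%%, %d inestimable pair(s)\n",
              100 * min(v, na.rm = TRUE), 100 * max(v, na.rm = TRUE),
              sum(is.na(v))))
  invisible(x)
}

#' @export
as.dist.barcode_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Count of differing comparable sites per sequence pair
#'
#' Absolute mutational differences under pairwise deletion, the input to
#' the statistical-parsimony clusterer. Pairs with many ambiguous
#' positions are compared over fewer sites and therefore connect more
#' easily; the comparable-site counts are returned so callers can flag
#' such pairs.
#'
#' @param ds a [barcode_dataset()].
#' @return list with integer matrices `diff` and `sites`.
#' @export
pairwise_diff_counts <- function(ds) {
  tl <- .pair_tallies(.code_matrix(ds))
  dimn <- list(names(ds$sequences), names(ds$sequences))
  dimnames(tl$mismatch) <- dimn
  dimnames(tl$n) <- dimn
  list(diff = tl$mismatch, sites = tl$n)
}

#' Serialise a distance matrix
#'
#' Writes the square form (ids as header row/column) and/or a long form
#' (`id1`, `id2`, `model`, `distance`, `sites`).
#'
#' @param dm a `barcode_dist`.
#' @param square_path,long_path output paths; either may be `NULL`.
#' @export
write_distance_matrix <- function(dm, square_path = NULL, long_path = NULL) {
  d <- dm$d
  dimnames(d) <- list(dm$ids, dm$ids)
  if (!is.null(square_path)) {
    df <- data.frame(id = dm$ids, d, check.names = FALSE)
    write.table(df, square_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(long_path)) {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    long <- data.frame(id1 = dm$ids[ut[, 1]], id2 = dm$ids[ut[, 2]],
                       model = dm$model, distance = d[ut],
                       sites = dm$sites[ut])
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
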