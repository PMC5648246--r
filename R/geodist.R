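#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (the mean Earth
#' radius). Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @param radius_km sphere radius.
#' @return distance in km; zero iff the points coincide.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = radius_km * 1000) / 1000
}

# symmetric km matrix for a set of points
.geo_matrix <- function(lat, lon, ids) {
  n <- length(lat)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  km <- haversine_km(lat[ut[, 1]], lon[ut[, 1]], lat[ut[, 2]], lon[ut[, 2]])
  m[ut] <- km
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles, with significance from
#' simultaneous row/column permutation of one matrix. The observed
#' statistic is included in the reference set (the +1 convention), so the
#' p-value is `(1 + #permuted r >= observed) / (1 + n_perm)` for the
#' default one-sided test of positive association, and can never be 0.
#' Matrices with zero variance in either triangle give an undefined
#' result, flagged rather than silently numeric.
#'
#' @param gen_dm,geo_dm square symmetric matrices over the same ids (in
#'   the same order).
#' @param n_perm number of permutations.
#' @param alternative `"greater"` (positive association, the default) or
#'   `"two.sided"`.
#' @param seed optional RNG seed for reproducible permutations.
#' @return object of class `mantel_result`: `r`, `p`, `n`, `n_perm`,
#'   `alternative`, `defined`.
#' @export
mantel_test <- function(gen_dm, geo_dm, n_perm = 999,
                        alternative = c("greater", "two.sided"),
                        seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gen_dm)
  stopifnot(n == nrow(geo_dm), n >= 3)
  ut <- upper.tri(gen_dm)
  x <- gen_dm[ut]
  y <- geo_dm[ut]
  if (var(x) == 0 || var(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          n_perm = n_perm, alternative = alternative,
                          defined = FALSE),
                     class = "mantel_result"))
  r_obs <- cor(x, y)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    pm <- sample.int(n)
    cor(x, geo_dm[pm, pm][ut])
  }, 0)
  p <- if (alternative == "greater")
    (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  else
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n = n, n_perm = n_perm,
                 alternative = alternative, defined = TRUE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (!x$defined) cat("mantel_result: undefined (zero-variance matrix)\n")
  else cat(sprintf("mantel_result: r = %.3f, p = %.4g (%s, %d permutations, n = %d)\n",
                   x$r, x$p, x$alternative, x$n_perm, x$n))
  invisible(x)
}

#' Isolation-by-distance screen across species
#'
#' Runs a Mantel test for every species with at least `min_n` individuals
#' (with coordinates) sampled from sites at least `min_span_km` apart.
#' Individuals sharing identical coordinates contribute zero geographic
#' distances and are retained; species sampled at a single site fall to
#' the zero-variance guard.
#'
#' @param ds a [barcode_dataset()].
#' @param dm the matching `barcode_dist`.
#' @param min_n minimum individuals per species.
#' @param min_span_km minimum maximum pairwise geographic distance.
#' @param n_perm permutations per test.
#' @param alpha significance level for the summary count.
#' @param seed RNG seed; species are tested in a fixed order from one
#'   stream, so results are reproducible.
#' @return data frame (`species`, `n`, `max_km`, `r`, `p`,
#'   `significant`) with attribute `n_significant` = number of species
#'   with positive correlation and `p` below `alpha`.
#' @export
ibd_screen <- function(ds, dm, min_n = 10, min_span_km = 275,
                       n_perm = 999, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- ds$records
  md <- md[md$species != "" & !is.na(md$latitude) & !is.na(md$longitude), ,
           drop = FALSE]
  rows <- list()
  for (sp in sort(unique(md$species))) {
    sub <- md[md$species == sp, , drop = FALSE]
    if (nrow(sub) < min_n) next
    geo <- .geo_matrix(sub$latitude, sub$longitude, sub$specimen_id)
    max_km <- max(geo)
    if (max_km < min_span_km) next
    idx <- match(sub$specimen_id, dm$ids)
    gen <- dm$d[idx, idx]
    dimnames(gen) <- list(sub$specimen_id, sub$specimen_id)
    mt <- mantel_test(gen, geo, n_perm = n_perm)
    rows[[length(rows) + 1]] <-
      data.frame(species = sp, n = nrow(sub), max_km = max_km,
                 r = mt$r, p = mt$p,
                 significant = isTRUE(mt$defined && mt$r > 0 && mt$p < alpha),
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), n = integer(), max_km = numeric(),
               r = numeric(), p = numeric(), significant = logical())
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}
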