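#' Neighbour-joining gene tree from a distance matrix
#'
#' Standard agglomerative neighbour joining on the full distance matrix.
#' Negative branch-length estimates (a known NJ artefact on non-additive
#' matrices) are clamped to zero with the deficit transferred to the
#' adjacent branch so that tip-to-tip path lengths are preserved; each
#' occurrence is reported via a message. Missing distances are a hard
#' error: saturated pairs must be filtered or imputed before tree
#' building.
#'
#' @param dm a `barcode_dist`.
#' @return an unrooted `phylo` tree whose tips are the matrix ids; on an
#'   additive matrix its path metric reproduces the input exactly.
#' @export
nj_build <- function(dm) {
  if (length(dm$ids) < 3) stop("need at least 3 sequences")
  if (anyNA(dm$d[upper.tri(dm$d)]))
    stop("distance matrix has inestimable pairs; ",
         "exclude those sequences or impute before tree building")
  d <- dm$d
  dimnames(d) <- list(dm$ids, dm$ids)
  phy <- ape::nj(stats::as.dist(d))
  neg <- which(phy$edge.length < 0)
  if (length(neg)) {
    message(length(neg), " negative NJ branch length(s) clamped to zero")
    for (e in neg) {
      deficit <- phy$edge.length[e]
      child <- phy$edge[e, 2]
      phy$edge.length[e] <- 0
      downstream <- which(phy$edge[, 1] == child)
      if (length(downstream))
        phy$edge.length[downstream] <- phy$edge.length[downstream] + deficit
    }
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Nonparametric bootstrap over alignment columns: each pseudoreplicate
#' resamples columns with replacement, rebuilds the distance matrix under
#' the same model and re-estimates the NJ tree; the support of an
#' internal edge is the percentage of replicates containing the same
#' bipartition. Resampling is per column, agnostic to codon position.
#'
#' @param ds a [barcode_dataset()].
#' @param model distance model, `"K2P"` or `"p"`.
#' @param n_reps number of pseudoreplicates (>= 1).
#' @param seed RNG seed; a fixed seed gives identical supports across
#'   runs.
#' @return the reference NJ tree with `node.label` holding support
#'   percentages (the root label is `NA`).
#' @export
bootstrap_support <- function(ds, model = "K2P", n_reps = 1000, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  codes <- .code_matrix(ds)
  build <- function(m) {
    dm <- suppressWarnings(.dist_from_codes(m, model))
    if (anyNA(dm$d)) stop("inestimable distances in bootstrap replicate")
    d <- dm$d
    dimnames(d) <- list(rownames(m), rownames(m))
    ape::nj(stats::as.dist(d))
  }
  ref <- build(codes)
  if (!is.null(seed)) set.seed(seed)
  counts <- ape::boot.phylo(ref, codes, build, B = n_reps, quiet = TRUE)
  support <- 100 * counts / n_reps
  support[1] <- NA  # root bipartition is trivial
  ref$node.label <- support
  ref
}
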