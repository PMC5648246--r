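# labels restricted to ids present in the matrix, named records only
.labeled <- function(dm, labels) {
  labels <- labels[names(labels) %in% dm$ids]
  labels[!is.na(labels) & labels != ""]
}

# intraspecific / congeneric distance pools (upper triangle, NA dropped)
.distance_pools <- function(dm, labels, genus_of_species) {
  labels <- .labeled(dm, labels)
  idx <- match(names(labels), dm$ids)
  d <- dm$d[idx, idx, drop = FALSE]
  same_sp <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same_sp]
  gen <- unname(genus_of_species[labels])
  same_gen <- outer(gen, gen, "==")
  cong <- d[ut & !same_sp & same_gen]
  list(intra = intra[!is.na(intra)], congeneric = cong[!is.na(cong)],
       labels = labels)
}

#' Intraspecific and congeneric divergence summaries
#'
#' The intraspecific pool holds every conspecific pair over species with
#' two or more members; the congeneric pool holds every pair of
#' individuals belonging to different species of the same genus. Means
#' are reported together with the comparison counts so that percentages
#' can be regressed without rounding ambiguity. An empty pool yields a
#' `NULL` summary, never zero.
#'
#' @param dm a `barcode_dist`.
#' @param labels named character vector: specimen id -> species label.
#' @param genus_of_species named character vector: species -> genus (as
#'   from [taxon_maps()]).
#' @return list with `intraspecific` and `congeneric` components, each
#'   `NULL` or a list of `mean`, `min`, `max`, `n_comparisons` plus
#'   taxon counts.
#' @export
divergence_summaries <- function(dm, labels, genus_of_species) {
  pools <- .distance_pools(dm, labels, genus_of_species)
  lab <- pools$labels
  tab <- table(lab)
  smry <- function(x) if (length(x) == 0) NULL else
    list(mean = mean(x), min = min(x), max = max(x),
         n_comparisons = length(x))
  intra <- smry(pools$intra)
  if (!is.null(intra)) {
    intra$n_species <- sum(tab >= 2)
    intra$n_genera <- length(unique(genus_of_species[names(tab)[tab >= 2]]))
  }
  cong <- smry(pools$congeneric)
  if (!is.null(cong)) {
    gen <- genus_of_species[names(tab)]
    multi <- table(gen)
    cong$n_species <- sum(gen %in% names(multi)[multi >= 2])
    cong$n_genera <- sum(multi >= 2)
  }
  list(intraspecific = intra, congeneric = cong,
       n_sequences = length(lab), n_species = length(tab))
}

#' Barcode-gap profile
#'
#' For every labeled sequence, the distance to its furthest conspecific
#' (absent for singletons) and to its nearest non-conspecific (the
#' nearest neighbour), plus a per-species gap verdict: a species with two
#' or more members shows a barcode gap when every member's
#' nearest-neighbour distance strictly exceeds that member's furthest
#' conspecific distance. Barcode sharing with another species shows up as
#' `nn_distance == 0` (identical over all mutually comparable sites).
#'
#' @inheritParams divergence_summaries
#' @return object of class `gap_profile`: list with `per_sequence` and
#'   `per_species` data frames.
#' @export
gap_profile <- function(dm, labels) {
  labels <- .labeled(dm, labels)
  if (length(unique(labels)) < 2) stop("need at least 2 species")
  idx <- match(names(labels), dm$ids)
  d <- dm$d[idx, idx, drop = FALSE]
  n <- length(labels)
  max_con <- nn <- rep(NA_real_, n)
  nn_tax <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    con <- labels == labels[i]
    con[i] <- FALSE
    if (any(con)) max_con[i] <- max(d[i, con], na.rm = TRUE)
    het <- labels != labels[i]
    dh <- d[i, het]
    j <- which.min(dh)
    nn[i] <- dh[j]
    nn_tax[i] <- labels[het][j]
  }
  per_seq <- data.frame(specimen_id = names(labels), species = unname(labels),
                        max_conspecific = max_con, nn_distance = nn,
                        nn_taxon = nn_tax, stringsAsFactors = FALSE)
  sp <- split(seq_len(n), labels)
  per_species <- data.frame(
    species = names(sp),
    n_individuals = lengths(sp),
    gap_present = vapply(sp, function(ix) {
      if (length(ix) < 2) return(NA)
      all(nn[ix] > max_con[ix])
    }, logical(1)),
    stringsAsFactors = FALSE)
  rownames(per_species) <- NULL
  structure(list(per_sequence = per_seq, per_species = per_species),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  ps <- x$per_species
  multi <- !is.na(ps$gap_present)
  cat("gap_profile:", nrow(x$per_sequence), "sequences,",
      nrow(ps), "species (", sum(!multi), "singletons )\n")
  cat("  barcode gap present for", sum(ps$gap_present[multi]), "of",
      sum(multi), "species with >= 2 individuals\n")
  invisible(x)
}

#' Empirical identification thresholds
#'
#' The 95th percentile of the intraspecific distance pool and the 5th
#' percentile of the congeneric pool, the two data-driven thresholds used
#' by the identification panel and the deep-divergence screen.
#' Percentiles use linear interpolation between closest ranks
#' ([stats::quantile()] type 7); the rule is fixed and used everywhere in
#' the package.
#'
#' @inheritParams divergence_summaries
#' @return list with `q95_intra` and `q05_congeneric` (fractions).
#' @export
empirical_thresholds <- function(dm, labels, genus_of_species) {
  pools <- .distance_pools(dm, labels, genus_of_species)
  if (length(pools$intra) == 0) stop("empty intraspecific pool")
  if (length(pools$congeneric) == 0) stop("empty congeneric pool")
  list(q95_intra = unname(quantile(pools$intra, 0.95, type = 7)),
       q05_congeneric = unname(quantile(pools$congeneric, 0.05, type = 7)))
}

#' Tree-based distinctiveness of singleton species
#'
#' A singleton cannot be assessed through intraspecific variation, so it
#' is examined on the gene tree: it is distinguishable when (a) its
#' barcode is not shared with any non-conspecific (no zero distance under
#' pairwise deletion) and (b) its tip is not nested inside the smallest
#' clade containing its nearest non-conspecific species. The tree is
#' midpoint rooted before clade queries.
#'
#' @inheritParams divergence_summaries
#' @param tree a `phylo` tree whose tips are the matrix ids.
#' @return data frame: singleton id, species, nearest non-conspecific
#'   species and distance, `shares_barcode`, `nested`, `distinguishable`.
#' @export
assess_singletons <- function(dm, labels, tree) {
  labels <- .labeled(dm, labels)
  tab <- table(labels)
  singles <- names(labels)[labels %in% names(tab)[tab == 1]]
  if (length(singles) == 0)
    return(data.frame(specimen_id = character(), species = character(),
                      nn_species = character(), nn_distance = numeric(),
                      shares_barcode = logical(), nested = logical(),
                      distinguishable = logical()))
  missing_tips <- setdiff(singles, tree$tip.label)
  if (length(missing_tips))
    stop("singleton id(s) absent from tree: ",
         paste(missing_tips, collapse = ", "))
  rooted <- phangorn::midpoint(tree)
  rows <- lapply(singles, function(id) {
    i <- match(id, dm$ids)
    het <- dm$ids %in% names(labels) & labels[dm$ids] != labels[[id]]
    het[is.na(het)] <- FALSE
    dh <- dm$d[i, het]
    j <- which.min(dh)
    nn_id <- dm$ids[het][j]
    nn_sp <- labels[[nn_id]]
    shares <- any(dh == 0, na.rm = TRUE)
    sp_tips <- names(labels)[labels == nn_sp]
    sp_tips <- intersect(sp_tips, rooted$tip.label)
    nested <- FALSE
    if (length(sp_tips) >= 2) {
      mrca <- ape::getMRCA(rooted, sp_tips)
      clade_tips <- phangorn::Descendants(rooted, mrca, type = "tips")[[1]]
      nested <- match(id, rooted$tip.label) %in% clade_tips
    }
    data.frame(specimen_id = id, species = labels[[id]], nn_species = nn_sp,
               nn_distance = unname(dh[j]), shares_barcode = shares,
               nested = nested, distinguishable = !shares && !nested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a gap profile as TSV tables
#'
#' One row per sequence (the scatter behind max-intraspecific vs
#' nearest-neighbour plots) and one row per species.
#'
#' @param gp a [gap_profile()].
#' @param per_sequence_path,per_species_path output paths.
#' @export
write_gap_profile <- function(gp, per_sequence_path, per_species_path) {
  write.table(gp$per_sequence, per_sequence_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gp$per_species, per_species_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
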