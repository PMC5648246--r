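#' Classify species against a MOTU partition
#'
#' Every labeled species is placed into exactly one of four categories:
#' `MATCH` (all its specimens alone in a single MOTU), `SPLIT` (spread
#' over k >= 2 MOTUs, each containing only that species), `MERGE` (a
#' single MOTU shared with other species) and `MIXTURE` (spread over
#' k >= 2 MOTUs with at least one shared). Singletons are classifiable: a
#' singleton alone in its MOTU is a MATCH, in a shared MOTU a MERGE.
#' Sequences present in the partition without a species label are
#' excluded with a warning.
#'
#' @param partition a `motu_partition` or named integer vector
#'   (specimen id -> MOTU id).
#' @param labels named character vector: specimen id -> species label.
#' @return object of class `concordance_report`: `species_table` (one
#'   row per species: category, k, MOTU ids) and `summary` (per-category
#'   species counts and percentages, always totalling 100%).
#' @export
classify_species <- function(partition, labels) {
  assignment <- if (inherits(partition, "motu_partition"))
    partition$assignment else partition
  labels <- labels[!is.na(labels) & labels != ""]
  labeled_ids <- intersect(names(assignment), names(labels))
  unlabeled <- setdiff(names(assignment), labeled_ids)
  if (length(unlabeled))
    warning(length(unlabeled),
            " sequence(s) without species label excluded from concordance")
  missing <- setdiff(names(labels)[names(labels) %in% labeled_ids == FALSE],
                     character(0))
  lab <- labels[labeled_ids]
  motu <- assignment[labeled_ids]
  sp_of_motu <- tapply(lab, motu, function(x) length(unique(x)))
  rows <- lapply(split(labeled_ids, lab), function(ids) {
    motus <- unique(motu[ids])
    k <- length(motus)
    shared <- any(sp_of_motu[as.character(motus)] > 1)
    category <- if (k == 1 && !shared) "MATCH"
      else if (k >= 2 && !shared) "SPLIT"
      else if (k == 1) "MERGE"
      else "MIXTURE"
    data.frame(species = lab[[ids[1]]], n = length(ids),
               category = category,
               k = if (category %in% c("SPLIT", "MIXTURE")) k else NA_integer_,
               motus = paste(sort(motus), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  lev <- c("MATCH", "SPLIT", "MERGE", "MIXTURE")
  counts <- table(factor(tbl$category, levels = lev))
  structure(list(species_table = tbl,
                 summary = data.frame(category = lev,
                                      n_species = as.integer(counts),
                                      pct = 100 * as.integer(counts) / nrow(tbl)),
                 n_species = nrow(tbl)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:", x$n_species, "species\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %4d (%5.2f%%)\n", s$category[i], s$n_species[i],
                s$pct[i]))
  invisible(x)
}

#' Flag species with deep intraspecific divergence
#'
#' Species whose maximum intraspecific distance reaches the cutoff
#' (conventionally the 95th percentile of all intraspecific distances),
#' the starting point of the geographic-pattern screen.
#'
#' @param dm a `barcode_dist`.
#' @param labels named character vector: specimen id -> species.
#' @param cutoff distance fraction, > 0.
#' @return data frame (`species`, `n`, `max_intraspecific`) sorted by
#'   decreasing divergence; empty when nothing reaches the cutoff.
#' @export
flag_deep_divergence <- function(dm, labels, cutoff) {
  stopifnot(cutoff > 0)
  labels <- .labeled(dm, labels)
  idx <- setNames(match(names(labels), dm$ids), names(labels))
  rows <- lapply(split(names(labels), labels), function(ids) {
    if (length(ids) < 2) return(NULL)
    sub <- dm$d[idx[ids], idx[ids]]
    data.frame(species = labels[[ids[1]]], n = length(ids),
               max_intraspecific = max(sub[upper.tri(sub)], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(species = character(), n = integer(),
                      max_intraspecific = numeric()))
  out <- out[out$max_intraspecific >= cutoff, , drop = FALSE]
  out <- out[order(-out$max_intraspecific), , drop = FALSE]
  rownames(out) <- NULL
  out
}
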