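#' Assemble a barcode data set from sequences and specimen metadata
#'
#' A `barcode_dataset` couples an aligned set of barcode sequences with one
#' metadata row per specimen (taxonomic labels, coordinates, locality).
#' All downstream stages of the package consume this container.
#'
#' @param sequences named character vector of aligned sequences over the
#'   IUPAC alphabet (gap symbol `-` allowed). All sequences must share one
#'   alignment length; names are the specimen ids.
#' @param metadata data frame with columns `specimen_id`, `species`,
#'   `genus`, `family`, `latitude`, `longitude`, `locality`. An empty or
#'   `NA` species label marks an unidentified record; such records are kept
#'   but excluded from species-level statistics.
#' @param provenance free-text description of where the data came from.
#' @return an object of class `barcode_dataset` with elements `records`
#'   (the metadata, ordered as the sequences), `sequences`,
#'   `alignment_length` and `provenance`.
#' @export
barcode_dataset <- function(sequences, metadata, provenance = "") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique specimen ids as names")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  need <- c("specimen_id", "species", "genus", "family",
            "latitude", "longitude", "locality")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$specimen_id))
    stop("duplicated specimen_id in metadata")
  absent <- setdiff(names(sequences), metadata$specimen_id)
  if (length(absent))
    stop("no metadata row for sequence id(s): ", paste(absent, collapse = ", "))
  md <- metadata[match(names(sequences), metadata$specimen_id), need, drop = FALSE]
  rownames(md) <- NULL
  md$species[is.na(md$species)] <- ""
  bad_lat <- !is.na(md$latitude) & (md$latitude < -90 | md$latitude > 90)
  bad_lon <- !is.na(md$longitude) & (md$longitude < -180 | md$longitude > 180)
  if (any(bad_lat) || any(bad_lon))
    stop("coordinates out of range for: ",
         paste(md$specimen_id[bad_lat | bad_lon], collapse = ", "))
  .check_taxonomy(md)
  structure(list(records = md,
                 sequences = toupper(sequences),
                 alignment_length = unname(lens[1]),
                 provenance = provenance),
            class = "barcode_dataset")
}

# one genus per species label, one family per genus
.check_taxonomy <- function(md) {
  lab <- md$species != ""
  if (any(lab)) {
    sp2gen <- tapply(md$genus[lab], md$species[lab],
                     function(x) length(unique(x)))
    if (any(sp2gen > 1))
      stop("species mapped to more than one genus: ",
           paste(names(sp2gen)[sp2gen > 1], collapse = ", "))
  }
  gen2fam <- tapply(md$family, md$genus, function(x) length(unique(x)))
  if (any(gen2fam > 1))
    stop("genus mapped to more than one family: ",
         paste(names(gen2fam)[gen2fam > 1], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.barcode_dataset <- function(x, ...) {
  lab <- x$records$species != ""
  cat("barcode_dataset:", nrow(x$records), "sequences,",
      length(unique(x$records$species[lab])), "named species,",
      "alignment length", x$alignment_length, "\n")
  if (sum(!lab)) cat("  unidentified records:", sum(!lab), "\n")
  invisible(x)
}

#' Read an aligned FASTA file and its specimen metadata table
#'
#' Joins sequences and metadata on specimen id. Every FASTA id must have a
#' metadata row; the join is a hard error otherwise, naming the offending
#' ids. Metadata rows without a sequence are dropped silently (a library
#' table may cover more specimens than were sequenced).
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param metadata_path path to a tab-separated metadata table with a
#'   header row.
#' @param col_map named character vector mapping the required column names
#'   (`specimen_id`, `species`, `genus`, `family`, `latitude`, `longitude`,
#'   `locality`) to the columns actually present in the file, so BOLD-style
#'   exports can be read without editing them.
#' @return a [barcode_dataset()].
#' @export
read_fasta_with_metadata <- function(fasta_path, metadata_path,
                                     col_map = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  names(seqs) <- names(dna)
  md <- read.delim(metadata_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(md)) stop("mapped column not in metadata: ", src)
      names(md)[names(md) == src] <- std
    }
  }
  md$species[is.na(md$species)] <- ""
  md$locality[is.na(md$locality)] <- ""
  barcode_dataset(toupper(seqs), md,
                  provenance = paste0("read from ", fasta_path))
}

#' Write a barcode data set back to FASTA + TSV
#'
#' The exact dialect [read_fasta_with_metadata()] reads, so a write/read
#' round trip reproduces the data set.
#'
#' @param ds a [barcode_dataset()].
#' @param fasta_path,metadata_path output paths.
#' @export
write_dataset <- function(ds, fasta_path, metadata_path) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (id in names(ds$sequences))
    writeLines(c(paste0(">", id), ds$sequences[[id]]), con)
  write.table(ds$records, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Quality-filter a barcode data set
#'
#' Retains sequences with at least `min_length` resolved positions
#' (non-gap, non-N) and an ambiguity fraction below `max_ambiguous_frac`.
#' Ambiguous calls are every non-ACGT, non-gap symbol; leading/trailing
#' gaps (shorter reads inside the alignment) count toward the length
#' shortfall, not toward ambiguity. Whitelisted ids are retained
#' regardless, mirroring curator overrides for unique records.
#'
#' @param ds a [barcode_dataset()].
#' @param min_length minimum resolved length in positions.
#' @param max_ambiguous_frac maximum fraction of ambiguous calls among
#'   non-gap positions (strict `<`).
#' @param whitelist specimen ids exempt from the filter.
#' @return list with the filtered `dataset` and a `rejections` data frame
#'   (specimen_id, reason, detail). Filtering is idempotent.
#' @export
qc_filter <- function(ds, min_length = 500, max_ambiguous_frac = 0.01,
                      whitelist = character()) {
  chars <- strsplit(ds$sequences, "")
  stats <- t(vapply(chars, function(ch) {
    gap <- ch == "-"
    acgt <- ch %in% c("A", "C", "G", "T")
    amb <- !gap & !acgt
    c(len = sum(!gap & ch != "N"),
      nongap = sum(!gap),
      amb = sum(amb))
  }, c(len = 0, nongap = 0, amb = 0)))
  frac <- ifelse(stats[, "nongap"] > 0, stats[, "amb"] / stats[, "nongap"], 1)
  short <- stats[, "len"] < min_length
  dirty <- frac >= max_ambiguous_frac
  keep <- (!short & !dirty) | names(ds$sequences) %in% whitelist
  rej <- data.frame(
    specimen_id = names(ds$sequences)[!keep],
    reason = ifelse(short[!keep], "length", "ambiguity"),
    detail = ifelse(short[!keep],
                    sprintf("%d resolved positions < %d", stats[!keep, "len"], min_length),
                    sprintf("%.2f%% ambiguous calls", 100 * frac[!keep])),
    stringsAsFactors = FALSE)
  rownames(rej) <- NULL
  out <- ds
  out$sequences <- ds$sequences[keep]
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  list(dataset = out, rejections = rej)
}

.stop_codons <- list(
  standard = c("TAA", "TAG", "TGA"),
  invertebrate_mito = c("TAA", "TAG"),
  vertebrate_mito = c("TAA", "TAG", "AGA", "AGG"))

#' Check the reading frame of each sequence
#'
#' Translation sanity check for protein-coding barcodes: reports in-frame
#' stop codons and gap runs whose length is not a multiple of three
#' (frame-shifting indels). A 3-bp deletion is reported but not flagged as
#' frame shifting. Codons containing ambiguity codes are skipped.
#'
#' @param ds a [barcode_dataset()].
#' @param frame_offset 0, 1 or 2: the position within the codon at which
#'   the alignment starts.
#' @param genetic_code one of `"invertebrate_mito"` (the default,
#'   appropriate for insect COI), `"standard"`, `"vertebrate_mito"`.
#' @return data frame with one row per sequence: stop-codon count and
#'   positions, gap-run descriptions, and whether any indel shifts frame.
#' @export
check_reading_frame <- function(ds, frame_offset = 0,
                                genetic_code = "invertebrate_mito") {
  stopifnot(frame_offset %in% 0:2)
  if (!genetic_code %in% names(.stop_codons))
    stop("unknown genetic code id: ", genetic_code)
  stops <- .stop_codons[[genetic_code]]
  res <- lapply(names(ds$sequences), function(id) {
    ch <- strsplit(ds$sequences[[id]], "")[[1]]
    gap <- ch == "-"
    runs <- rle(gap)
    ends <- cumsum(runs$lengths)
    gap_runs <- data.frame(start = ends - runs$lengths + 1,
                           len = runs$lengths)[runs$values, , drop = FALSE]
    # trailing/leading gaps are read-length artefacts, not indels
    internal <- gap_runs[gap_runs$start > 1 &
                         gap_runs$start + gap_runs$len - 1 < length(ch), ,
                         drop = FALSE]
    shifts <- internal$len %% 3 != 0
    deg <- ch[!gap]
    usable <- seq_len(length(deg) - frame_offset)
    deg <- deg[frame_offset + usable]
    n_codon <- length(deg) %/% 3
    codons <- vapply(seq_len(n_codon), function(k)
      paste(deg[(3 * k - 2):(3 * k)], collapse = ""), character(1))
    stop_at <- which(codons %in% stops)
    data.frame(specimen_id = id,
               n_stop_codons = length(stop_at),
               stop_codon_positions = paste(stop_at, collapse = ","),
               n_internal_gap_runs = nrow(internal),
               gap_run_lengths = paste(internal$len, collapse = ","),
               frame_shifting = any(shifts),
               clean = length(stop_at) == 0 && !any(shifts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Species, genus and family lookup maps for a data set
#'
#' @param ds a [barcode_dataset()].
#' @return list with `species` (named by specimen id; `""` for
#'   unidentified records), `genus_of_species` (named by species label)
#'   and `family_of_genus` (named by genus).
#' @export
taxon_maps <- function(ds) {
  md <- ds$records
  lab <- md$species != ""
  list(species = setNames(md$species, md$specimen_id),
       genus_of_species = setNames(md$genus[lab], md$species[lab])[
         !duplicated(md$species[lab])],
       family_of_genus = setNames(md$family, md$genus)[!duplicated(md$genus)])
}
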