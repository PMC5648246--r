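# deterministic per-stage seed fan-out: enabling or disabling one stage
# must not shift another stage's random stream
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.default_config <- function() {
  list(fasta = NULL, metadata = NULL, col_map = NULL,
       out_dir = "barcodegap_run", seed = 1,
       model = "K2P",
       stages = c("qc", "distances", "gap", "identification", "motu",
                  "concordance", "ibd", "tree"),
       qc = list(min_length = 500, max_ambiguous_frac = 0.01,
                 whitelist = character()),
       identification = list(density_fallback = NULL),
       motu = list(abgd_P = 0.01, abgd_X = 1.5, tcs_limit = 0.95,
                   resl_seed_threshold = 0.022,
                   resl_refine_range = c(0.007, 0.022)),
       ibd = list(min_n = 10, min_span_km = 275, n_perm = 999,
                  alpha = 0.05),
       tree = list(bootstrap_reps = 0))
}

#' Run the full barcode analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order (QC, distances,
#' barcode gap, identification panel, MOTU delimitation, concordance,
#' isolation-by-distance screen, NJ tree), writing every report table, a
#' machine-readable manifest of all parameters actually used, a summary
#' of the headline numbers and a log into the run directory. `qc` and
#' `distances` are required stages and abort the run on failure; the
#' remaining stages are optional and are logged and skipped on failure.
#' One global seed fans out deterministically to per-stage seeds, so the
#' same configuration and seed give byte-identical outputs.
#'
#' @param config a named list or path to a YAML file. Unknown keys are
#'   rejected. Required: `fasta` and `metadata` input paths. See the
#'   package vignette for the full key set and defaults.
#' @return (invisibly) the run directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$fasta) || is.null(cfg$metadata))
    stop("config must provide 'fasta' and 'metadata' paths")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  cat("", file = log_path)
  summary_out <- list()
  outp <- function(f) file.path(cfg$out_dir, f)
  optional <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logf("SKIPPED optional stage ", stage, ": ", conditionMessage(e))
      warning("stage '", stage, "' skipped: ", conditionMessage(e))
      NULL
    })
  }

  logf("reading ", cfg$fasta)
  ds <- read_fasta_with_metadata(cfg$fasta, cfg$metadata, cfg$col_map)

  if ("qc" %in% cfg$stages) {
    qc <- qc_filter(ds, cfg$qc$min_length, cfg$qc$max_ambiguous_frac,
                    cfg$qc$whitelist)
    ds <- qc$dataset
    write.table(qc$rejections, outp("qc_rejections.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logf("qc: kept ", nrow(ds$records), ", rejected ", nrow(qc$rejections))
    summary_out$n_sequences <- nrow(ds$records)
  }
  maps <- taxon_maps(ds)
  labels <- maps$species

  if (!"distances" %in% cfg$stages)
    stop("the 'distances' stage is required by all downstream stages")
  dm <- distance_matrix(ds, cfg$model)
  write_distance_matrix(dm, outp("distance_matrix.tsv"),
                        outp("distances_long.tsv"))
  logf("distances: ", cfg$model, " matrix for ", length(dm$ids),
       " sequences")

  if ("gap" %in% cfg$stages) optional("gap", {
    sm <- divergence_summaries(dm, labels, maps$genus_of_species)
    gp <- gap_profile(dm, labels)
    th <- empirical_thresholds(dm, labels, maps$genus_of_species)
    write_gap_profile(gp, outp("gap_per_sequence.tsv"),
                      outp("gap_per_species.tsv"))
    summary_out$mean_intraspecific_pct <- 100 * sm$intraspecific$mean
    summary_out$mean_congeneric_pct <-
      if (is.null(sm$congeneric)) NA else 100 * sm$congeneric$mean
    summary_out$q95_intra_pct <- 100 * th$q95_intra
    summary_out$q05_congeneric_pct <- 100 * th$q05_congeneric
    ps <- gp$per_species
    multi <- !is.na(ps$gap_present)
    summary_out$gap_present_species <- sum(ps$gap_present[multi])
    summary_out$gap_assessed_species <- sum(multi)
  })

  if ("identification" %in% cfg$stages) optional("identification", {
    panel <- run_identification_panel(
      dm, labels, density_fallback = cfg$identification$density_fallback)
    write.table(panel, outp("identification_panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bm <- panel[panel$criterion == "BM" & panel$outcome == "correct", ]
    summary_out$bm_correct_pct <- bm$pct[1]
    summary_out$n_queries <- bm$n_queries[1]
  })

  partitions <- list()
  if ("motu" %in% cfg$stages) optional("motu", {
    m <- cfg$motu
    partitions <- list(
      ABGD_initial = abgd_partition(dm, m$abgd_P, m$abgd_X),
      ABGD_recursive = abgd_recursive(dm, m$abgd_P, m$abgd_X),
      TCS = tcs_cluster(ds, m$tcs_limit),
      RESL = resl_cluster(dm, m$resl_seed_threshold, m$resl_refine_range))
    for (nm in names(partitions))
      write_partition(partitions[[nm]],
                      outp(sprintf("partition_%s.tsv", nm)))
    summary_out$motu_counts <- lapply(partitions, function(p) p$n_motus)
  })

  if ("concordance" %in% cfg$stages && length(partitions))
    optional("concordance", {
      conc <- lapply(partitions, classify_species, labels = labels)
      tabs <- do.call(rbind, lapply(names(conc), function(nm)
        cbind(method = nm, conc[[nm]]$summary)))
      write.table(tabs, outp("concordance_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary_out$match_pct <- lapply(conc, function(cr)
        cr$summary$pct[cr$summary$category == "MATCH"])
    })

  if ("ibd" %in% cfg$stages) optional("ibd", {
    g <- cfg$ibd
    scr <- ibd_screen(ds, dm, g$min_n, g$min_span_km, g$n_perm, g$alpha,
                      seed = .stage_seed(cfg$seed, "ibd"))
    write.table(scr, outp("ibd_screen.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary_out$ibd_species_tested <- nrow(scr)
    summary_out$ibd_significant <- attr(scr, "n_significant")
  })

  if ("tree" %in% cfg$stages) optional("tree", {
    phy <- if (cfg$tree$bootstrap_reps > 0)
      bootstrap_support(ds, cfg$model, cfg$tree$bootstrap_reps,
                        seed = .stage_seed(cfg$seed, "tree"))
    else nj_build(dm)
    ape::write.tree(phy, outp("nj_tree.nwk"))
  })

  manifest <- cfg
  manifest$package_version <- as.character(utils::packageVersion("barcodegap"))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  jsonlite::write_json(summary_out, outp("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  logf("done")
  invisible(cfg$out_dir)
}

#' Compare a completed run against stated expectations
#'
#' Reads the run's `summary.json` and an expectations table (TSV with
#' columns `key`, `expected`, `tolerance`, or a JSON list of such
#' records) and reports observed vs expected per key. Expectation keys
#' address the summary with `$` as the nesting separator (e.g.
#' `motu_counts$TCS`). Missing keys are a hard error.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @param expectations_file path to the expectations table.
#' @return data frame: `key`, `observed`, `expected`, `tolerance`,
#'   `pass`.
#' @export
regression_report <- function(run_dir, expectations_file) {
  smry <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                              simplifyVector = TRUE)
  exp <- if (grepl("\\.json$", expectations_file))
    jsonlite::read_json(expectations_file, simplifyVector = TRUE)
  else read.delim(expectations_file, sep = "\t", stringsAsFactors = FALSE)
  if (NROW(exp) == 0)
    return(data.frame(key = character(), observed = numeric(),
                      expected = numeric(), tolerance = numeric(),
                      pass = logical()))
  lookup <- function(key) {
    node <- smry
    for (part in strsplit(key, "$", fixed = TRUE)[[1]]) {
      if (is.null(node[[part]])) return(NULL)
      node <- node[[part]]
    }
    node
  }
  obs <- lapply(exp$key, lookup)
  missing <- vapply(obs, is.null, TRUE)
  if (any(missing))
    stop("expectation key(s) absent from run summary: ",
         paste(exp$key[missing], collapse = ", "))
  obs <- vapply(obs, as.numeric, 0)
  data.frame(key = exp$key, observed = obs, expected = exp$expected,
             tolerance = exp$tolerance,
             pass = abs(obs - exp$expected) <= exp$tolerance)
}
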