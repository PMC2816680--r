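#' Full run configuration
#'
#' Bundles every knob of an end-to-end run so that a saved configuration
#' (it serializes cleanly to JSON in the run manifest) reproduces the run
#' exactly given the same inputs.
#'
#' @param spec a [window_spec()].
#' @param shuffle a [shuffle_config()]; its seed is the run's master seed.
#' @param backend a [fold_backend()].
#' @param min_codons CDS length filter threshold (default 50; genes must be
#'   strictly longer).
#' @param fraction tail fraction for [stratify()] (default 0.05).
#' @param exclude_taxa taxon groups excluded from genome-level GC
#'   correlations.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(spec = window_spec(), shuffle = shuffle_config(),
                       backend = fold_backend(), min_codons = 50L,
                       fraction = 0.05,
                       exclude_taxa = c("plants", "birds", "mammals")) {
  structure(
    list(spec = spec, shuffle = shuffle, backend = backend,
         min_codons = as.integer(min_codons), fraction = fraction,
         exclude_taxa = exclude_taxa),
    class = "run_config"
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of an object via its serialized JSON representation
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
             f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates, per species: CDS validation and filtering, the
#' sliding-window permutation scan, and the genome summary; then, across
#' species, the comparative statistics. All stages write versioned TSV
#' tables into \code{outdir} together with a JSON manifest recording the
#' configuration hash, input hashes and failures. A rerun with unchanged
#' inputs and configuration skips species whose per-species scan output
#' already exists under matching hashes, and a failure in one species does
#' not abort the others.
#'
#' Outputs: \code{gene_windows_<species>.tsv}, \code{genome_summary.tsv},
#' \code{rejections.tsv}, \code{correlations.tsv}, \code{stratified.tsv},
#' \code{pcr_<species>.tsv} (when expression data are supplied) and
#' \code{manifest.json}.
#'
#' @param genes gene table with \code{gene_id}, \code{species_id},
#'   \code{seq} (unvalidated is fine: the length/alphabet filter runs first).
#' @param outdir output directory (created if needed).
#' @param config a [run_config()].
#' @param metadata optional species metadata ([read_metadata()] columns;
#'   \code{genomic_gc} is computed here from the accepted genes).
#' @param expression optional expression table ([read_expression()]).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(genes, outdir, config = run_config(),
                         metadata = NULL, expression = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- object_hash(config[setdiff(names(config), "backend")])
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL

  filtered <- filter_cds(genes, min_codons = config$min_codons)
  write_tsv(filtered$report, file.path(outdir, "rejections.tsv"))
  accepted <- filtered$genes
  species <- unique(accepted$species_id)

  failures <- list()
  profiles <- list()
  species_hashes <- list()
  for (sp in species) {
    sub <- accepted[accepted$species_id == sp, ]
    sp_hash <- object_hash(list(genes = sub[, c("gene_id", "seq")],
                                config = cfg_hash))
    species_hashes[[sp]] <- sp_hash
    sp_file <- file.path(outdir, paste0("gene_windows_", sp, ".tsv"))
    cached <- !is.null(old_manifest) &&
      identical(old_manifest$species_hashes[[sp]], unname(sp_hash)) &&
      file.exists(sp_file)
    if (cached) {
      profiles[[sp]] <- utils::read.delim(sp_file, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(
      zscan(sub, spec = config$spec, shuffle = config$shuffle,
            backend = config$backend),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[sp]] <- conditionMessage(res)
      next
    }
    if (is.null(res$profiles) || nrow(res$profiles) == 0L) {
      failures[[sp]] <- paste("no gene scanned:",
                              res$skipped$reason[1] %||% "unknown")
      next
    }
    write_tsv(res$profiles, sp_file)
    # read the persisted table back so summaries are identical whether a
    # later run recomputes or reuses the cache (TSV precision round trip)
    profiles[[sp]] <- utils::read.delim(sp_file, stringsAsFactors = FALSE)
  }

  all_profiles <- do.call(rbind, unname(profiles))
  summary_tab <- summarize_genome(all_profiles)
  write_tsv(summary_tab, file.path(outdir, "genome_summary.tsv"))

  if (!is.null(metadata) && nrow(summary_tab)) {
    md <- metadata
    md$genomic_gc <- vapply(md$species_id, function(sp) {
      sub <- accepted[accepted$species_id == sp, ]
      if (nrow(sub)) compute_genomic_gc(sub) else NA_real_
    }, numeric(1))
    corr <- cross_species_analysis(summary_tab, md,
                                   exclude_taxa = config$exclude_taxa)
    write_tsv(corr, file.path(outdir, "correlations.tsv"))
  }

  strat <- list()
  for (sp in names(profiles)) {
    sub <- accepted[accepted$species_id == sp, ]
    ann <- gene_annotations(sub, profiles[[sp]], expression = expression)
    for (crit in c("gc", "enc", "expression")) {
      row <- tryCatch(
        cbind(species_id = sp,
              stratify(ann, crit, fraction = config$fraction)),
        error = function(e) NULL
      )
      if (!is.null(row)) strat[[length(strat) + 1L]] <- row
    }
    if (!is.null(expression)) {
      pcr <- tryCatch(pc_regression(ann), error = function(e) NULL)
      if (!is.null(pcr)) {
        write_tsv(
          data.frame(species_id = sp,
                     predictor = names(pcr$contributions),
                     contribution = unname(pcr$contributions),
                     r_squared = pcr$r_squared, n = pcr$n),
          file.path(outdir, paste0("pcr_", sp, ".tsv"))
        )
      }
    }
  }
  if (length(strat)) {
    write_tsv(do.call(rbind, strat), file.path(outdir, "stratified.tsv"))
  }

  manifest <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("fiveprime")),
    config = config[setdiff(names(config), "backend")],
    backend = unclass(config$backend),
    config_hash = unname(cfg_hash),
    species_hashes = lapply(species_hashes, unname),
    n_genes_accepted = nrow(accepted),
    n_rejected = sum(filtered$report$action == "rejected"),
    failures = failures
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE),
             manifest_path)
  invisible(manifest)
}
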