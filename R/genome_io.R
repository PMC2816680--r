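#' Read and filter coding sequences from a FASTA file
#'
#' Reads a CDS FASTA, normalizes sequences (uppercase, U mapped to T) and
#' applies the validation rules used for all downstream analyses: the length
#' must be a positive multiple of 3 ("frame"), the sequence must contain only
#' A/C/G/T ("ambiguous"), and the gene must be strictly longer than
#' \code{min_codons} codons ("too_short"; the default keeps genes of 51+
#' codons, which guarantees full coverage of the default 13-window scan).
#' Malformed records are rejected, never fatal; genes with internal stop
#' codons or a non-ATG start are kept but flagged with a warning row in the
#' report.
#'
#' @param path path to a FASTA file of coding sequences, one record per gene.
#' @param min_codons genes must be strictly longer than this many codons
#'   (default 50).
#' @param species_id species label attached to every accepted gene; defaults
#'   to the file name without extension.
#' @param code a [genetic_code()] object used to locate stop codons.
#' @return A list with components \code{genes} (data frame with columns
#'   \code{gene_id}, \code{species_id}, \code{seq}, \code{n_codons}) and
#'   \code{report} (data frame with columns \code{gene_id}, \code{reason},
#'   \code{action} -- "rejected" or "warning").
#' @seealso [filter_cds()] for applying the same rules to an in-memory table,
#'   [write_cds_fasta()] for the round trip.
#' @export
read_cds_fasta <- function(path, min_codons = 50, species_id = NULL,
                           code = genetic_code()) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_nt(as.character(set))
  genes <- data.frame(gene_id = ids,
                      species_id = rep_len(species_id, length(ids)),
                      seq = seqs, stringsAsFactors = FALSE)
  filter_cds(genes, min_codons = min_codons, code = code)
}

#' Validate and filter an in-memory table of coding sequences
#'
#' @param genes data frame with columns \code{gene_id}, \code{species_id},
#'   \code{seq}.
#' @inheritParams read_cds_fasta
#' @return Same structure as [read_cds_fasta()].
#' @export
filter_cds <- function(genes, min_codons = 50, code = genetic_code()) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "seq") %in% names(genes)))
  if (is.null(genes$species_id)) genes$species_id <- NA_character_
  seqs <- normalize_nt(genes$seq)
  n <- nchar(seqs)

  rej_reason <- character(nrow(genes))
  bad_alpha <- grepl("[^ACGT]", seqs)
  bad_frame <- !bad_alpha & (n == 0L | n %% 3L != 0L)
  ncod <- ifelse(n %% 3L == 0L, n %/% 3L, NA_integer_)
  too_short <- !bad_alpha & !bad_frame & ncod <= min_codons
  rej_reason[too_short] <- "too_short"
  rej_reason[bad_frame] <- "frame"
  rej_reason[bad_alpha] <- "ambiguous"
  keep <- rej_reason == ""

  report <- data.frame(
    gene_id = genes$gene_id[!keep],
    reason = rej_reason[!keep],
    action = rep("rejected", sum(!keep)),
    stringsAsFactors = FALSE
  )

  out <- data.frame(
    gene_id = genes$gene_id[keep],
    species_id = genes$species_id[keep],
    seq = seqs[keep],
    n_codons = ncod[keep],
    stringsAsFactors = FALSE
  )

  # warnings, not rejections: paper-silent cases are kept but flagged
  if (nrow(out)) {
    stop_re <- paste0("^(", paste(code$stop_codons, collapse = "|"), ")$")
    warn <- lapply(seq_len(nrow(out)), function(i) {
      cods <- split_codons(out$seq[i])
      w <- character(0)
      if (any(grepl(stop_re, cods[-length(cods)]))) w <- c(w, "internal_stop")
      if (cods[1] != "ATG") w <- c(w, "non_atg_start")
      w
    })
    nw <- lengths(warn)
    if (any(nw > 0)) {
      report <- rbind(report, data.frame(
        gene_id = rep(out$gene_id, nw),
        reason = unlist(warn),
        action = "warning",
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  rownames(report) <- NULL
  list(genes = out, report = report)
}

#' Write coding sequences to FASTA
#'
#' @param genes gene table as returned by [read_cds_fasta()]\code{$genes}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  set <- Biostrings::DNAStringSet(genes$seq)
  names(set) <- genes$gene_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Pooled genomic GC content of a set of coding sequences
#'
#' Total G+C over total length, pooled across genes (not the mean of per-gene
#' fractions), matching the use of "GC content in coding sequences" as a
#' genome-level covariate.
#'
#' @param genes gene table (data frame with \code{seq}) or character vector of
#'   sequences.
#' @return GC fraction in \[0, 1\].
#' @export
compute_genomic_gc <- function(genes) {
  seqs <- if (is.data.frame(genes)) genes$seq else as.character(genes)
  if (length(seqs) == 0L) stop("no genes")
  sum(gc_count(seqs)) / sum(nchar(seqs))
}

#' Read a species metadata table
#'
#' Tab-separated with header; columns \code{species_id}, \code{taxon_group}
#' (one of bacteria, archaea, fungi, plants, insects, fishes, birds, mammals,
#' other) and optional \code{optimal_growth_temperature} in degrees Celsius.
#' Missing temperatures stay \code{NA}.
#'
#' @param path path to the TSV file.
#' @return Data frame, one row per species.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "taxon_group") %in% names(md))) {
    stop("metadata must have columns species_id and taxon_group")
  }
  dup <- md$species_id[duplicated(md$species_id)]
  if (length(dup)) stop("duplicate species_id in metadata: ",
                        paste(unique(dup), collapse = ", "))
  groups <- c("bacteria", "archaea", "fungi", "plants", "insects",
              "fishes", "birds", "mammals", "other")
  bad <- setdiff(unique(md$taxon_group), groups)
  if (length(bad)) stop("unknown taxon_group: ", paste(bad, collapse = ", "))
  if (is.null(md$optimal_growth_temperature)) {
    md$optimal_growth_temperature <- NA_real_
  }
  md$optimal_growth_temperature <- as.numeric(md$optimal_growth_temperature)
  if (any(is.infinite(md$optimal_growth_temperature), na.rm = TRUE)) {
    stop("optimal_growth_temperature must be finite where present")
  }
  md
}

#' Read a gene expression table
#'
#' Tab-separated with header; columns \code{gene_id} and \code{expression}
#' (non-negative; zero is a valid level). For multi-tissue data the stored
#' value is expected to already be the geometric mean across tissues.
#'
#' @param path path to the TSV file.
#' @return Data frame with columns \code{gene_id}, \code{expression}.
#' @export
read_expression <- function(path) {
  ex <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(ex))) {
    stop("expression table must have columns gene_id and expression")
  }
  dup <- ex$gene_id[duplicated(ex$gene_id)]
  if (length(dup)) stop("duplicate gene_id in expression table: ",
                        paste(unique(dup), collapse = ", "))
  ex$expression <- as.numeric(ex$expression)
  if (any(!is.na(ex$expression) & ex$expression < 0)) {
    stop("expression levels must be non-negative")
  }
  ex[, c("gene_id", "expression")]
}
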