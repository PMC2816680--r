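#' Configure an RNA folding backend
#'
#' Two backends compute the minimum-free-energy (MFE, kcal/mol) of a
#' nucleotide window:
#' \describe{
#'   \item{\code{"rnafold"}}{adapter to ViennaRNA's \code{RNAfold} executable,
#'     run in batch over stdin. The configuration mirrors the analysis rules:
#'     folding at 37 degrees C, GU pairs allowed, dangling-end mode 1 (each
#'     unpaired base joins at most one dangling end). Requires \code{RNAfold}
#'     on the \code{PATH}.}
#'   \item{\code{"nnfold"}}{the package's built-in simplified nearest-neighbor
#'     folder (compiled): Turner-style stacking energies, hairpin/bulge/
#'     internal-loop initiation penalties, linear multiloop cost, no dangling
#'     ends. Parameterized at 37 degrees C only. Fast and dependency-free; used
#'     for the large permutation suites.}
#' }
#' Both are deterministic and report energies to 0.01 kcal/mol; the MFE is
#' never positive because the open chain (energy 0) is always attainable.
#' Energies are backend-specific: never compare values across backends.
#'
#' @param name \code{"nnfold"} (default) or \code{"rnafold"}.
#' @param temperature folding temperature, degrees Celsius (default 37; the
#'   built-in folder supports only 37).
#' @param allow_GU allow GU wobble pairs (default TRUE).
#' @param dangles dangling-end mode for \code{rnafold} (0, 1 or 2; default 1).
#' @return An object of class \code{"fold_backend"}.
#' @export
fold_backend <- function(name = c("nnfold", "rnafold"), temperature = 37,
                         allow_GU = TRUE, dangles = 1L) {
  name <- match.arg(name)
  if (name == "nnfold" && temperature != 37) {
    stop("the built-in nnfold backend is parameterized at 37 C only; ",
         "use fold_backend(\"rnafold\", temperature = ...) instead")
  }
  stopifnot(dangles %in% 0:2)
  structure(
    list(name = name, temperature = temperature, allow_GU = isTRUE(allow_GU),
         dangles = as.integer(dangles)),
    class = "fold_backend"
  )
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("<fold_backend: %s, %g C, GU %s, dangles %d>\n",
              x$name, x$temperature, if (x$allow_GU) "on" else "off",
              x$dangles))
  invisible(x)
}

check_rna <- function(seqs) {
  seqs <- chartr("Tt", "Uu", toupper(seqs))
  bad <- grepl("[^ACGU]", seqs) | nchar(seqs) == 0L
  if (any(bad)) {
    stop("sequence must be non-empty and contain only A/C/G/U (or T): ",
         seqs[which(bad)[1]])
  }
  seqs
}

#' Minimum free energy of one window
#'
#' @param seq nucleotide string (DNA or RNA alphabet; T is transcribed to U at
#'   this boundary).
#' @param backend a [fold_backend()].
#' @return List with \code{delta_g} (kcal/mol, <= 0) and \code{structure}
#'   (dot-bracket string from the \code{rnafold} backend, otherwise \code{NA}).
#' @examples
#' fold_mfe("GGGGGGAAAAACCCCCC", fold_backend("nnfold"))
#' @export
fold_mfe <- function(seq, backend = fold_backend()) {
  stopifnot(length(seq) == 1L)
  seq <- check_rna(seq)
  if (backend$name == "nnfold") {
    list(delta_g = nnfold_mfe(seq, backend$allow_GU), structure = NA_character_)
  } else {
    res <- rnafold_run(seq, backend)
    list(delta_g = res$energy, structure = res$structure)
  }
}

#' Fold a batch of windows
#'
#' Order-preserving, memoized: each distinct window string is folded once.
#'
#' @param seqs character vector of window sequences.
#' @param backend a [fold_backend()].
#' @param memoize fold each distinct string once (default TRUE).
#' @return Numeric vector of MFE values (kcal/mol), one per input window.
#' @export
fold_batch <- function(seqs, backend = fold_backend(), memoize = TRUE) {
  if (length(seqs) == 0L) return(numeric(0))
  seqs <- check_rna(seqs)
  targets <- if (memoize) unique(seqs) else seqs
  dg <- if (backend$name == "nnfold") {
    nnfold_mfe(targets, backend$allow_GU)
  } else {
    rnafold_run(targets, backend)$energy
  }
  if (memoize) dg <- dg[match(seqs, targets)]
  unname(dg)
}

# Run RNAfold over a set of sequences in one process; returns energies and
# dot-bracket structures.
rnafold_run <- function(seqs, backend) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold executable not found on PATH; select the built-in backend ",
         "with fold_backend(\"nnfold\")")
  }
  args <- c("--noPS", paste0("-T", backend$temperature),
            paste0("-d", backend$dangles))
  if (!backend$allow_GU) args <- c(args, "--noGU")
  out <- suppressWarnings(
    system2("RNAfold", args = args, input = seqs, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("RNAfold failed (status ", status, ")")
  out <- out[nzchar(out)]
  if (length(out) != 2L * length(seqs)) {
    stop("unexpected RNAfold output (", length(out), " lines for ",
         length(seqs), " sequences)")
  }
  slines <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(slines, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", slines))
  energy <- as.numeric(gsub("[() ]", "", m))
  structure_ <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)$", "", slines)
  if (anyNA(energy)) stop("could not parse RNAfold energies")
  list(energy = energy, structure = structure_)
}
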