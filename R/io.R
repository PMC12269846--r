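# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA proteomes, glycosite observation tables, ortholog-pair tables, TMT
# plex matrices with channel metadata, and the biophysics CSVs.

.GLYCOSITE_COLS <- c("accession", "taxid", "position", "residue",
                     "glycoform", "biosource", "psm_count")

.firstToken <- function(headers) {
  tok <- sub("\\s.*$", "", headers)
  # UniProt-style db|ACCESSION|ENTRY headers: keep the accession field
  upt <- grepl("^[a-z]{2}\\|[^|]+\\|", tok)
  tok[upt] <- vapply(strsplit(tok[upt], "|", fixed = TRUE), `[`, "", 2)
  tok
}

#' Read a protein FASTA file
#'
#' Wraps \code{Biostrings::readAAStringSet}: sequences are upper-cased,
#' records are named by the first header token (the accession field for
#' UniProt-style \code{db|ACC|ENTRY} headers), and zero-length records are
#' dropped with a warning. Header lines lacking an accession token raise a
#' parse error naming the offending line.
#'
#' @param path FASTA file, wrapped or unwrapped.
#' @param species optional NCBI taxid stored as \code{mcols(x)$species}.
#' @return An \code{AAStringSet} named by accession.
#' @export
readProteome <- function(path, species = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("not FASTA: no '>' header found in ", path)
  bad <- hdr[!grepl("^>\\s*\\S", lines[hdr])]
  if (length(bad))
    stop("malformed FASTA header (no accession token) at line ", bad[1],
         " of ", path)
  x <- readAAStringSet(path)
  names(x) <- .firstToken(names(x))
  if (anyDuplicated(names(x)))
    stop("duplicated accession(s) in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  empty <- width(x) == 0
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty sequence dropped: ",
            paste(names(x)[empty], collapse = ", "))
    x <- x[!empty]
  }
  x <- AAStringSet(toupper(as.character(x)))
  S4Vectors::mcols(x)$species <- rep(as.integer(species), length(x))
  message("read ", length(x), " protein record(s) from ", path)
  x
}

#' Write a protein FASTA file
#'
#' @param x an \code{AAStringSet} (or named character vector) of protein
#'   sequences, named by accession.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(x, path) {
  if (is.character(x)) x <- AAStringSet(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all records must be named by accession")
  writeXStringSet(x, path)
  invisible(path)
}

#' Read a glycosite observation table
#'
#' Tab-separated with header columns \code{accession, taxid, position,
#' residue, glycoform, biosource, psm_count}; positions are 1-based on the
#' canonical sequence.
#'
#' @param path TSV file path.
#' @param proteome optional \code{AAStringSet}; when supplied, each
#'   observation's stated residue is checked against the sequence and
#'   mismatching rows raise an error.
#' @return A data.frame of observations.
#' @export
readGlycositeTable <- function(path, proteome = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  out <- validateGlycositeTable(x, proteome = proteome)
  message("read ", nrow(out), " glycosite observation(s) from ", path)
  out
}

#' Validate a glycosite observation table
#'
#' @param x data.frame with the glycosite table columns.
#' @param proteome optional \code{AAStringSet} for residue cross-checks.
#' @return The validated data.frame (types coerced).
#' @export
validateGlycositeTable <- function(x, proteome = NULL) {
  miss <- setdiff(.GLYCOSITE_COLS, names(x))
  if (length(miss))
    stop("glycosite table lacks column(s): ", paste(miss, collapse = ", "))
  x$position <- as.integer(x$position)
  x$taxid <- as.integer(x$taxid)
  x$psm_count <- as.integer(x$psm_count)
  x$residue <- toupper(x$residue)
  if (any(is.na(x$position)) || any(x$position < 1))
    stop("positions must be 1-based positive integers")
  if (any(!x$residue %in% .STY))
    stop("residues must be one of S/T/Y; offending row(s): ",
         paste(head(which(!x$residue %in% .STY)), collapse = ", "))
  if (any(is.na(x$psm_count)) || any(x$psm_count < 1))
    stop("psm_count must be >= 1")
  if (!is.null(proteome)) {
    # strip isoform suffixes: only canonical sequences are aligned
    iso <- grepl("-\\d+$", x$accession)
    if (any(iso)) {
      warning(sum(iso), " isoform accession(s) stripped to canonical form")
      x$accession[iso] <- sub("-\\d+$", "", x$accession[iso])
    }
    unknown <- setdiff(unique(x$accession), names(proteome))
    if (length(unknown))
      stop("accession(s) missing from proteome: ",
           paste(unknown, collapse = ", "))
    seqs <- as.character(proteome)[x$accession]
    if (any(x$position > nchar(seqs)))
      stop("position beyond sequence length; offending row(s): ",
           paste(head(which(x$position > nchar(seqs))), collapse = ", "))
    actual <- substr(seqs, x$position, x$position)
    bad <- actual != x$residue
    if (any(bad))
      stop("stated residue does not match sequence; offending row(s): ",
           paste(head(which(bad)), collapse = ", "))
  }
  x
}

#' Write a glycosite observation table
#'
#' @param x glycosite data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGlycositeTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog-pair table
#'
#' Tab-separated with columns \code{animal_accession, human_accession} and
#' optionally \code{method} (curated / gene-name / sequence-search).
#'
#' @param path TSV file path.
#' @return A data.frame of pairs.
#' @export
readOrthologPairs <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("animal_accession", "human_accession"), names(x))
  if (length(miss))
    stop("pair table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$method)) x$method <- "curated"
  message("read ", nrow(x), " ortholog pair(s) from ", path)
  x
}

#' Read TMT plex matrices and channel metadata into a TmtExperiment
#'
#' Each plex file is a TSV whose first column holds protein accessions,
#' whose remaining columns are reporter channels, and which may carry a
#' \code{psm_count} column. The metadata TSV has columns \code{plex,
#' channel, is_reference} plus any design columns (genotype, condition,
#' clone).
#'
#' @param plex_paths named character vector of plex TSV paths; names are
#'   plex ids (basenames used when unnamed).
#' @param meta_path channel-metadata TSV path.
#' @return A \code{\link{TmtExperiment}}.
#' @export
readTmtPlexes <- function(plex_paths, meta_path) {
  if (is.null(names(plex_paths)))
    names(plex_paths) <- sub("\\.[^.]*$", "", basename(plex_paths))
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("plex", "channel", "is_reference"), names(meta))
  if (length(miss))
    stop("channel metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta$is_reference <- as.logical(meta$is_reference) |
    meta$is_reference %in% c(1, "1", "TRUE", "true", "yes")
  mats <- list(); psms <- list()
  for (p in names(plex_paths)) {
    tab <- read.delim(plex_paths[[p]], stringsAsFactors = FALSE)
    acc <- tab[[1]]
    psm <- if ("psm_count" %in% names(tab))
      as.integer(tab$psm_count) else rep(2L, length(acc))
    tab$psm_count <- NULL
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- acc
    mats[[p]] <- m
    psms[[p]] <- setNames(psm, acc)
    message("plex ", p, ": ", nrow(m), " proteins x ", ncol(m), " channels")
  }
  TmtExperiment(intensities = mats, psm = psms,
                channelData = DataFrame(meta))
}

#' Read mass-photometry landing events
#'
#' CSV with columns \code{event_id, contrast_or_mass, unit} and condition
#' labels (\code{glycoform, pH, replicate}); \code{unit} is
#' \code{"contrast"} or \code{"kDa"}.
#'
#' @param path CSV file path.
#' @return A data.frame of events.
#' @export
readLandingEvents <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"contrast_or_mass" %in% names(x))
    stop("events table lacks column contrast_or_mass")
  message("read ", nrow(x), " landing event(s) from ", path)
  x
}

#' Read a calibration-standard table
#'
#' CSV with columns \code{contrast, standard_mass_kDa}.
#'
#' @param path CSV file path.
#' @return A data.frame with columns \code{contrast, standard_mass_kDa}.
#' @export
readCalibrationTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("contrast", "standard_mass_kDa"), names(x))
  if (length(miss))
    stop("calibration table lacks column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read a granule-diameter table
#'
#' CSV with columns \code{diameter_nm, clone, genotype}.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readGranuleTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("diameter_nm", "clone", "genotype"), names(x))
  if (length(miss))
    stop("granule table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$diameter_nm <= 0)) stop("diameters must be positive")
  x
}

#' Read a neurotransmitter-uptake table
#'
#' CSV with columns \code{cpm, protein_mg, reserpine, genotype, replicate}.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readUptakeTable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cpm", "protein_mg", "reserpine", "genotype",
                    "replicate"), names(x))
  if (length(miss))
    stop("uptake table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$cpm < 0)) stop("cpm must be >= 0")
  if (any(x$protein_mg <= 0)) stop("protein_mg must be positive")
  x
}
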