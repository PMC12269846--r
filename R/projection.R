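# Projection of animal glycosites onto human orthologs and consolidation
# into the expanded human-coordinate glycoproteome. The conservation rule
# is positional, not identity-based: an animal Ser/Thr/Tyr site is
# conserved when the aligned human residue is any of Ser, Thr or Tyr; a
# site aligned to a gap or to any other residue is non-conserved.

#' Project animal glycosites onto human orthologs
#'
#' Each animal protein is globally aligned to its human ortholog
#' (full-length sequences) and every observed glycosite position is mapped
#' through the alignment. The projected site is \code{conserved} when the
#' aligned human residue is Ser, Thr or Tyr (identity is not required:
#' S -> Y counts), and \code{non_conserved} when it is any other residue or
#' a gap. Observations whose accession has no ortholog pair are excluded
#' from projection and returned separately.
#'
#' @param observations glycosite data.frame (see
#'   \code{\link{readGlycositeTable}}).
#' @param pairs ortholog-pair data.frame with columns
#'   \code{animal_accession, human_accession}.
#' @param animal_proteome,human_proteome \code{AAStringSet}s named by
#'   accession.
#' @param params \code{\link{alignmentParams}} for the alignments.
#' @return A list with \code{projected} (data.frame adding
#'   \code{human_accession, human_position, human_residue, status}),
#'   \code{unpaired} (observations lacking an ortholog) and
#'   \code{alignments} (one \code{ProteinAlignment} per aligned pair).
#' @export
projectSites <- function(observations, pairs, animal_proteome,
                         human_proteome, params = alignmentParams()) {
  observations <- validateGlycositeTable(observations,
                                         proteome = animal_proteome)
  if (anyDuplicated(pairs$animal_accession))
    stop("each animal accession may appear in at most one ortholog pair")
  missing_h <- setdiff(unique(pairs$human_accession), names(human_proteome))
  if (length(missing_h))
    stop("human sequence(s) missing: ", paste(missing_h, collapse = ", "))

  paired <- observations$accession %in% pairs$animal_accession
  unpaired <- observations[!paired, , drop = FALSE]
  if (nrow(unpaired))
    message(nrow(unpaired), " observation(s) on ",
            length(unique(unpaired$accession)),
            " unpaired protein(s) excluded from projection")
  obs <- observations[paired, , drop = FALSE]

  accs <- unique(obs$accession)
  hum_seqs <- as.character(human_proteome)
  ani_seqs <- as.character(animal_proteome)
  alns <- vector("list", length(accs)); names(alns) <- accs
  obs$human_accession <- pairs$human_accession[
    match(obs$accession, pairs$animal_accession)]
  obs$human_position <- NA_integer_
  obs$human_residue <- NA_character_
  for (acc in accs) {
    hacc <- pairs$human_accession[match(acc, pairs$animal_accession)]
    aln <- globalAlign(ani_seqs[[acc]], hum_seqs[[hacc]], params)
    alns[[acc]] <- aln
    rows <- which(obs$accession == acc)
    hp <- mapPosition(aln, obs$position[rows])
    obs$human_position[rows] <- hp
    hit <- !is.na(hp)
    obs$human_residue[rows][hit] <- substring(hum_seqs[[hacc]],
                                              hp[hit], hp[hit])
  }
  obs$status <- ifelse(!is.na(obs$human_residue) &
                         obs$human_residue %in% .STY,
                       "conserved", "non_conserved")
  rownames(obs) <- NULL
  list(projected = obs, unpaired = unpaired, alignments = alns)
}

#' Consolidate human-native and projected animal glycosites
#'
#' Builds the expanded glycoproteome: the union of experimentally
#' identified human sites and conserved animal sites, keyed by
#' (human accession, human position). Multiple observations converging on
#' one human residue merge into a single expanded site whose species,
#' biosource and glycoform sets are unions over the contributing
#' observations; evidence is \code{human_native}, \code{animal_conserved},
#' or \code{both}.
#'
#' @param human_observations glycosite data.frame of human observations
#'   (taxid 9606, positions in human coordinates).
#' @param projected_sites the \code{projected} data.frame from
#'   \code{\link{projectSites}} (non-conserved rows are ignored).
#' @return A data.frame of expanded sites with columns
#'   \code{human_accession, human_position, human_residue, evidence,
#'   species, biosources, glycoforms, n_human_obs, n_animal_obs}; set-valued
#'   columns are comma-separated sorted unique values.
#' @export
consolidateSites <- function(human_observations, projected_sites) {
  hum <- human_observations
  if (nrow(hum)) {
    miss <- setdiff(.GLYCOSITE_COLS, names(hum))
    if (length(miss))
      stop("human observation table lacks column(s): ",
           paste(miss, collapse = ", "))
  }
  ani <- projected_sites[projected_sites$status == "conserved", ,
                         drop = FALSE]

  key_h <- if (nrow(hum)) paste(hum$accession, hum$position) else character(0)
  key_a <- if (nrow(ani)) paste(ani$human_accession, ani$human_position)
           else character(0)

  # residue consistency at shared keys (sequence-version mismatch guard)
  res_h <- if (nrow(hum)) tapply(hum$residue, key_h, function(r)
    unique(r)) else list()
  res_a <- if (nrow(ani)) tapply(ani$human_residue, key_a, function(r)
    unique(r)) else list()
  if (any(lengths(res_h) > 1) || any(lengths(res_a) > 1))
    stop("conflicting residue letters at key(s): ",
         paste(c(names(res_h)[lengths(res_h) > 1],
                 names(res_a)[lengths(res_a) > 1]), collapse = ", "))
  shared <- intersect(names(res_h), names(res_a))
  bad <- shared[unlist(res_h[shared]) != unlist(res_a[shared])]
  if (length(bad))
    stop("human residue disagrees between native and projected site at: ",
         paste(bad, collapse = ", "),
         " (sequence-version mismatch?)")

  keys <- sort(unique(c(key_h, key_a)))
  collapse <- function(v) paste(sort(unique(as.character(v))),
                                collapse = ",")
  agg <- function(values, key, keys) {
    out <- rep("", length(keys))
    if (length(values)) {
      t <- tapply(values, key, collapse)
      out[match(names(t), keys)] <- t
    }
    out
  }
  mergeSets <- function(a, b) {
    ifelse(a == "", b, ifelse(b == "", a,
      vapply(strsplit(paste(a, b, sep = ","), ","), collapse, "")))
  }

  n_h <- integer(length(keys)); n_a <- integer(length(keys))
  if (length(key_h)) {
    t <- table(key_h); n_h[match(names(t), keys)] <- as.integer(t)
  }
  if (length(key_a)) {
    t <- table(key_a); n_a[match(names(t), keys)] <- as.integer(t)
  }

  residue <- rep(NA_character_, length(keys))
  residue[match(names(res_h), keys)] <- unlist(res_h)
  residue[match(names(res_a), keys)] <- unlist(res_a)

  out <- data.frame(
    human_accession = sub(" \\S+$", "", keys),
    human_position = as.integer(sub("^\\S+ ", "", keys)),
    human_residue = residue,
    evidence = ifelse(n_h > 0 & n_a > 0, "both",
                      ifelse(n_h > 0, "human_native", "animal_conserved")),
    species = mergeSets(
      agg(if (nrow(hum)) hum$taxid else integer(0), key_h, keys),
      agg(if (nrow(ani)) ani$taxid else integer(0), key_a, keys)),
    biosources = mergeSets(
      agg(if (nrow(hum)) hum$biosource else character(0), key_h, keys),
      agg(if (nrow(ani)) ani$biosource else character(0), key_a, keys)),
    glycoforms = mergeSets(
      agg(if (nrow(hum)) hum$glycoform else character(0), key_h, keys),
      agg(if (nrow(ani)) ani$glycoform else character(0), key_a, keys)),
    n_human_obs = n_h,
    n_animal_obs = n_a
  )
  out <- out[order(out$human_accession, out$human_position), ]
  rownames(out) <- NULL
  message("consolidated ", nrow(out), " expanded site(s): ",
          sum(out$evidence == "human_native"), " human-only, ",
          sum(out$evidence == "animal_conserved"), " animal-only, ",
          sum(out$evidence == "both"), " both")
  out
}

#' Species-combination overlap of the expanded glycoproteome
#'
#' Counts expanded sites per non-empty combination of
#' \{human, mouse, rat, pig\} evidence (15 categories), the layout of a
#' four-set Venn diagram over species sources.
#'
#' @param expanded expanded-site data.frame from
#'   \code{\link{consolidateSites}}.
#' @return A list with \code{counts} (named integer vector over all 15
#'   combinations, names like \code{"human+mouse"}),
#'   \code{human_animal_overlap} (sites with human and >= 1 animal
#'   evidence) and \code{total}.
#' @export
speciesOverlap <- function(expanded) {
  sp_names <- unname(.SPECIES_NAMES)
  combos <- unlist(lapply(seq_along(sp_names), function(k)
    apply(utils::combn(sp_names, k), 2, paste, collapse = "+")))
  counts <- setNames(integer(length(combos)), combos)
  if (nrow(expanded)) {
    cat_of <- vapply(strsplit(expanded$species, ","), function(tx) {
      nm <- .SPECIES_NAMES[tx]
      nm <- nm[!is.na(nm)]
      if (!length(nm)) return("other")
      paste(sp_names[sp_names %in% nm], collapse = "+")
    }, "")
    t <- table(cat_of)
    known <- intersect(names(t), combos)
    counts[known] <- counts[known] + as.integer(t[known])
    extra <- setdiff(names(t), combos)
    if (length(extra))
      counts <- c(counts, setNames(as.integer(t[extra]), extra))
  }
  has_h <- grepl("(^|\\+)human(\\+|$)", names(counts))
  has_a <- grepl("mouse|rat|pig", names(counts))
  list(counts = counts,
       human_animal_overlap = sum(counts[has_h & has_a]),
       total = nrow(expanded))
}

#' Novel sites relative to a reference compilation
#'
#' Partitions expanded sites by membership of their
#' (accession, position) key in an external reference site set.
#'
#' @param expanded expanded-site data.frame.
#' @param reference data.frame with columns \code{accession, position} (or
#'   \code{human_accession, human_position}).
#' @return A list with \code{novel} and \code{known} counts.
#' @export
noveltyVsReference <- function(expanded, reference) {
  acc <- reference$accession %||% reference$human_accession
  pos <- reference$position %||% reference$human_position
  ref_keys <- unique(paste(acc, pos))
  keys <- paste(expanded$human_accession, expanded$human_position)
  known <- sum(keys %in% ref_keys)
  list(novel = nrow(expanded) - known, known = known)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Glycosite density over extracellular residues
#'
#' Number of expanded sites per 100 extracellular amino acids of one
#' protein; sites outside the extracellular ranges are excluded from the
#' numerator.
#'
#' @param accession protein accession.
#' @param expanded expanded-site data.frame.
#' @param extracellular_ranges data.frame with columns \code{accession,
#'   start, end} (1-based inclusive, non-overlapping per protein).
#' @return Sites per 100 extracellular residues.
#' @export
siteDensity <- function(accession, expanded, extracellular_ranges) {
  r <- extracellular_ranges[extracellular_ranges$accession == accession, ,
                            drop = FALSE]
  if (nrow(r) == 0 || sum(r$end - r$start + 1) == 0)
    stop("no extracellular residues annotated for ", accession)
  if (any(r$start < 1) || any(r$end < r$start))
    stop("ranges must be 1-based inclusive with start <= end")
  r <- r[order(r$start), ]
  if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
    stop("extracellular ranges overlap for ", accession)
  len <- sum(r$end - r$start + 1)
  pos <- expanded$human_position[expanded$human_accession == accession]
  inside <- vapply(pos, function(p) any(p >= r$start & p <= r$end), NA)
  100 * sum(inside) / len
}

#' Concordance with external glycosylation predictions
#'
#' Fraction of expanded sites flagged as predicted glycosylated by an
#' external predictor; sites lacking a flag are excluded from the fraction
#' and counted separately.
#'
#' @param expanded expanded-site data.frame.
#' @param prediction_flags data.frame with columns \code{accession,
#'   position, predicted} (logical).
#' @return A list with \code{fraction} (NA when no site is flagged),
#'   \code{n_scored} and \code{n_unflagged}.
#' @export
predictionConcordance <- function(expanded, prediction_flags) {
  keys <- paste(expanded$human_accession, expanded$human_position)
  fk <- paste(prediction_flags$accession, prediction_flags$position)
  idx <- match(keys, fk)
  flag <- prediction_flags$predicted[idx]
  scored <- !is.na(idx)
  list(fraction = if (any(scored)) mean(flag[scored]) else NA_real_,
       n_scored = sum(scored),
       n_unflagged = sum(!scored))
}
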