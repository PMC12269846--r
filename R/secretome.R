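# Multi-batch TMT secretome quantification: quantifiability filtering,
# sample-loading normalization within each plex, internal reference scaling
# (IRS) across plexes via the pooled reference channel carried in every
# plex, and differential secretion testing on the combined matrix.

#' TmtExperiment: a set of TMT plexes with channel metadata
#'
#' Holds one reporter-intensity matrix (proteins x channels) and one PSM
#' count vector per plex, plus a channel-metadata table with at least
#' \code{plex}, \code{channel} and \code{is_reference} columns. Every plex
#' must carry at least one reference channel (the pooled internal reference
#' secretome that makes between-batch scaling possible).
#'
#' @slot intensities named list of non-negative matrices, one per plex,
#'   with protein rownames and channel colnames.
#' @slot psm named list of integer vectors (PSM count per protein), names
#'   matching the matrix rownames.
#' @slot channelData a \code{DataFrame} with one row per channel across all
#'   plexes.
#' @slot filterLog list recording what \code{\link{filterQuantifiable}}
#'   removed.
#' @export
setClass("TmtExperiment",
  representation(intensities = "list", psm = "list",
                 channelData = "DataFrame", filterLog = "list"),
  prototype(filterLog = list()),
  validity = function(object) {
    msg <- NULL
    cd <- object@channelData
    need <- c("plex", "channel", "is_reference")
    if (!all(need %in% colnames(cd)))
      return(paste("channelData needs columns:",
                   paste(need, collapse = ", ")))
    if (!setequal(names(object@intensities), unique(cd$plex)))
      msg <- c(msg, "plex names must match channelData$plex")
    for (p in names(object@intensities)) {
      m <- object@intensities[[p]]
      meta <- cd[cd$plex == p, , drop = FALSE]
      if (is.null(rownames(m)))
        msg <- c(msg, paste0("plex ", p, ": matrix needs protein rownames"))
      if (ncol(m) != nrow(meta))
        msg <- c(msg, paste0("plex ", p,
                             ": channel count differs from metadata"))
      else if (!identical(colnames(m), as.character(meta$channel)))
        msg <- c(msg, paste0("plex ", p,
                             ": channel names differ from metadata"))
      if (any(m < 0, na.rm = TRUE))
        msg <- c(msg, paste0("plex ", p, ": negative intensities"))
      if (!any(meta$is_reference))
        msg <- c(msg, paste0("plex ", p, ": no reference channel"))
      ps <- object@psm[[p]]
      if (is.null(ps) || !identical(names(ps), rownames(m)))
        msg <- c(msg, paste0("plex ", p,
                             ": psm names must match protein rownames"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a TmtExperiment
#'
#' @param intensities named list of protein x channel matrices, one per
#'   plex.
#' @param psm named list of per-protein PSM counts; defaults to 2 for every
#'   protein (i.e. quantifiable) when omitted.
#' @param channelData data.frame/DataFrame of channel metadata
#'   (\code{plex, channel, is_reference} plus design columns).
#' @return A \code{TmtExperiment}.
#' @export
TmtExperiment <- function(intensities, psm = NULL, channelData) {
  if (is.null(names(intensities)))
    names(intensities) <- paste0("plex", seq_along(intensities))
  channelData <- DataFrame(channelData)
  channelData$plex <- as.character(channelData$plex)
  channelData$channel <- as.character(channelData$channel)
  if (is.null(psm))
    psm <- lapply(intensities, function(m)
      setNames(rep(2L, nrow(m)), rownames(m)))
  if (is.null(names(psm))) names(psm) <- names(intensities)
  new("TmtExperiment", intensities = intensities, psm = psm,
      channelData = channelData)
}

setMethod("show", "TmtExperiment", function(object) {
  cat("TmtExperiment with", length(object@intensities), "plex(es)\n")
  for (p in names(object@intensities)) {
    m <- object@intensities[[p]]
    nref <- sum(object@channelData$is_reference &
                  object@channelData$plex == p)
    cat("  ", p, ": ", nrow(m), " proteins x ", ncol(m), " channels (",
        nref, " reference)\n", sep = "")
  }
  if (length(object@filterLog))
    cat("  filtered:", paste(names(object@filterLog),
        unlist(object@filterLog), sep = "=", collapse = ", "), "\n")
})

#' @rdname TmtExperiment-accessors
#' @export
plexes <- function(x) x@intensities
#' Accessors for TmtExperiment
#'
#' @param x a \code{TmtExperiment}.
#' @return \code{plexes}: list of intensity matrices; \code{psmCounts}:
#'   list of PSM vectors; \code{channelData}: the metadata
#'   \code{DataFrame}; \code{filterLog}: removal counts by reason.
#' @name TmtExperiment-accessors
#' @export
psmCounts <- function(x) x@psm
#' @rdname TmtExperiment-accessors
#' @export
channelData <- function(x) x@channelData
#' @rdname TmtExperiment-accessors
#' @export
filterLog <- function(x) x@filterLog

#' Retain quantifiable proteins
#'
#' Keeps proteins that have a nonzero intensity in every channel of every
#' plex and at least 2 PSMs in every plex; everything else (missing from a
#' plex, a zero channel, or single-PSM identifications) is removed and
#' counted by reason in \code{\link{filterLog}}.
#'
#' @param x a \code{TmtExperiment}.
#' @param min_psm minimum PSM count (default 2).
#' @return The filtered \code{TmtExperiment}.
#' @export
filterQuantifiable <- function(x, min_psm = 2L) {
  mats <- x@intensities
  all_prot <- unique(unlist(lapply(mats, rownames)))
  complete <- rep(TRUE, length(all_prot)); names(complete) <- all_prot
  psm_ok <- rep(TRUE, length(all_prot)); names(psm_ok) <- all_prot
  for (p in names(mats)) {
    m <- mats[[p]]
    present <- all_prot %in% rownames(m)
    nz <- rep(FALSE, length(all_prot))
    nz[present] <- apply(m[all_prot[present], , drop = FALSE] > 0, 1, all)
    complete <- complete & nz
    ps <- rep(0L, length(all_prot))
    ps[present] <- x@psm[[p]][all_prot[present]]
    psm_ok <- psm_ok & (ps >= min_psm)
  }
  keep <- all_prot[complete & psm_ok]
  removed_missing <- sum(!complete)
  removed_psm <- sum(complete & !psm_ok)
  message("filterQuantifiable: kept ", length(keep), "/", length(all_prot),
          " (removed ", removed_missing, " missing/zero-channel, ",
          removed_psm, " low-PSM)")
  out <- x
  out@intensities <- lapply(mats, function(m) m[keep, , drop = FALSE])
  out@psm <- lapply(names(mats), function(p) x@psm[[p]][keep])
  names(out@psm) <- names(mats)
  out@filterLog <- list(kept = length(keep),
                        removed_missing_or_zero = removed_missing,
                        removed_low_psm = removed_psm)
  validObject(out)
  out
}

#' Sample-loading normalization
#'
#' Within each plex, scales every channel by (mean of all channel totals) /
#' (that channel's total) so all channel totals are equal afterwards; this
#' corrects unequal peptide loading before between-batch scaling.
#'
#' @param x a \code{TmtExperiment}.
#' @return The normalized \code{TmtExperiment}.
#' @export
normalizeSampleLoading <- function(x) {
  out <- x
  out@intensities <- lapply(x@intensities, function(m) {
    tot <- colSums(m)
    if (any(tot == 0)) stop("channel with zero total intensity")
    sweep(m, 2, mean(tot) / tot, "*")
  })
  out
}

#' Internal reference scaling across plexes
#'
#' For every protein, each plex's reference summary is the geometric mean
#' of its reference channels; the global summary is the geometric mean of
#' the plex summaries, and all channels of that plex are multiplied by
#' global/plex on a protein-specific basis. Afterwards the per-protein
#' reference summaries are equal across plexes, so channels from different
#' batches are directly comparable. Proteins with a zero reference
#' intensity in some plex cannot be scaled and are dropped with a warning;
#' plexes are combined over the intersection of surviving proteins.
#'
#' @param x a \code{TmtExperiment} (typically filtered and
#'   loading-normalized).
#' @return A \code{SummarizedExperiment} with assay \code{"irs"} (the
#'   combined scaled matrix), colData from the channel metadata, and the
#'   per-protein/per-plex scaling factors in \code{metadata()$irs_factors}.
#' @export
irsCombine <- function(x) {
  mats <- x@intensities
  common <- Reduce(intersect, lapply(mats, rownames))
  dropped <- unique(unlist(lapply(mats, rownames)))
  dropped <- setdiff(dropped, common)
  if (length(dropped))
    message(length(dropped),
            " protein(s) absent from some plex dropped before IRS")
  mats <- lapply(mats, function(m) m[common, , drop = FALSE])

  geomean <- function(m) exp(rowMeans(log(m)))
  cd <- x@channelData
  refsum <- sapply(names(mats), function(p) {
    refch <- cd$channel[cd$plex == p & cd$is_reference]
    geomean(mats[[p]][, refch, drop = FALSE])
  })
  refsum <- matrix(refsum, nrow = length(common),
                   dimnames = list(common, names(mats)))
  bad <- apply(refsum == 0 | !is.finite(refsum), 1, any)
  if (any(bad)) {
    warning(sum(bad), " protein(s) with zero reference intensity in some ",
            "plex excluded from IRS: ",
            paste(head(common[bad]), collapse = ", "))
    common <- common[!bad]
    refsum <- refsum[!bad, , drop = FALSE]
    mats <- lapply(mats, function(m) m[common, , drop = FALSE])
  }
  if (!length(common)) stop("no protein is quantifiable in every plex")
  global <- exp(rowMeans(log(refsum)))
  factors <- global / refsum   # proteins x plexes
  scaled <- lapply(names(mats), function(p) mats[[p]] * factors[, p])
  combined <- do.call(cbind, scaled)
  ord <- unlist(lapply(names(mats), function(p)
    which(cd$plex == p)[match(colnames(mats[[p]]),
                              cd$channel[cd$plex == p])]))
  colnames(combined) <- paste(cd$plex[ord], cd$channel[ord], sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(irs = combined), colData = cd[ord, , drop = FALSE])
  S4Vectors::metadata(se)$irs_factors <- factors
  se
}

#' Differential secretion between two channel groups
#'
#' Two-sided Welch t-test on log2 IRS-normalized intensities per protein;
#' log2 fold change is mean(log2 group A) - mean(log2 group B).
#' Benjamini-Hochberg adjustment by default; Bonferroni selectable for
#' genotype (WT vs knockout) contrasts. Residual zeros (which should not
#' survive filtering) are replaced by half the smallest positive intensity
#' with a warning before the log transform.
#'
#' @param x a \code{SummarizedExperiment} from \code{\link{irsCombine}}, or
#'   a positive matrix.
#' @param group_a,group_b column names (or indices / logical masks) of the
#'   two groups; each needs >= 2 channels.
#' @param alpha significance level on the adjusted p-value (default 0.1).
#' @param adjust \code{"BH"} (default) or \code{"bonferroni"}.
#' @param direction fold-change direction required for a responsive call;
#'   see \code{\link{classifyResponsive}}.
#' @return A data.frame with \code{protein, log2fc, pvalue, padj,
#'   responsive}.
#' @export
differentialSecretion <- function(x, group_a, group_b, alpha = 0.1,
                                  adjust = c("BH", "bonferroni"),
                                  direction = c("positive", "negative",
                                                "both")) {
  adjust <- match.arg(adjust)
  direction <- match.arg(direction)
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x) else as.matrix(x)
  pick <- function(g) {
    if (is.logical(g)) which(g) else if (is.numeric(g)) as.integer(g)
    else match(g, colnames(m))
  }
  ia <- pick(group_a); ib <- pick(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown channel in group definition")
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 channels")
  if (any(m[, c(ia, ib)] <= 0)) {
    repl <- min(m[m > 0]) / 2
    warning("non-positive intensities replaced by half the matrix minimum (",
            format(repl), ") before log transform")
    m[m <= 0] <- repl
  }
  lm2 <- log2(m)
  a <- lm2[, ia, drop = FALSE]; b <- lm2[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  sed <- sqrt(va / na + vb / nb)
  tstat <- (ma - mb) / sed
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate rows: zero variance in both groups
  degen <- sed == 0 | !is.finite(tstat)
  p[degen & abs(ma - mb) < 1e-12] <- 1
  p[degen & abs(ma - mb) >= 1e-12] <- 0
  padj <- p.adjust(p, method = adjust)
  res <- data.frame(protein = rownames(m), log2fc = ma - mb,
                    pvalue = p, padj = padj, row.names = NULL)
  res$responsive <- classifyResponsive(res, alpha = alpha,
                                       direction = direction,
                                       return_flags = TRUE)
  res
}

#' Classify responsive proteins
#'
#' A protein is responsive when its adjusted p-value is below \code{alpha}
#' and its log2 fold change lies in the requested direction (positive =
#' secretion increased on depolarization for a depolarized-vs-basal
#' contrast).
#'
#' @param results data.frame from \code{\link{differentialSecretion}}.
#' @param alpha adjusted-p threshold (default 0.1).
#' @param direction \code{"positive"} (default), \code{"negative"} or
#'   \code{"both"}.
#' @param return_flags return the logical vector instead of the subset.
#' @return Character vector of responsive proteins (or logical flags).
#' @export
classifyResponsive <- function(results, alpha = 0.1,
                               direction = c("positive", "negative",
                                             "both"),
                               return_flags = FALSE) {
  direction <- match.arg(direction)
  ok_dir <- switch(direction,
                   positive = results$log2fc > 0,
                   negative = results$log2fc < 0,
                   both = rep(TRUE, nrow(results)))
  flags <- results$padj < alpha & ok_dir
  if (return_flags) flags else results$protein[flags]
}

#' Count expanded glycosites per protein
#'
#' @param proteins character vector of accessions (e.g. the responsive
#'   set).
#' @param expanded expanded-site data.frame from
#'   \code{\link{consolidateSites}}.
#' @return A data.frame with \code{accession, n_glycosites} (0 for proteins
#'   absent from the site table), ordered by decreasing count.
#' @export
annotateGlycosites <- function(proteins, expanded) {
  t <- table(expanded$human_accession)
  n <- as.integer(t[proteins])
  n[is.na(n)] <- 0L
  out <- data.frame(accession = proteins, n_glycosites = n)
  out[order(-out$n_glycosites, out$accession), , drop = FALSE]
}
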