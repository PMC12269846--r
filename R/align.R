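# Global pairwise protein alignment with affine gaps, used to lift animal
# glycosite coordinates onto human orthologs. The aligner is a
# Needleman-Wunsch/Gotoh implementation with a pluggable substitution
# matrix (Gonnet 1992 by default, BLOSUM62 shipped as an alternative) and a
# fixed, documented tie-break so projected coordinates are reproducible.

#' Load a substitution matrix
#'
#' Matrices ship as plain-text tab-separated files (first row/column =
#' residue letters) under \code{inst/extdata}; \code{"gonnet"} and
#' \code{"blosum62"} name the bundled ones, any other value is taken as a
#' file path.
#'
#' @param name \code{"gonnet"} (Gonnet 1992, the default used for ortholog
#'   projection), \code{"blosum62"}, or a path to a matrix file in the same
#'   format.
#' @return A symmetric numeric matrix over the 20 canonical residues.
#' @export
loadSubstitutionMatrix <- function(name = "gonnet") {
  path <- switch(tolower(name),
    gonnet = , gonnet1992 = system.file("extdata", "gonnet1992.txt",
                                        package = "OGlycoAtlas"),
    blosum62 = system.file("extdata", "blosum62.txt",
                           package = "OGlycoAtlas"),
    name)
  if (!file.exists(path)) stop("no substitution matrix at ", path)
  m <- as.matrix(read.delim(path, comment.char = "#", row.names = 1,
                            check.names = FALSE))
  colnames(m) <- trimws(colnames(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("substitution matrix is not symmetric")
  m
}

#' Alignment parameters
#'
#' Affine-gap convention: a gap run of length k costs
#' \code{gap_open + k * gap_extend}; terminal gaps are penalized (true
#' global alignment of full-length orthologs).
#'
#' @param matrix substitution matrix name or matrix (see
#'   \code{\link{loadSubstitutionMatrix}}).
#' @param gap_open gap opening penalty (<= gap_extend <= 0); default -10 on
#'   the Gonnet scale.
#' @param gap_extend per-residue gap extension penalty; default -1.
#' @return An \code{AlignmentParams} object.
#' @export
alignmentParams <- function(matrix = "gonnet", gap_open = -10,
                            gap_extend = -1) {
  m <- if (is.matrix(matrix)) matrix else loadSubstitutionMatrix(matrix)
  mname <- if (is.matrix(matrix)) "custom" else as.character(matrix)
  new("AlignmentParams", matrixName = mname, matrix = m,
      gapOpen = as.numeric(gap_open), gapExtend = as.numeric(gap_extend))
}

#' @rdname alignmentParams
#' @export
setClass("AlignmentParams",
         representation(matrixName = "character", matrix = "matrix",
                        gapOpen = "numeric", gapExtend = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (!(object@gapOpen <= object@gapExtend &&
                 object@gapExtend <= 0))
             msg <- c(msg, "must have gap_open <= gap_extend <= 0")
           if (!isTRUE(all.equal(object@matrix, t(object@matrix),
                                 tolerance = 1e-8)))
             msg <- c(msg, "substitution matrix must be symmetric")
           if (is.null(msg)) TRUE else msg
         })

#' Pairwise global protein alignment
#'
#' S4 container for one gapped global alignment; see
#' \code{\link{globalAlign}}.
#'
#' @slot gappedA,gappedB equal-length gapped sequences (gap = \code{"-"}).
#' @slot score alignment score under the parameters used.
#' @slot params the \code{AlignmentParams} used.
#' @export
setClass("ProteinAlignment",
         representation(gappedA = "character", gappedB = "character",
                        score = "numeric", params = "AlignmentParams"),
         validity = function(object) {
           msg <- NULL
           if (nchar(object@gappedA) != nchar(object@gappedB))
             msg <- c(msg, "gapped sequences must have equal length")
           ca <- strsplit(object@gappedA, "")[[1]]
           cb <- strsplit(object@gappedB, "")[[1]]
           if (any(ca == "-" & cb == "-"))
             msg <- c(msg, "no column may be gap in both sequences")
           if (is.null(msg)) TRUE else msg
         })

setMethod("show", "ProteinAlignment", function(object) {
  cat("ProteinAlignment (global, affine gaps)\n")
  cat("  columns:", nchar(object@gappedA),
      " score:", format(object@score), "\n")
  w <- min(60, nchar(object@gappedA))
  cat("  A: ", substr(object@gappedA, 1, w),
      if (nchar(object@gappedA) > w) "..." else "", "\n", sep = "")
  cat("  B: ", substr(object@gappedB, 1, w),
      if (nchar(object@gappedB) > w) "..." else "", "\n", sep = "")
})

#' Accessors for ProteinAlignment
#'
#' @param x a \code{ProteinAlignment}.
#' @return \code{alignedA}/\code{alignedB}: the gapped sequences;
#'   \code{alignmentScore}: the score.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
alignedA <- function(x) x@gappedA
#' @rdname alignment-accessors
#' @export
alignedB <- function(x) x@gappedB
#' @rdname alignment-accessors
#' @export
alignmentScore <- function(x) x@score

#' Global alignment of two protein sequences
#'
#' Optimal global (end-to-end) alignment under Needleman-Wunsch with
#' affine gaps. Ties in the traceback are broken deterministically:
#' diagonal over gap-in-b over gap-in-a. Empty sequences are allowed and
#' yield all-gap alignments costing one affine gap run.
#'
#' @param a,b amino-acid strings (canonical letters covered by the matrix).
#' @param params an \code{\link{alignmentParams}} object.
#' @return A \code{ProteinAlignment}.
#' @examples
#' aln <- globalAlign("ACDE", "ADE")
#' columnMap(aln)
#' @export
globalAlign <- function(a, b, params = alignmentParams()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  alphabet <- rownames(params@matrix)
  for (nm in c("a", "b")) {
    s <- get(nm)
    ch <- strsplit(s, "")[[1]]
    bad <- which(!ch %in% alphabet)
    if (length(bad))
      stop("residue '", ch[bad[1]], "' at position ", bad[1], " of ", nm,
           " has no substitution-matrix entry")
  }
  res <- .gotohAlign(a, b, params@matrix, paste(alphabet, collapse = ""),
                     params@gapOpen, params@gapExtend)
  new("ProteinAlignment", gappedA = res$gapped_a, gappedB = res$gapped_b,
      score = res$score, params = params)
}

#' Column map of an alignment
#'
#' @param aln a \code{ProteinAlignment}.
#' @return A data.frame with one row per alignment column: \code{column},
#'   \code{pos_a}, \code{pos_b} (1-based residue indices, \code{NA} where
#'   the column is a gap in that sequence).
#' @export
columnMap <- function(aln) {
  ca <- strsplit(aln@gappedA, "")[[1]]
  cb <- strsplit(aln@gappedB, "")[[1]]
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  data.frame(column = seq_along(ca), pos_a = pos_a, pos_b = pos_b)
}

#' Map a residue position through an alignment
#'
#' @param aln a \code{ProteinAlignment}.
#' @param pos_in_a 1-based residue index in sequence a.
#' @return The 1-based index of the residue in b sharing the column, or
#'   \code{NA} when that column is a gap in b.
#' @export
mapPosition <- function(aln, pos_in_a) {
  cm <- columnMap(aln)
  n_a <- sum(!is.na(cm$pos_a))
  if (any(pos_in_a < 1 | pos_in_a > n_a))
    stop("position out of range 1..", n_a)
  cm$pos_b[match(pos_in_a, cm$pos_a)]
}

# recompute an alignment's score from its gapped strings (used by tests and
# the validity invariant: column substitution scores + affine gap runs)
.scoreFromGapped <- function(gapped_a, gapped_b, params) {
  ca <- strsplit(gapped_a, "")[[1]]
  cb <- strsplit(gapped_b, "")[[1]]
  sub <- sum(params@matrix[cbind(ca[ca != "-" & cb != "-"],
                                 cb[ca != "-" & cb != "-"])])
  gapRuns <- function(isgap) {
    r <- rle(isgap)
    lens <- r$lengths[r$values]
    if (!length(lens)) return(0)
    length(lens) * params@gapOpen + sum(lens) * params@gapExtend
  }
  sub + gapRuns(ca == "-") + gapRuns(cb == "-")
}
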