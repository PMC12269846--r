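# Independent oracles used across the suite.

# Exhaustive enumeration of all global alignments of a and b under affine
# gap costs (gap run of length k costs go + k*ge). Pure recursion over the
# three column types, no dynamic programming, so it is independent of the
# package's aligner. Only feasible for short sequences.
bruteForceAlignScore <- function(a, b, mat, go, ge) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n)
      best <- max(best,
                  ge + (if (prev == "X") 0 else go) + rec(i + 1, j, "X"))
    if (j <= m)
      best <- max(best,
                  ge + (if (prev == "Y") 0 else go) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "")
}

# affine score of a given gapped alignment, recomputed column-by-column
scoreGapped <- function(ga, gb, mat, go, ge) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  both <- ca != "-" & cb != "-"
  s <- if (any(both)) sum(mat[cbind(ca[both], cb[both])]) else 0
  runs <- function(g) {
    r <- rle(g); lens <- r$lengths[r$values]
    if (!length(lens)) 0 else length(lens) * go + sum(lens) * ge
  }
  s + runs(ca == "-") + runs(cb == "-")
}

randomSeq <- function(n, alphabet = c("A", "C", "D", "E"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# minimal glycosite observation rows
obsRow <- function(accession, position, residue = "T", taxid = 9606L,
                   glycoform = "HexNAc", biosource = "src",
                   psm_count = 2L) {
  data.frame(accession = accession, taxid = taxid, position = position,
             residue = residue, glycoform = glycoform,
             biosource = biosource, psm_count = psm_count)
}

# projected-site rows in the shape projectSites() emits
projRow <- function(human_accession, human_position, taxid = 10090L,
                    human_residue = "T", status = "conserved",
                    accession = "ANI", position = 1L,
                    biosource = "brain", glycoform = "HexNAc") {
  data.frame(accession = accession, taxid = taxid, position = position,
             residue = "T", glycoform = glycoform, biosource = biosource,
             psm_count = 2L, human_accession = human_accession,
             human_position = human_position,
             human_residue = human_residue, status = status)
}
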