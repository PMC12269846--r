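# Elemental and protein mass arithmetic, including annotation of the
# glycosaminoglycan linkage-region ("GAG stub") masses observed as residual
# hexasaccharide modifications on Ser after chondroitinase treatment.

# IUPAC/CODATA monoisotopic atomic masses (u), >= 6 decimals
.ELEMENT_MONO <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Se = 79.9165213,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Fe = 55.9349375
)

# standard average residue masses (Da) and water
.RESIDUE_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_AVG <- 18.01528

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts, e.g.
#' \code{elementalComposition(C = 37, H = 55, N = 1, O = 30)} for the
#' unsulfated GAG linkage-region hexasaccharide stub.
#'
#' @param ... named non-negative integer atom counts, or a single named
#'   vector.
#' @return A named integer vector of class \code{ElementalComposition}.
#' @examples
#' elementalComposition(H = 2, O = 1)
#' @export
elementalComposition <- function(...) {
  x <- c(...)
  if (length(x) == 0) {
    out <- integer(0)
    class(out) <- "ElementalComposition"
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all element counts must be named by element symbol")
  unknown <- setdiff(names(x), names(.ELEMENT_MONO))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(x < 0) || any(x != floor(x)))
    stop("element counts must be non-negative integers")
  counts <- tapply(as.integer(x), names(x), sum)
  out <- setNames(as.integer(counts), names(counts))
  class(out) <- "ElementalComposition"
  out
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp a named count vector as returned by
#'   \code{\link{elementalComposition}} (a plain named vector is accepted).
#' @return Monoisotopic mass in u.
#' @examples
#' monoisotopicMass(elementalComposition(C = 37, H = 55, N = 1, O = 30))
#' @export
monoisotopicMass <- function(comp) {
  if (!inherits(comp, "ElementalComposition"))
    comp <- do.call(elementalComposition, as.list(comp))
  if (length(comp) == 0) return(0)
  sum(unclass(comp) * .ELEMENT_MONO[names(comp)])
}

#' Average (isotope-weighted) mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water, the convention
#' used to state e.g. the 50.438 kDa chromogranin A primary-sequence mass.
#'
#' @param sequence amino-acid string over the 20 canonical letters.
#' @param on_x action for the ambiguity letter X: \code{"error"} (default)
#'   or \code{"skip"} (X residues contribute no mass).
#' @return Mass in kDa, rounded to 3 decimals.
#' @examples
#' averageProteinMass("GG")
#' @export
averageProteinMass <- function(sequence, on_x = c("error", "skip")) {
  on_x <- match.arg(on_x)
  sequence <- as.character(sequence)
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (any(aa == "X")) {
    if (on_x == "error")
      stop("sequence contains ambiguity letter X at position ",
           which(aa == "X")[1])
    aa <- aa[aa != "X"]
  }
  bad <- setdiff(unique(aa), names(.RESIDUE_AVG))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  round((sum(.RESIDUE_AVG[aa]) + .WATER_AVG) / 1000, 3)
}

#' GAG linkage-region stub classes
#'
#' The residual hexasaccharide left on Ser after chondroitinase ABC
#' digestion, HexA(-H2O)HexNAcHexAHexHexXyl-O-, occurs without, with one, or
#' with two sulfate groups. Expected monoisotopic masses are computed from
#' the elemental compositions so the SO3 spacing (79.95682 u) is structural.
#'
#' @return A data.frame with columns \code{label}, \code{formula} and
#'   \code{expected_mass} (u).
#' @examples
#' gagStubClasses()
#' @export
gagStubClasses <- function() {
  comps <- list(
    "unsulfated"    = elementalComposition(C = 37, H = 55, N = 1, O = 30),
    "mono-sulfated" = elementalComposition(C = 37, H = 55, N = 1, O = 33,
                                           S = 1),
    "di-sulfated"   = elementalComposition(C = 37, H = 55, N = 1, O = 36,
                                           S = 2)
  )
  data.frame(
    label = names(comps),
    formula = vapply(comps, function(cc)
      paste0(names(cc), ifelse(unclass(cc) > 1, unclass(cc), ""),
             collapse = ""), ""),
    expected_mass = vapply(comps, monoisotopicMass, 0),
    row.names = NULL
  )
}

#' Classify an observed glycan mass increment as a GAG stub
#'
#' Matches an observed modification mass against the three linkage-region
#' stub classes within a relative (ppm) tolerance; when several classes
#' match, the closest is returned.
#'
#' @param observed_delta observed modification mass in u (> 0).
#' @param tol_ppm relative tolerance in ppm (default 10, the usual
#'   high-resolution precursor tolerance).
#' @return One row of \code{\link{gagStubClasses}} with an added
#'   \code{ppm_error} column, or \code{NULL} when nothing matches.
#' @examples
#' classifyGagStub(993.2809)
#' @export
classifyGagStub <- function(observed_delta, tol_ppm = 10) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || tol_ppm <= 0)
    stop("tol_ppm must be a positive number")
  if (!is.numeric(observed_delta) || length(observed_delta) != 1 ||
      observed_delta <= 0)
    stop("observed_delta must be a single positive mass in u")
  cls <- gagStubClasses()
  ppm <- 1e6 * (observed_delta - cls$expected_mass) / cls$expected_mass
  ok <- abs(ppm) <= tol_ppm
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(abs(ppm[ok]))]
  out <- cls[i, , drop = FALSE]
  out$ppm_error <- ppm[i]
  rownames(out) <- NULL
  out
}

#' Average GalNAc glycans per protein molecule
#'
#' Converts a compositional glycan measurement (micromoles of GalNAc per
#' 100 mg of protein) and the protein molar mass (mg/umol, i.e. kDa) into
#' the average number of glycans carried per molecule.
#'
#' @param umol_per_100mg micromoles of glycan per 100 mg protein (> 0
#'   unless exactly 0).
#' @param mw_mg_per_umol protein molar mass in mg/umol (> 0).
#' @return Average glycans per molecule.
#' @examples
#' glycansPerMolecule(5, 48)
#' @export
glycansPerMolecule <- function(umol_per_100mg, mw_mg_per_umol) {
  if (!is.numeric(umol_per_100mg) || umol_per_100mg < 0)
    stop("umol_per_100mg must be non-negative")
  if (!is.numeric(mw_mg_per_umol) || mw_mg_per_umol <= 0)
    stop("mw_mg_per_umol must be positive")
  umol_per_100mg * mw_mg_per_umol / 100
}
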