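# Mass-photometry calibration and oligomer profiling, dense-core-granule
# (DCG) morphometry, and vesicular noradrenaline-uptake normalization.

.OLIGO_CLASSES <- c("I", "II", "IV", "VIII", "X", "XL")
.OLIGO_MULTIPLES <- c(I = 1, II = 2, IV = 4, VIII = 8)

#' Contrast-to-mass calibration fit
#'
#' @slot slope,intercept coefficients of mass = slope x contrast +
#'   intercept (kDa).
#' @slot sigma residual standard error (kDa; 0 for an exact 2-point fit).
#' @slot standards the standard masses used (kDa).
#' @export
setClass("CalibrationFit",
         representation(slope = "numeric", intercept = "numeric",
                        sigma = "numeric", standards = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (object@slope <= 0)
             msg <- c(msg, "slope must be positive")
           if (length(object@standards) < 2)
             msg <- c(msg, "calibration needs >= 2 standards")
           if (is.null(msg)) TRUE else msg
         })

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit: mass =", format(object@slope), "x contrast +",
      format(object@intercept), "kDa\n")
  cat("  residual SE:", format(object@sigma), "kDa;",
      length(object@standards), "standards (",
      paste(object@standards, collapse = ", "), "kDa)\n")
})

#' Fit a contrast-to-mass calibration line
#'
#' Ordinary least squares of standard mass on landing-event contrast, the
#' per-session calibration against a native protein-standard ladder (66,
#' 146, 242, 480 kDa in the typical setup).
#'
#' @param contrasts observed contrasts, paired with \code{standard_masses}.
#' @param standard_masses known masses (kDa); >= 2 distinct values.
#' @return A \code{CalibrationFit}.
#' @export
fitContrastCalibration <- function(contrasts, standard_masses) {
  if (length(contrasts) != length(standard_masses))
    stop("contrasts and standard_masses must be paired")
  if (length(unique(standard_masses)) < 2)
    stop("calibration needs >= 2 distinct standards")
  if (var(contrasts) == 0) stop("contrasts have zero variance")
  fit <- lm(standard_masses ~ contrasts)
  # an exact (e.g. 2-point) calibration is legitimate here
  s <- suppressWarnings(summary(fit)$sigma)
  new("CalibrationFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      sigma = if (is.finite(s)) s else 0,
      standards = sort(unique(standard_masses)))
}

#' Calibrate a mixed-standard contrast recording
#'
#' When only a pooled recording of the standard ladder is available (no
#' per-standard labels), contrasts are partitioned into as many clusters as
#' there are standards (k-means seeded at evenly spaced quantiles, so the
#' result is deterministic), cluster centers are paired with the sorted
#' standard masses, and the calibration line is fitted through the centers.
#'
#' @param contrasts unlabeled contrasts from a standard-ladder recording.
#' @param standard_masses the known ladder masses (kDa).
#' @return A \code{CalibrationFit}.
#' @export
calibrateFromMixture <- function(contrasts, standard_masses) {
  k <- length(unique(standard_masses))
  if (k < 2) stop("calibration needs >= 2 distinct standards")
  if (length(contrasts) < k) stop("fewer contrasts than standards")
  centers <- stats::quantile(contrasts, probs = seq(0.5, k - 0.5, 1) / k)
  km <- kmeans(contrasts, centers = matrix(centers, ncol = 1))
  mu <- sort(as.numeric(km$centers))
  fitContrastCalibration(mu, sort(unique(standard_masses)))
}

#' Convert contrasts to masses
#'
#' @param fit a \code{CalibrationFit}.
#' @param contrasts landing-event contrasts.
#' @return Masses in kDa.
#' @export
applyCalibration <- function(fit, contrasts) {
  fit@slope * contrasts + fit@intercept
}

#' Molecules per landing event
#'
#' Real-valued molecule count of each landing event, mass divided by the
#' monomer mass (e.g. 50.438 kDa for the chromogranin A primary sequence
#' without his-tag). Non-positive masses are rejected with a warning.
#'
#' @param masses calibrated event masses (kDa).
#' @param monomer_mass monomer mass (kDa, > 0).
#' @return Numeric molecule counts (one per retained event).
#' @export
eventsToCounts <- function(masses, monomer_mass) {
  if (!is.numeric(monomer_mass) || monomer_mass <= 0)
    stop("monomer_mass must be positive")
  bad <- !is.finite(masses) | masses <= 0
  if (any(bad)) {
    warning(sum(bad), " event(s) with non-positive mass rejected")
    masses <- masses[!bad]
  }
  masses / monomer_mass
}

#' Smallest oligomer exceeding a mass threshold
#'
#' The smallest integer number of monomers whose combined mass strictly
#' exceeds a threshold. With the 50.438 kDa chromogranin A monomer and the
#' 500 kDa class boundary this is 10 (10 x 50.438 = 504.38 kDa), which is
#' why the >500 kDa class is annotated as complexes of >10 molecules.
#'
#' @param threshold mass threshold (kDa).
#' @param monomer_mass monomer mass (kDa).
#' @return Integer count.
#' @export
monomersToExceed <- function(threshold, monomer_mass) {
  if (monomer_mass <= 0 || threshold <= 0)
    stop("threshold and monomer_mass must be positive")
  n <- floor(threshold / monomer_mass) + 1L
  as.integer(n)
}

#' Oligomer-class profile of landing events
#'
#' Events are classified by hard mass thresholds first (> \code{xl_threshold}
#' kDa = class XL, else > \code{x_threshold} kDa = class X) and otherwise to
#' the nearest of \{1, 2, 4, 8\} x monomer mass (classes I, II, IV, VIII;
#' ties go to the smaller oligomer). Fractions are normalized by the event
#' count.
#'
#' @param masses calibrated event masses (kDa), non-empty.
#' @param monomer_mass monomer mass (kDa).
#' @param x_threshold lower bound of the large-complex class X (default
#'   500 kDa).
#' @param xl_threshold lower bound of the very-large class XL (default
#'   10000 kDa).
#' @return An \code{OligomerProfile}.
#' @export
oligomerProfile <- function(masses, monomer_mass, x_threshold = 500,
                            xl_threshold = 10000) {
  masses <- masses[is.finite(masses)]
  if (!length(masses)) stop("no landing events")
  if (any(masses <= 0)) {
    warning(sum(masses <= 0), " non-positive event mass(es) rejected")
    masses <- masses[masses > 0]
    if (!length(masses)) stop("no landing events")
  }
  cls <- character(length(masses))
  cls[masses > xl_threshold] <- "XL"
  cls[masses > x_threshold & masses <= xl_threshold] <- "X"
  small <- cls == ""
  if (any(small)) {
    d <- abs(outer(masses[small], .OLIGO_MULTIPLES * monomer_mass, "-"))
    cls[small] <- names(.OLIGO_MULTIPLES)[apply(d, 1, which.min)]
  }
  frac <- setNames(numeric(length(.OLIGO_CLASSES)), .OLIGO_CLASSES)
  t <- table(cls) / length(masses)
  frac[names(t)] <- as.numeric(t)
  new("OligomerProfile", fractions = frac, nEvents = length(masses),
      monomerMass = monomer_mass)
}

#' Oligomer-class profile
#'
#' Fractions of mass-photometry landing events per oligomer class
#' (I = monomer, II = dimer, IV = tetramer, VIII = octamer, X = >500 kDa,
#' XL = >10000 kDa).
#'
#' @slot fractions named fractions over the six classes, summing to 1.
#' @slot nEvents number of events profiled.
#' @slot monomerMass monomer mass used (kDa).
#' @export
setClass("OligomerProfile",
         representation(fractions = "numeric", nEvents = "integer",
                        monomerMass = "numeric"),
         validity = function(object) {
           msg <- NULL
           f <- object@fractions
           if (!identical(names(f), .OLIGO_CLASSES))
             msg <- c(msg, "fractions must be named I,II,IV,VIII,X,XL")
           if (any(f < 0) || any(f > 1))
             msg <- c(msg, "fractions must lie in [0,1]")
           if (abs(sum(f) - 1) > 1e-9)
             msg <- c(msg, "fractions must sum to 1")
           if (object@nEvents <= 0)
             msg <- c(msg, "event count must be positive")
           if (is.null(msg)) TRUE else msg
         })

setMethod("show", "OligomerProfile", function(object) {
  cat("OligomerProfile (", object@nEvents, " events, monomer ",
      object@monomerMass, " kDa)\n", sep = "")
  print(round(object@fractions, 4))
})

#' @rdname oligomerProfile
#' @param x an \code{OligomerProfile}.
#' @export
oligomerFractions <- function(x) x@fractions

#' Compare oligomer-class fractions across conditions
#'
#' Per class, a one-way ANOVA of the replicate fractions across condition
#' groups with Tukey HSD post-hoc pairwise comparisons.
#'
#' @param data long data.frame with columns \code{condition, replicate,
#'   class, fraction}; >= 2 conditions and >= 2 replicates per condition.
#' @return A list with \code{anova} (data.frame \code{class, F, pvalue})
#'   and \code{tukey} (data.frame \code{class, comparison, diff, p_adj}).
#' @export
compareProfiles <- function(data) {
  need <- c("condition", "replicate", "class", "fraction")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(data$condition)) < 2) stop("need >= 2 conditions")
  reps <- table(unique(data[c("condition", "replicate")])$condition)
  if (any(reps < 2)) stop("every condition needs >= 2 replicates")
  out_a <- NULL; out_t <- NULL
  for (cl in unique(data$class)) {
    d <- data[data$class == cl, ]
    d$condition <- factor(d$condition)
    fit <- aov(fraction ~ condition, data = d)
    s <- summary(fit)[[1]]
    out_a <- rbind(out_a, data.frame(class = cl, F = s$`F value`[1],
                                     pvalue = s$`Pr(>F)`[1]))
    tk <- TukeyHSD(fit)$condition
    out_t <- rbind(out_t, data.frame(class = cl,
                                     comparison = rownames(tk),
                                     diff = tk[, "diff"],
                                     p_adj = tk[, "p adj"],
                                     row.names = NULL))
  }
  list(anova = out_a, tukey = out_t)
}

#' Dense-core-granule size distribution
#'
#' Per-clone relative frequency histogram of granule diameters on
#' half-open, lower-inclusive bins \code{[k*w, (k+1)*w)}, the per-clone
#' fraction of granules above a diameter threshold, and an unpaired
#' two-sided t-test on those per-clone fractions between each non-reference
#' genotype and the reference genotype.
#'
#' @param granules data.frame with columns \code{diameter_nm, clone,
#'   genotype}.
#' @param bin_width_nm histogram bin width (default 20 nm).
#' @param threshold_nm large-granule threshold (default 170 nm).
#' @param reference reference genotype (default \code{"WT"} when present,
#'   else the first).
#' @return A list with \code{histogram}, \code{fractions} (per clone) and
#'   \code{tests} (one row per genotype vs reference).
#' @export
granuleSizeDistribution <- function(granules, bin_width_nm = 20,
                                    threshold_nm = 170,
                                    reference = NULL) {
  if (!nrow(granules)) stop("empty granule population")
  if (bin_width_nm <= 0) stop("bin width must be positive")
  if (any(granules$diameter_nm <= 0)) stop("diameters must be positive")
  gts <- unique(granules$genotype)
  if (is.null(reference))
    reference <- if ("WT" %in% gts) "WT" else gts[1]

  bin <- floor(granules$diameter_nm / bin_width_nm)
  hist <- do.call(rbind, lapply(split(granules, granules[c("genotype",
                                                           "clone")],
                                      drop = TRUE), function(d) {
    b <- floor(d$diameter_nm / bin_width_nm)
    t <- table(b)
    data.frame(genotype = d$genotype[1], clone = d$clone[1],
               bin_low = as.integer(names(t)) * bin_width_nm,
               bin_high = (as.integer(names(t)) + 1) * bin_width_nm,
               count = as.integer(t),
               freq = as.integer(t) / nrow(d))
  }))
  rownames(hist) <- NULL

  fr <- do.call(rbind, lapply(split(granules, granules[c("genotype",
                                                         "clone")],
                                    drop = TRUE), function(d)
    data.frame(genotype = d$genotype[1], clone = d$clone[1],
               n = nrow(d),
               fraction_above = mean(d$diameter_nm > threshold_nm))))
  rownames(fr) <- NULL

  tests <- NULL
  for (g in setdiff(gts, reference)) {
    a <- fr$fraction_above[fr$genotype == g]
    b <- fr$fraction_above[fr$genotype == reference]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- t.test(a, b, var.equal = FALSE)
      tests <- rbind(tests, data.frame(
        genotype = g, reference = reference,
        diff = mean(a) - mean(b), pvalue = tt$p.value))
    }
  }
  list(histogram = hist, fractions = fr, tests = tests)
}

#' Normalize vesicular neurotransmitter uptake
#'
#' Per replicate, uptake is expressed per mg protein and the vesicular
#' component is the difference between the untreated and the
#' reserpine-treated (VMAT-blocked) measurement. Percent change of each
#' genotype versus the control is computed from per-replicate ratios to the
#' control mean (mean +/- SEM), and genotypes are compared by one-way ANOVA
#' with Tukey HSD. Replicates missing either member of the reserpine pair
#' are excluded with a warning.
#'
#' @param measurements data.frame with columns \code{cpm, protein_mg,
#'   reserpine} (0/1), \code{genotype, replicate}.
#' @param control control genotype (default \code{"WT"}).
#' @return A list with \code{replicates} (per-replicate vesicular uptake,
#'   cpm/mg), \code{summary} (per genotype: mean, sem, percent_change,
#'   percent_change_sem) and \code{anova} (list with \code{F, pvalue,
#'   tukey}).
#' @export
normalizeUptake <- function(measurements, control = "WT") {
  m <- measurements
  m$permg <- m$cpm / m$protein_mg
  key <- interaction(m$genotype, m$replicate, drop = TRUE)
  reps <- NULL
  for (k in levels(key)) {
    d <- m[key == k, ]
    v0 <- d$permg[d$reserpine == 0]; v1 <- d$permg[d$reserpine == 1]
    if (!length(v0) || !length(v1)) {
      warning("replicate ", k, " lacks a reserpine pair; excluded")
      next
    }
    reps <- rbind(reps, data.frame(genotype = d$genotype[1],
                                   replicate = d$replicate[1],
                                   vesicular = mean(v0) - mean(v1)))
  }
  if (is.null(reps)) stop("no complete reserpine pairs")
  if (!control %in% reps$genotype)
    stop("control genotype ", control, " absent")
  ctrl_mean <- mean(reps$vesicular[reps$genotype == control])
  sem <- function(x) sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(reps, reps$genotype), function(d) {
    pc <- 100 * (d$vesicular / ctrl_mean - 1)
    data.frame(genotype = d$genotype[1], n = nrow(d),
               mean = mean(d$vesicular), sem = sem(d$vesicular),
               percent_change = mean(pc), percent_change_sem = sem(pc))
  }))
  rownames(summ) <- NULL

  anova <- NULL
  if (length(unique(reps$genotype)) >= 2 &&
      all(table(reps$genotype) >= 2)) {
    reps$genotype <- factor(reps$genotype)
    fit <- aov(vesicular ~ genotype, data = reps)
    s <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$genotype
    anova <- list(F = s$`F value`[1], pvalue = s$`Pr(>F)`[1],
                  tukey = data.frame(comparison = rownames(tk),
                                     diff = tk[, "diff"],
                                     p_adj = tk[, "p adj"],
                                     row.names = NULL))
  }
  list(replicates = reps, summary = summ, anova = anova)
}
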