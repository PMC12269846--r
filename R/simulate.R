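# Seeded synthetic-data generators. Each generator draws from its own
# named pseudo-random stream derived from the single integer seed, so
# adding a generator never perturbs another's output, and each one returns
# a machine-readable truth table for recovery tests. Defaults are chosen to
# emulate the statistical structure of the study conditions each pipeline
# stage assumes (divergence and sites per ortholog pair, TMT batch/loading
# structure, oligomer mass mixtures, granule diameter mixtures,
# reserpine-sensitive uptake).

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate ortholog proteome pairs with known site conservation
#'
#' Animal protein sequences are drawn uniformly over the 20 canonical
#' residues; the human ortholog is derived by per-residue substitution
#' (uniform over the other 19 residues, so the chance a substituted
#' Ser/Thr/Tyr stays within \{S,T,Y\} is 2/19) and geometric-length
#' insertions/deletions. Glycosites are placed on animal Ser/Thr/Tyr
#' residues before mutation; indels are kept at least
#' \code{indel_site_buffer} residues away from every site so the
#' ground-truth label depends only on the substitution at the site itself.
#'
#' @param n_proteins number of ortholog pairs.
#' @param mean_length mean protein length (Poisson, floor 30).
#' @param substitution_rate per-residue substitution probability in [0,1].
#' @param indel_rate per-residue probability of starting an indel in [0,1]
#'   (split evenly between insertion and deletion).
#' @param sites_per_protein glycosites requested per protein (capped by the
#'   available S/T/Y residues).
#' @param mean_indel_length mean indel length (geometric).
#' @param indel_site_buffer minimum distance (residues) between an indel
#'   and a glycosite (default 10).
#' @param seed integer seed.
#' @return A list with \code{animal}, \code{human} (\code{AAStringSet}s),
#'   \code{pairs}, \code{sites} (a glycosite observation table) and
#'   \code{truth} (data.frame \code{accession, position, human_position,
#'   human_residue, conserved}).
#' @export
simOrthologProteomes <- function(n_proteins = 200, mean_length = 300,
                                 substitution_rate = 0.05,
                                 indel_rate = 0.01, sites_per_protein = 3,
                                 mean_indel_length = 2,
                                 indel_site_buffer = 10, seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, mean_length >= 30,
            n_proteins >= 1, sites_per_protein >= 0)
  .withStreamSeed(seed, "ortholog", {
    animal <- character(n_proteins); human <- character(n_proteins)
    sites <- NULL; truth <- NULL
    for (i in seq_len(n_proteins)) {
      len <- max(30L, rpois(1, mean_length))
      a <- sample(.AA20, len, replace = TRUE)

      sty <- which(a %in% .STY)
      pos <- sort(sample(sty, min(sites_per_protein, length(sty))))
      near_site <- rep(FALSE, len)
      for (p in pos)
        near_site[max(1, p - indel_site_buffer):
                  min(len, p + indel_site_buffer)] <- TRUE

      # substitutions: uniform over the other 19 residues
      h <- a
      subst <- runif(len) < substitution_rate
      if (any(subst))
        h[subst] <- vapply(a[subst], function(x)
          sample(setdiff(.AA20, x), 1), "")

      # indels away from sites; deletions must not touch buffered windows
      map <- integer(len)   # animal position -> human position (NA deleted)
      out <- character(0)
      j <- 0L; skip <- 0L
      for (p in seq_len(len)) {
        if (skip > 0L) { skip <- skip - 1L; map[p] <- NA_integer_; next }
        evt <- if (!near_site[p]) runif(1) else 1
        if (evt < indel_rate / 2) {               # deletion starting here
          L <- 1L + rgeom(1, 1 / mean_indel_length)
          L <- min(L, len - p + 1L)
          if (!any(near_site[p:(p + L - 1L)])) {
            map[p] <- NA_integer_; skip <- L - 1L; next
          }
          # would clip a site window: fall through, no deletion
        }
        j <- j + 1L; out <- c(out, h[p]); map[p] <- j
        if (evt >= indel_rate / 2 && evt < indel_rate) { # insertion after p
          L <- 1L + rgeom(1, 1 / mean_indel_length)
          out <- c(out, sample(.AA20, L, replace = TRUE))
          j <- j + L
        }
      }
      animal[i] <- paste(a, collapse = "")
      human[i] <- paste(out, collapse = "")

      if (length(pos)) {
        hp <- map[pos]
        hres <- ifelse(is.na(hp), NA_character_,
                       substring(human[i], hp, hp))
        acc <- sprintf("ANI%04d", i)
        sites <- rbind(sites, data.frame(
          accession = acc, taxid = 10090L, position = pos,
          residue = a[pos],
          glycoform = sample(c("HexNAc", "Hex1HexNAc1"), length(pos),
                             replace = TRUE),
          biosource = "synthetic brain",
          psm_count = 1L + rpois(length(pos), 2)))
        truth <- rbind(truth, data.frame(
          accession = acc, position = pos, human_position = hp,
          human_residue = hres,
          conserved = !is.na(hres) & hres %in% .STY))
      }
    }
    acc_a <- sprintf("ANI%04d", seq_len(n_proteins))
    acc_h <- sprintf("HUM%04d", seq_len(n_proteins))
    animal <- AAStringSet(setNames(animal, acc_a))
    human <- AAStringSet(setNames(human, acc_h))
    list(animal = animal, human = human,
         pairs = data.frame(animal_accession = acc_a,
                            human_accession = acc_h, method = "curated"),
         sites = sites, truth = truth)
  })
}

#' Simulate a multi-plex TMT experiment with known fold changes
#'
#' Intensities are base abundance x condition effect x per-plex batch
#' factor x per-channel loading factor x log-normal noise. Channel 1 of
#' every plex is the pooled internal reference (no condition effect); the
#' remaining channels carry condition labels, by default alternating
#' \code{"basal"} / \code{"depolarized"} within each plex.
#'
#' @param n_proteins number of proteins.
#' @param n_plexes number of plexes (batches).
#' @param channels_per_plex channels per plex (>= 4, incl. the reference).
#' @param frac_de fraction of proteins with a true fold change in [0,1].
#' @param log2fc magnitude of the true log2 fold change
#'   (depolarized vs basal; signs alternate across affected proteins).
#' @param batch_sd sd of log batch factors (ignored when
#'   \code{batch_factors} given).
#' @param batch_factors optional explicit multiplicative batch factor per
#'   plex.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @param loading_spread sd of log per-channel loading factors.
#' @param conditions optional list (one per plex) of condition labels for
#'   the non-reference channels.
#' @param seed integer seed.
#' @return A list with \code{experiment} (a \code{\link{TmtExperiment}})
#'   and \code{truth} (data.frame \code{protein, log2fc}).
#' @export
simTmtExperiment <- function(n_proteins = 200, n_plexes = 2,
                             channels_per_plex = 10, frac_de = 0.1,
                             log2fc = 1, batch_sd = 0.5,
                             batch_factors = NULL, noise_cv = 0.1,
                             loading_spread = 0.1, conditions = NULL,
                             seed = 1) {
  if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0,1]")
  if (channels_per_plex < 4)
    stop("need >= 4 channels per plex (incl. the reference)")
  .withStreamSeed(seed, "tmt", {
    prot <- sprintf("PROT%04d", seq_len(n_proteins))
    base <- exp(rnorm(n_proteins, log(1e6), 1))
    true_fc <- numeric(n_proteins)
    n_de <- round(frac_de * n_proteins)
    if (n_de > 0) {
      idx <- sample(n_proteins, n_de)
      true_fc[idx] <- log2fc * rep_len(c(1, -1), n_de)
    }
    if (is.null(batch_factors))
      batch_factors <- exp(rnorm(n_plexes, 0, batch_sd))
    sdlog <- sqrt(log(1 + noise_cv^2))

    mats <- list(); psms <- list(); meta <- NULL
    for (b in seq_len(n_plexes)) {
      plex <- paste0("plex", b)
      cond <- if (!is.null(conditions)) conditions[[b]] else
        rep_len(c("basal", "depolarized"), channels_per_plex - 1)
      labels <- c("reference", cond)
      load <- exp(rnorm(channels_per_plex, 0, loading_spread))
      m <- matrix(0, n_proteins, channels_per_plex,
                  dimnames = list(prot, paste0("ch", seq_len(
                    channels_per_plex))))
      for (ch in seq_len(channels_per_plex)) {
        eff <- if (labels[ch] == "depolarized") 2^true_fc else 1
        noise <- if (sdlog > 0) exp(rnorm(n_proteins, 0, sdlog)) else 1
        m[, ch] <- base * eff * batch_factors[b] * load[ch] * noise
      }
      mats[[plex]] <- m
      psms[[plex]] <- setNames(2L + rpois(n_proteins, 3), prot)
      meta <- rbind(meta, data.frame(
        plex = plex, channel = colnames(m),
        genotype = "WT", condition = labels, clone = "c1",
        is_reference = labels == "reference"))
    }
    list(experiment = TmtExperiment(mats, psms, meta),
         truth = data.frame(protein = prot, log2fc = true_fc),
         batch_factors = batch_factors)
  })
}

#' Simulate mass-photometry landing events
#'
#' Events in classes I/II/IV/VIII are drawn at \{1,2,4,8\} x monomer mass
#' plus Gaussian measurement noise; class X events are uniform on
#' \code{x_range} and class XL uniform on \code{xl_range}.
#'
#' @param weights named class weights over a subset of
#'   \code{c("I","II","IV","VIII","X","XL")}, summing to 1.
#' @param monomer_mass monomer mass (kDa), default the 50.438 kDa
#'   chromogranin A primary sequence.
#' @param noise_sd Gaussian mass noise sd (kDa), >= 0.
#' @param n_events number of events (>= 1).
#' @param x_range,xl_range uniform mass ranges (kDa) for the threshold
#'   classes.
#' @param seed integer seed.
#' @return A list with \code{events} (data.frame \code{event_id, mass_kda,
#'   class_true}) and \code{weights}.
#' @export
simLandingEvents <- function(weights = c(I = 0.45, II = 0.30, IV = 0.15,
                                         VIII = 0.07, X = 0.03),
                             monomer_mass = 50.438, noise_sd = 5,
                             n_events = 2000, x_range = c(600, 5000),
                             xl_range = c(10500, 30000), seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_events < 1) stop("n_events must be >= 1")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (!all(names(weights) %in% .OLIGO_CLASSES))
    stop("weights must be named by oligomer class")
  .withStreamSeed(seed, "landing", {
    cls <- sample(names(weights), n_events, replace = TRUE, prob = weights)
    mass <- numeric(n_events)
    small <- cls %in% names(.OLIGO_MULTIPLES)
    mass[small] <- .OLIGO_MULTIPLES[cls[small]] * monomer_mass +
      rnorm(sum(small), 0, noise_sd)
    mass[cls == "X"] <- runif(sum(cls == "X"), x_range[1], x_range[2])
    mass[cls == "XL"] <- runif(sum(cls == "XL"), xl_range[1], xl_range[2])
    mass <- pmax(mass, 1)
    list(events = data.frame(event_id = seq_len(n_events),
                             mass_kda = mass, class_true = cls),
         weights = weights)
  })
}

#' Simulate dense-core-granule diameter populations
#'
#' Per clone, diameters are drawn from the genotype's log-normal
#' distribution; clone sizes are uniform over \code{n_range} (the per-clone
#' granule counts reported for this kind of TEM quantification span a few
#' hundred).
#'
#' @param genotype_params named list, one \code{c(meanlog=, sdlog=)} per
#'   genotype.
#' @param clones clones per genotype.
#' @param n_range integer range of granules per clone (default 272--633).
#' @param threshold_nm threshold used for the truth table (default 170).
#' @param seed integer seed.
#' @return A list with \code{granules} (data.frame \code{diameter_nm,
#'   clone, genotype}) and \code{truth} (per-genotype theoretical
#'   fraction above the threshold).
#' @export
simGranules <- function(genotype_params = list(
                          WT = c(meanlog = log(130), sdlog = 0.25),
                          SC = c(meanlog = log(150), sdlog = 0.25)),
                        clones = 3, n_range = c(272, 633),
                        threshold_nm = 170, seed = 1) {
  stopifnot(clones >= 1, n_range[1] >= 10)
  .withStreamSeed(seed, "granule", {
    gran <- NULL
    for (g in names(genotype_params)) {
      pars <- genotype_params[[g]]
      for (k in seq_len(clones)) {
        n <- sample(seq(n_range[1], n_range[2]), 1)
        gran <- rbind(gran, data.frame(
          diameter_nm = rlnorm(n, pars["meanlog"], pars["sdlog"]),
          clone = paste0(g, "_c", k), genotype = g))
      }
    }
    truth <- data.frame(
      genotype = names(genotype_params),
      frac_above = vapply(genotype_params, function(p)
        1 - stats::plnorm(threshold_nm, p["meanlog"], p["sdlog"]), 0))
    rownames(truth) <- NULL
    list(granules = gran, truth = truth)
  })
}

#' Simulate noradrenaline-uptake measurements
#'
#' Per replicate and genotype, the untreated per-mg uptake is the vesicular
#' rate (WT rate x genotype multiplier) plus the non-vesicular floor; the
#' reserpine-treated measurement is the floor alone. Log-normal noise with
#' the stated CV multiplies each measurement. The default noise/replicate
#' structure mirrors the scale of reported uptake experiments (a few
#' replicates, SEM of the percent change around 20 points).
#'
#' @param wt_rate WT vesicular uptake (cpm per mg).
#' @param multipliers named vesicular-rate multipliers per genotype
#'   (include the control at 1).
#' @param reserpine_floor non-vesicular background (cpm per mg).
#' @param noise_cv measurement CV.
#' @param n_replicates replicates per genotype.
#' @param protein_mg nominal protein mass per well (mg).
#' @param seed integer seed.
#' @return A list with \code{measurements} (uptake table, see
#'   \code{\link{readUptakeTable}}) and \code{truth} (per-genotype true
#'   percent change of vesicular uptake vs control).
#' @export
simUptake <- function(wt_rate = 1000,
                      multipliers = c(WT = 1, SC = 1.66, dB4GALT7 = 2.06),
                      reserpine_floor = 100, noise_cv = 0.3,
                      n_replicates = 6, protein_mg = 0.5, seed = 1) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  .withStreamSeed(seed, "uptake", {
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noise <- function(n) if (sdlog > 0) exp(rnorm(n, -sdlog^2 / 2, sdlog))
                         else rep(1, n)
    rows <- NULL
    for (g in names(multipliers)) {
      for (r in seq_len(n_replicates)) {
        mg <- protein_mg * runif(2, 0.9, 1.1)
        cpm0 <- (wt_rate * multipliers[[g]] + reserpine_floor) * mg[1] *
          noise(1)
        cpm1 <- reserpine_floor * mg[2] * noise(1)
        rows <- rbind(rows,
          data.frame(cpm = c(cpm0, cpm1), protein_mg = mg,
                     reserpine = c(0L, 1L), genotype = g, replicate = r))
      }
    }
    ctrl <- names(multipliers)[1]
    truth <- data.frame(
      genotype = names(multipliers),
      percent_change = 100 * (unname(multipliers) /
                                multipliers[[ctrl]] - 1))
    list(measurements = rows, truth = truth)
  })
}
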