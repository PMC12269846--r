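# projection of animal sites onto human orthologs and consolidation

makeProteomes <- function(animal_seqs, human_seqs) {
  list(animal = Biostrings::AAStringSet(animal_seqs),
       human = Biostrings::AAStringSet(human_seqs),
       pairs = data.frame(animal_accession = names(animal_seqs),
                          human_accession = names(human_seqs)))
}

test_that("projection applies the Ser/Thr/Tyr rule across identical,
           substituted and cross-identity orthologs", {
  px <- makeProteomes(
    c(A1 = "MKKVTLLAAA", A2 = "MKKVSLLAAA", A3 = "MKKVTLLAAA"),
    c(H1 = "MKKVTLLAAA",   # identical: T stays T
      H2 = "MKKVALLAAA",   # S -> A: lost
      H3 = "MKKVYLLAAA"))  # T -> Y: still a glycosylatable residue
  obs <- rbind(obsRow("A1", 5, "T", taxid = 10090L),
               obsRow("A2", 5, "S", taxid = 10090L),
               obsRow("A3", 5, "T", taxid = 10116L))
  pr <- suppressMessages(projectSites(obs, px$pairs, px$animal, px$human))
  p <- pr$projected
  expect_equal(p$human_position, c(5L, 5L, 5L))
  expect_equal(p$human_residue, c("T", "A", "Y"))
  expect_equal(p$status, c("conserved", "non_conserved", "conserved"))
  expect_equal(nrow(pr$unpaired), 0)
})

test_that("unpaired observations are excluded and reported, and residue
           mismatches are fatal", {
  px <- makeProteomes(c(A1 = "MKKVTLLAAA"), c(H1 = "MKKVTLLAAA"))
  obs <- rbind(obsRow("A1", 5, "T", taxid = 10090L),
               obsRow("ZZ9", 3, "S", taxid = 10090L))
  px$animal <- c(px$animal, Biostrings::AAStringSet(c(ZZ9 = "AASAA")))
  pr <- suppressMessages(projectSites(obs, px$pairs, px$animal, px$human))
  expect_equal(nrow(pr$projected), 1)
  expect_equal(pr$unpaired$accession, "ZZ9")

  bad <- obsRow("A1", 4, "T", taxid = 10090L)  # position 4 is V
  expect_error(
    suppressMessages(projectSites(bad, px$pairs, px$animal, px$human)),
    "does not match")
})

test_that("consolidation merges coincident sites, unions disjoint ones and
           deduplicates converging animal sites", {
  # coincident human + animal site -> one site, evidence both
  hum <- obsRow("P1", 10, "T")
  proj <- projRow("P1", 10, taxid = 10090L)
  ex <- suppressMessages(consolidateSites(hum, proj))
  expect_equal(nrow(ex), 1)
  expect_equal(ex$evidence, "both")
  expect_setequal(strsplit(ex$species, ",")[[1]], c("9606", "10090"))

  # disjoint 2 human + 3 animal -> 5 sites
  hum <- rbind(obsRow("P1", 1, "T"), obsRow("P1", 2, "T"))
  proj <- rbind(projRow("P2", 1), projRow("P2", 2), projRow("P2", 3))
  ex <- suppressMessages(consolidateSites(hum, proj))
  expect_equal(nrow(ex), 5)
  expect_equal(sum(ex$evidence == "human_native"), 2)
  expect_equal(sum(ex$evidence == "animal_conserved"), 3)

  # mouse + rat converging on one human residue -> one site, 2 species
  proj <- rbind(projRow("P3", 7, taxid = 10090L),
                projRow("P3", 7, taxid = 10116L))
  ex <- suppressMessages(consolidateSites(hum[0, ], proj))
  expect_equal(nrow(ex), 1)
  expect_equal(length(strsplit(ex$species, ",")[[1]]), 2)

  # non-conserved projections never enter the expansion
  proj2 <- rbind(projRow("P4", 1),
                 projRow("P5", 2, human_residue = "A",
                         status = "non_conserved"))
  ex <- suppressMessages(consolidateSites(hum[0, ], proj2))
  expect_equal(ex$human_accession, "P4")
})

test_that("conflicting residue letters at one key raise a
           sequence-version error", {
  hum <- obsRow("P1", 10, "T")
  proj <- projRow("P1", 10, human_residue = "S")
  expect_error(suppressMessages(consolidateSites(hum, proj)),
               "disagrees|conflicting")
})

test_that("expanded bookkeeping identities hold and re-consolidation is
           stable on generated data", {
  sim <- simOrthologProteomes(n_proteins = 30, mean_length = 150,
                              substitution_rate = 0.1, indel_rate = 0.02,
                              seed = 21)
  pr <- suppressMessages(projectSites(sim$sites, sim$pairs, sim$animal,
                                      sim$human))
  # a few human-native observations on the same human proteins
  hum <- do.call(rbind, lapply(1:10, function(i) {
    s <- as.character(sim$human[[i]])
    sty <- gregexpr("[STY]", s)[[1]]
    if (sty[1] == -1) return(NULL)
    obsRow(names(sim$human)[i], sty[1],
           substring(s, sty[1], sty[1]))
  }))
  ex <- suppressMessages(consolidateSites(hum, pr$projected))
  expect_equal(nrow(ex),
               sum(ex$evidence == "human_native") +
                 sum(ex$evidence == "animal_conserved") +
                 sum(ex$evidence == "both"))
  ov <- speciesOverlap(ex)
  expect_equal(sum(ov$counts), nrow(ex))      # categories partition sites
  expect_equal(ov$total, nrow(ex))
  # consolidating the same inputs again gives the same table
  ex2 <- suppressMessages(consolidateSites(hum, pr$projected))
  expect_identical(ex, ex2)
})

test_that("species-combination counts equal direct enumeration on a random
           fixture", {
  set.seed(3)
  taxids <- c(9606, 10090, 10116, 9823)
  species <- vapply(1:50, function(i)
    paste(sort(sample(taxids, sample(1:4, 1))), collapse = ","), "")
  ex <- data.frame(human_accession = sprintf("P%02d", 1:50),
                   human_position = 1L, species = species)
  ov <- speciesOverlap(ex)
  names_of <- c("9606" = "human", "10090" = "mouse", "10116" = "rat",
                "9823" = "pig")
  enum <- table(vapply(strsplit(species, ","), function(tx) {
    nm <- names_of[tx]
    paste(intersect(c("human", "mouse", "rat", "pig"), nm),
          collapse = "+")
  }, ""))
  for (cat in names(enum))
    expect_equal(unname(ov$counts[cat]), unname(as.integer(enum[cat])),
                 info = cat)
  # all-singleton fixture: every multi-species category is zero
  ex1 <- data.frame(human_accession = "P1", human_position = 1:4,
                    species = as.character(taxids))
  ov1 <- speciesOverlap(ex1)
  expect_true(all(ov1$counts[grepl("\\+", names(ov1$counts))] == 0))
  expect_equal(ov1$human_animal_overlap, 0)
})

test_that("novelty against a reference compilation is a set difference", {
  ex <- data.frame(human_accession = rep("P1", 10), human_position = 1:10)
  ref_all <- data.frame(accession = "P1", position = 1:10)
  expect_equal(noveltyVsReference(ex, ref_all)$novel, 0)
  ref_none <- data.frame(accession = character(0), position = integer(0))
  expect_equal(noveltyVsReference(ex, ref_none)$novel, 10)
  ref4 <- data.frame(accession = "P1", position = c(2, 4, 6, 8))
  nv <- noveltyVsReference(ex, ref4)
  expect_equal(nv$novel, 6)
  expect_equal(nv$known, 4)
})

test_that("glycosite density counts sites per 100 extracellular residues
           and is shift-invariant", {
  ranges <- data.frame(accession = "P1", start = 1, end = 100)
  ex <- data.frame(human_accession = "P1", human_position = 50L)
  expect_equal(siteDensity("P1", ex, ranges), 1.0)

  ranges <- data.frame(accession = "P1", start = c(1, 201),
                       end = c(200, 350))  # 350 extracellular residues
  ex <- data.frame(human_accession = "P1",
                   human_position = c(10, 20, 30, 40, 210, 220, 230, 400))
  expect_equal(siteDensity("P1", ex, ranges), 100 * 7 / 350)  # 2.0

  off <- 57L  # common shift of ranges and sites changes nothing
  ex2 <- ex; ex2$human_position <- ex2$human_position + off
  r2 <- ranges; r2$start <- r2$start + off; r2$end <- r2$end + off
  expect_equal(siteDensity("P1", ex2, r2), siteDensity("P1", ex, ranges))

  expect_equal(siteDensity("P1", ex[0, ], ranges), 0)
  expect_error(siteDensity("P2", ex, ranges), "no extracellular")
  bad <- data.frame(accession = "P1", start = c(1, 50), end = c(60, 90))
  expect_error(siteDensity("P1", ex, bad), "overlap")
})

test_that("prediction concordance scores flagged sites and reports
           unflagged ones", {
  ex <- data.frame(human_accession = "P1", human_position = 1:4)
  flags <- data.frame(accession = "P1", position = 1:4, predicted = TRUE)
  expect_equal(predictionConcordance(ex, flags)$fraction, 1.0)
  flags$predicted <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(predictionConcordance(ex, flags)$fraction, 0.75)
  none <- flags[0, ]
  pc <- predictionConcordance(ex, none)
  expect_true(is.na(pc$fraction))
  expect_equal(pc$n_unflagged, 4)
})
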