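# TMT filtering, normalization, internal reference scaling and
# differential secretion

toyPlex <- function() {
  # 6 proteins: p3 and p5 have a zero/missing channel, p6 has 1 PSM
  m <- matrix(100, 6, 4, dimnames = list(paste0("p", 1:6),
                                         paste0("ch", 1:4)))
  m["p3", 2] <- 0
  m["p5", 4] <- 0
  psm <- setNames(c(3L, 2L, 3L, 5L, 3L, 1L), rownames(m))
  meta <- data.frame(plex = "plex1", channel = colnames(m),
                     genotype = "WT",
                     condition = c("reference", "basal", "basal",
                                   "depolarized"),
                     clone = "c1",
                     is_reference = c(TRUE, FALSE, FALSE, FALSE))
  TmtExperiment(list(plex1 = m), list(plex1 = psm), meta)
}

test_that("quantifiability filtering keeps complete >=2-PSM proteins and
           logs removals by reason", {
  x <- suppressMessages(filterQuantifiable(toyPlex()))
  expect_setequal(rownames(plexes(x)$plex1), c("p1", "p2", "p4"))
  expect_equal(filterLog(x)$removed_missing_or_zero, 2)
  expect_equal(filterLog(x)$removed_low_psm, 1)
  expect_equal(filterLog(x)$kept, 3)
})

test_that("sample-loading normalization equalizes channel totals, preserves
           the grand total and within-channel ordering", {
  set.seed(5)
  m <- matrix(rlnorm(40, 10, 1), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("ch", 1:4)))
  m[, 2] <- m[, 2] * 2   # overloaded channel
  meta <- data.frame(plex = "plex1", channel = colnames(m),
                     is_reference = c(TRUE, FALSE, FALSE, FALSE))
  x <- TmtExperiment(list(plex1 = m), channelData = meta)
  y <- normalizeSampleLoading(x)
  my <- plexes(y)$plex1
  tot <- colSums(my)
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
  expect_equal(sum(my), sum(m))               # conservation
  expect_equal(order(my[, 2]), order(m[, 2])) # per-channel scalar
  # closed-form factor on the overloaded channel
  expect_equal(my[, 2], m[, 2] * mean(colSums(m)) / sum(m[, 2]))
  # already-equal totals are a fixed point
  z <- normalizeSampleLoading(y)
  expect_equal(plexes(z)$plex1, my)

  m0 <- m; m0[, 3] <- 0
  x0 <- TmtExperiment(list(plex1 = m0), channelData = meta)
  expect_error(normalizeSampleLoading(x0), "zero total")
})

test_that("IRS equalizes per-protein reference summaries with closed-form
           geometric-mean factors", {
  m1 <- matrix(c(100, 200,   # ref channel
                 110, 190,
                 90, 210), 2, 3,
               dimnames = list(c("pA", "pB"), paste0("ch", 1:3)))
  m2 <- m1 * 4   # plex2 reference is 4x plex1's
  meta <- rbind(
    data.frame(plex = "plex1", channel = paste0("ch", 1:3),
               is_reference = c(TRUE, FALSE, FALSE)),
    data.frame(plex = "plex2", channel = paste0("ch", 1:3),
               is_reference = c(TRUE, FALSE, FALSE)))
  x <- TmtExperiment(list(plex1 = m1, plex2 = m2), channelData = meta)
  se <- irsCombine(x)
  f <- S4Vectors::metadata(se)$irs_factors
  expect_equal(unname(f[, "plex1"]), c(2, 2))   # sqrt(4) up
  expect_equal(unname(f[, "plex2"]), c(0.5, 0.5))
  a <- SummarizedExperiment::assay(se)
  expect_equal(a[, "plex1.ch1"], a[, "plex2.ch1"])  # refs equalized

  # identical references: identity transform
  x2 <- TmtExperiment(list(plex1 = m1, plex2 = m1), channelData = meta)
  a2 <- SummarizedExperiment::assay(irsCombine(x2))
  expect_equal(unname(a2[, 1:3]), unname(m1))

  # single plex: identity
  x1 <- TmtExperiment(list(plex1 = m1),
                      channelData = meta[meta$plex == "plex1", ])
  expect_equal(unname(SummarizedExperiment::assay(irsCombine(x1))),
               unname(m1))

  # zero reference intensity cannot be scaled
  m3 <- m2; m3["pB", 1] <- 0
  x3 <- TmtExperiment(list(plex1 = m1, plex2 = m3), channelData = meta)
  expect_warning(se3 <- irsCombine(x3), "zero reference")
  expect_equal(rownames(se3), "pA")
})

test_that("the IRS post-condition holds on generated multi-batch data and
           the batch factor is eliminated", {
  st <- simTmtExperiment(n_proteins = 80, n_plexes = 3,
                         channels_per_plex = 6, batch_factors = c(1, 3, 7),
                         noise_cv = 0.1, loading_spread = 0.1, seed = 31)
  x <- normalizeSampleLoading(suppressMessages(
    filterQuantifiable(st$experiment)))
  # pre-IRS: per-protein reference summaries differ across plexes
  cd <- channelData(x)
  refOf <- function(mats) sapply(names(mats), function(p)
    mats[[p]][, cd$channel[cd$plex == p & cd$is_reference][1]])
  pre <- refOf(plexes(x))
  expect_gt(mean(apply(pre, 1, sd) / rowMeans(pre)), 0)
  se <- suppressMessages(irsCombine(x))
  a <- SummarizedExperiment::assay(se)
  scd <- SummarizedExperiment::colData(se)
  post <- a[, scd$is_reference]
  rel <- apply(post, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(max(rel), 1e-9)
})

test_that("differential secretion recovers known fold changes and behaves
           at the null", {
  # identical groups: log2FC 0, p 1
  m <- matrix(100, 3, 4, dimnames = list(paste0("p", 1:3),
                                         paste0("s", 1:4)))
  res <- differentialSecretion(m, c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))

  # known truth: n=5 vs n=5, true log2FC 2, noise sd 0.1 on log2 scale
  set.seed(8)
  n <- 50
  base <- rnorm(n, 20, 1)
  fc <- rep(c(2, 0), length.out = n)
  la <- base + fc + matrix(rnorm(5 * n, 0, 0.1), n, 5)
  lb <- base + matrix(rnorm(5 * n, 0, 0.1), n, 5)
  mm <- 2^cbind(la, lb)
  colnames(mm) <- paste0("s", 1:10); rownames(mm) <- paste0("p", 1:n)
  res <- differentialSecretion(mm, paste0("s", 1:5), paste0("s", 6:10))
  expect_true(all(abs(res$log2fc - fc) < 0.2))
  expect_true(all(res$padj[fc == 2] < 0.1))

  # Welch engine agrees with stats::t.test
  i <- 1
  tt <- t.test(log2(mm[i, 1:5]), log2(mm[i, 6:10]))
  expect_equal(res$pvalue[i], tt$p.value)
  expect_true(all(res$padj >= res$pvalue))

  # all-null simulation: BH keeps the discovery fraction near alpha
  set.seed(13)
  nullm <- 2^matrix(rnorm(1000 * 8, 20, 0.5), 1000, 8)
  rownames(nullm) <- paste0("p", 1:1000)
  colnames(nullm) <- paste0("s", 1:8)
  resn <- differentialSecretion(nullm, paste0("s", 1:4), paste0("s", 5:8),
                                direction = "both")
  expect_lt(mean(resn$padj < 0.1), 0.1 + 0.03)

  expect_error(differentialSecretion(m, "s1", c("s2", "s3")),
               "at least 2")
})

test_that("responsiveness requires significance and the requested
           direction", {
  res <- data.frame(protein = c("a", "b", "c"),
                    log2fc = c(1, -1, 0.5),
                    pvalue = c(0.001, 0.001, 0.4),
                    padj = c(0.05, 0.05, 0.5))
  expect_equal(classifyResponsive(res, alpha = 0.1), "a")
  expect_setequal(classifyResponsive(res, alpha = 0.1, direction = "both"),
                  c("a", "b"))
  expect_equal(classifyResponsive(res, alpha = 0.1,
                                  direction = "negative"), "b")
  expect_length(classifyResponsive(res, alpha = 0.01), 0)
})

test_that("glycosite annotation counts expanded sites per responsive
           protein and ranks the top carrier first", {
  ex <- data.frame(
    human_accession = c(rep("CHGB", 5), rep("CHGA", 3), "SCG2"),
    human_position = c(1:5, 1:3, 1))
  ann <- annotateGlycosites(c("CHGA", "CHGB", "SCG2", "VGF"), ex)
  expect_equal(ann$n_glycosites[ann$accession == "CHGA"], 3)
  expect_equal(ann$n_glycosites[ann$accession == "VGF"], 0)
  expect_equal(ann$accession[1], "CHGB")   # maximum count ranks first
})
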