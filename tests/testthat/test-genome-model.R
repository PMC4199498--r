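test_that("GFF3 + chrom-sizes loading parses features and checks bounds", {
  gff <- tempfile(fileext = ".gff3")
  sizes <- tempfile(fileext = ".sizes")
  writeLines(c(
    "##gff-version 3",
    "chrA\ttoy\tgene\t101\t200\t.\t+\t.\tID=gA1",
    "chrA\ttoy\tgene\t301\t400\t.\t-\t.\tID=gA2",
    "chrA\ttoy\tcentromere\t441\t560\t.\t.\t.\tID=CENA",
    "chrB\ttoy\tgene\t11\t60\t.\t+\t.\tID=gB1",
    "chrB\ttoy\tgene\t101\t160\t.\t-\t.\tID=gB2",
    "chrB\ttoy\tgene\t201\t260\t.\t+\t.\tID=gB3",
    "chrB\ttoy\tgene\t301\t360\t.\t-\t.\tID=gB4",
    "chrB\ttoy\tcentromere\t401\t520\t.\t.\t.\tID=CENB",
    "chrB\ttoy\tlong_terminal_repeat\t551\t600\t.\t+\t.\tID=ltr1"),
    gff)
  writeLines(c("chrA\t1000", "chrB\t800"), sizes)
  g <- loadAnnotation(gff, sizes)
  expect_s4_class(g, "GenomeAnnotation")
  expect_equal(unname(chromLengths(g)), c(1000L, 800L))
  expect_equal(length(genes(g)), 6L)
  expect_equal(length(features(g, "LTR")), 1L)
  expect_equal(length(centromeres(g)), 2L)

  # feature beyond chromosome length is a hard error naming the feature
  writeLines(c("##gff-version 3",
               "chrA\ttoy\tgene\t900\t1100\t.\t+\t.\tID=gBad"), gff)
  expect_error(loadAnnotation(gff, sizes), "gBad")
  # unknown chromosome is a hard error
  writeLines(c("##gff-version 3",
               "chrZ\ttoy\tgene\t1\t100\t.\t+\t.\tID=gZ"), gff)
  expect_error(loadAnnotation(gff, sizes), "chrZ")
})

test_that("synthetic genome round-trips through write + load unchanged", {
  gm <- makeGenome(simulationConfig(seed = 7, nChromosomes = 3,
                                    minLength = 1e5, maxLength = 2e5))
  g <- gm$genome
  gff <- tempfile(fileext = ".gff3"); sizes <- tempfile(fileext = ".sizes")
  writeAnnotation(g, gff, sizes)
  g2 <- loadAnnotation(gff, sizes)
  expect_identical(chromLengths(g2), chromLengths(g))
  expect_identical(granges(GenomicRanges::sort(centromeres(g2))),
                   granges(GenomicRanges::sort(centromeres(g))))
  f1 <- features(g); f2 <- features(g2)
  expect_identical(granges(f2), granges(f1))
  expect_identical(f2$kind, f1$kind)
  expect_identical(as.character(strand(f2)), as.character(strand(f1)))
})

test_that("centromere windows are centered, truncated and side-resolved", {
  g <- toyGenome(c(chr1 = 500000L), cenMid0 = c(chr1 = 150000L))
  w <- centromereWindow(g, "chr1", 100000)
  expect_equal(start(w), 100001L)   # [100000, 200000) in 0-based terms
  expect_equal(end(w), 200000L)

  gNearEnd <- toyGenome(c(chr1 = 500000L), cenMid0 = c(chr1 = 20000L))
  w2 <- centromereWindow(gNearEnd, "chr1", 100000)
  expect_equal(start(w2), 1L)       # truncated at the chromosome start
  expect_equal(end(w2), 70000L)

  wl <- centromereWindow(g, "chr1", 50000, side = "left")
  wr <- centromereWindow(g, "chr1", 50000, side = "right")
  expect_equal(c(start(wl), end(wl)), c(100001L, 150000L))
  expect_equal(c(start(wr), end(wr)), c(150001L, 200000L))
  expect_error(centromereWindow(g, "chrNope", 1000), "unknown chromosome")
})

test_that("window length matches a per-bp membership oracle on a synthetic genome", {
  gm <- makeGenome(simulationConfig(seed = 11, nChromosomes = 4,
                                    minLength = 1e5, maxLength = 2e5))
  g <- gm$genome
  w <- centromereWindows(g, 25000)
  lens <- chromLengths(g)
  for (ch in names(lens)) {
    expected <- sum(bpMembership(w, ch, lens[[ch]]))
    got <- sum(width(w[as.character(seqnames(w)) == ch]))
    expect_equal(got, expected)
    expect_lte(got, 25000)
  }
  # equality whenever the midpoint is at least width/2 from both ends
  mids <- smcseq:::.cenMid(g)
  for (ch in names(mids))
    if (mids[[ch]] >= 12500 && lens[[ch]] - mids[[ch]] >= 12500)
      expect_equal(sum(width(w[as.character(seqnames(w)) == ch])), 25000L)
})

test_that("arm regions equal whole chromosome minus the three exclusions", {
  g <- toyGenome(c(chr1 = 500000L), cenMid0 = c(chr1 = 250000L))
  arms <- armRegions(g)
  expect_equal(start(arms), c(20001L, 262501L))
  expect_equal(end(arms), c(237500L, 480000L))

  tiny <- toyGenome(c(chr1 = 60000L), cenMid0 = c(chr1 = 30000L))
  expect_equal(length(armRegions(tiny)), 0L)
})

test_that("LTR exclusion spans flanking ORFs and matches a per-bp oracle", {
  len <- 100000L
  genes <- data.frame(
    chrom = "chr1",
    start0 = c(30000L, 40000L, 52000L, 60000L),
    end0   = c(32000L, 42000L, 54000L, 62000L),
    strand = c("+", "-", "+", "-"))
  ltrs <- data.frame(chrom = "chr1",
                     start0 = c(45000L, 70000L), end0 = c(45330L, 70330L))
  g <- toyGenome(c(chr1 = len), cenMid0 = c(chr1 = 90000L),
                 genes = genes, ltrs = ltrs)
  arms <- armRegions(g, pericen = 25000, subtel = 20000)

  # independent per-bp evaluation of the three masking rules
  excl <- logical(len)
  excl[1:20000] <- TRUE; excl[(len - 20000 + 1):len] <- TRUE
  excl[(90000 - 12500 + 1):min(len, 90000 + 12500)] <- TRUE  # truncated
  excl[42001:52000] <- TRUE     # LTR1: upstream ORF end 42000 -> next ORF 52000
  excl[62001:len] <- TRUE       # LTR2: upstream end 62000, no downstream ORF
  expect_equal(sum(width(arms)), sum(!excl))
  expect_equal(bpMembership(arms, "chr1", len), !excl)
})

test_that("arms plus exclusions partition each chromosome exactly once", {
  gm <- makeGenome(simulationConfig(seed = 5, nChromosomes = 3,
                                    minLength = 1.2e5, maxLength = 2e5))
  g <- gm$genome
  arms <- armRegions(g)
  lens <- chromLengths(g)
  cw <- centromereWindows(g, 25000)
  ltrx <- smcseq:::.ltrExclusions(g)
  for (ch in names(lens)) {
    len <- lens[[ch]]
    inArm <- bpMembership(arms, ch, len)
    excl <- bpMembership(cw, ch, len) | bpMembership(ltrx, ch, len)
    excl[1:min(20000, len)] <- TRUE
    excl[max(1, len - 20000 + 1):len] <- TRUE
    expect_identical(inArm, !excl)
  }
})

test_that("region normalization is idempotent", {
  gm <- makeGenome(simulationConfig(seed = 2, nChromosomes = 2,
                                    minLength = 1.2e5, maxLength = 1.5e5))
  arms <- armRegions(gm$genome)
  renorm <- reduce(GenomicRanges::sort(arms, ignore.strand = TRUE))
  expect_identical(granges(renorm), granges(arms))
  expect_equal(sum(width(renorm)), sum(width(arms)))
})

test_that("convergent intergenic regions follow orientation and adjacency", {
  mk <- function(genes) toyGenome(c(chr1 = 1000L), cenMid0 = c(chr1 = 900L),
                                  genes = genes)
  conv <- convergentIntergenicRegions(mk(data.frame(
    chrom = "chr1", start0 = c(10L, 30L), end0 = c(20L, 40L),
    strand = c("+", "-"))))
  expect_equal(c(start(conv), end(conv)), c(21L, 30L))  # [20, 30) gap

  divergent <- convergentIntergenicRegions(mk(data.frame(
    chrom = "chr1", start0 = c(10L, 30L), end0 = c(20L, 40L),
    strand = c("-", "+"))))
  expect_equal(length(divergent), 0L)

  overlapping <- convergentIntergenicRegions(mk(data.frame(
    chrom = "chr1", start0 = c(10L, 15L), end0 = c(20L, 40L),
    strand = c("+", "-"))))
  expect_equal(length(overlapping), 0L)

  # a gene nested in the + gene breaks adjacency
  nested <- convergentIntergenicRegions(mk(data.frame(
    chrom = "chr1", start0 = c(10L, 12L, 60L), end0 = c(50L, 20L, 80L),
    strand = c("+", "+", "-"))))
  expect_equal(length(nested), 0L)
})

test_that("generator's convergent truth list matches the region finder", {
  for (s in c(1, 9, 23)) {
    gm <- makeGenome(simulationConfig(seed = s, nChromosomes = 3,
                                      minLength = 1e5, maxLength = 2e5))
    conv <- convergentIntergenicRegions(gm$genome)
    expect_identical(granges(conv), granges(gm$truth$convergent))
    # regions never overlap a gene body
    expect_false(any(IRanges::overlapsAny(conv, genes(gm$genome),
                                          ignore.strand = TRUE)))
  }
})

test_that("convergent fraction 0 yields no convergent regions", {
  gm <- makeGenome(simulationConfig(seed = 3, nChromosomes = 2,
                                    minLength = 1e5, maxLength = 1.5e5,
                                    convergentFraction = 0))
  expect_equal(length(convergentIntergenicRegions(gm$genome)), 0L)
})

test_that("shortest-arm length is the centromere-to-nearest-telomere distance", {
  g <- toyGenome(c(chr1 = 500000L), cenMid0 = c(chr1 = 150000L))
  expect_equal(shortestArmLength(g, "chr1"), 150000)
  gMeta <- toyGenome(c(chr1 = 400000L), cenMid0 = c(chr1 = 200000L))
  expect_equal(shortestArmLength(gMeta, "chr1"), 200000)
  expect_error(shortestArmLength(g, "chrX"), "unknown chromosome")

  gm <- makeGenome(simulationConfig(seed = 4))
  g16 <- gm$genome
  sa <- shortestArmLengths(g16)
  expect_true(all(sa <= chromLengths(g16)[names(sa)] / 2))
  al <- armLengths(g16)
  expect_equal(length(al), 32L)
  expect_equal(sum(al), sum(as.numeric(chromLengths(g16))))
})
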