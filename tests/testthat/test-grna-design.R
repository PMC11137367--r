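test_that("gcFraction computes (#G + #C)/length and rejects bad input", {
  expect_equal(gcFraction(c("ATAT", "GGCC", "ATGC")), c(0, 1, 0.5))
  expect_error(gcFraction(""), "empty")
  expect_error(gcFraction("ACGN"), "ambiguous")
})

test_that("meltingTemp implements both estimators, monotone in GC", {
  expect_equal(meltingTemp("ACGT", method = "wallace"), 12)  # 2*2 + 4*2
  s50 <- paste(rep("AG", 15), collapse = "")                 # 30-mer, 50% GC
  expect_equal(meltingTemp(s50, method = "gc_formula"),
               81.5 + 0.41 * 50 - 675 / 30)                  # 79.5
  lo <- paste(c(rep("G", 12), rep("A", 18)), collapse = "")  # 40%
  hi <- paste(c(rep("G", 18), rep("A", 12)), collapse = "")  # 60%
  for (m in c("wallace", "gc_formula"))
    expect_lt(meltingTemp(lo, method = m), meltingTemp(hi, method = m))
  ## auto switches estimator at 14 nt
  expect_equal(meltingTemp("ACGTACGTACGT"),
               meltingTemp("ACGTACGTACGT", method = "wallace"))
  expect_error(meltingTemp("ACGT", method = "nope"))
})

test_that("naive scan reproduces the worked toy contig on both strands", {
  g <- Biostrings::DNAStringSet(c(c1 = "GGTTAACCTTAGG"))
  sc <- naiveSpacerScan(g, pam = "TTA", spacerLength = 3L)
  ## forward PAM at 0-based 2 -> spacer (5,8) "ACC"; PAM at 8 rejected
  ## (window truncated); reverse PAM (forward TAA at 3) -> spacer (0,3)
  ## = revcomp("GGT") = "ACC"
  expect_equal(nrow(sc), 2L)
  expect_identical(sc$strand, c("-", "+"))
  expect_identical(sc$spacer_start, c(0L, 5L))
  expect_identical(sc$spacer_end, c(3L, 8L))
  expect_identical(sc$spacer_seq, c("ACC", "ACC"))
  ## no PAM at all
  g2 <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 50), collapse = "")))
  expect_equal(nrow(naiveSpacerScan(g2, "TTA", 3L)), 0L)
})

test_that("enumerateSpacers agrees with the naive window-scan oracle", {
  for (seed in c(3, 8, 21)) {
    gseq <- randomDna(4000, gc = 0.40, seed = seed)
    ## salt in an N-block: windows containing N must be dropped by both
    substr(gseq, 2001, 2010) <- "NNNNNNNNNN"
    genome <- Biostrings::DNAStringSet(setNames(gseq, "ctgA"))
    ss <- enumerateSpacers(genome, designConfig())
    got <- as.data.frame(ss)
    want <- naiveSpacerScan(genome, "TTA", 30L)
    rownames(got) <- rownames(want) <- NULL
    cols <- c("contig", "strand", "spacer_start", "spacer_end", "pam",
              "spacer_seq")
    expect_identical(got[, cols], want[, cols])
    expect_equal(got$gc_fraction, want$gc_fraction, tolerance = 1e-12)
    expect_false(any(grepl("N", got$spacer_seq)))
  }
})

test_that("design is strand-symmetric under genome mirroring", {
  sim <- simulateGenome(smallSimConfig(5, genomeLength = 10000L))
  fwd <- as.data.frame(enumerateSpacers(sim$genome, designConfig()))
  rev <- as.data.frame(enumerateSpacers(mirrorGenome(sim$genome),
                                        designConfig()))
  clen <- Biostrings::width(sim$genome)[1]
  ## mirror the reverse-scan coordinates back onto the forward genome
  rev$ms <- clen - rev$spacer_end
  rev$me <- clen - rev$spacer_start
  rev$mstrand <- ifelse(rev$strand == "+", "-", "+")
  key <- function(a, b, c, d) paste(a, b, c, d, sep = "|")
  expect_setequal(key(rev$ms, rev$me, rev$mstrand, rev$spacer_seq),
                  key(fwd$spacer_start, fwd$spacer_end, fwd$strand,
                      fwd$spacer_seq))
})

test_that("gene assignment uses full containment, overlapping genes get both", {
  gseq <- randomDna(1000, 0.5, 13)
  ## place a PAM so one candidate sits at a known position: TTA at 1-based
  ## 101 -> + spacer (103, 133) 0-based
  substr(gseq, 101, 103) <- "TTA"
  genome <- Biostrings::DNAStringSet(c(c1 = gseq))
  ss <- enumerateSpacers(genome, designConfig())
  df <- as.data.frame(ss)
  i <- which(df$spacer_start == 103 & df$strand == "+")
  expect_length(i, 1L)
  genes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(51, 90, 120), c(500, 400, 128)),
    gene_id = c("gContain", "gAlso", "gPartial"))
  asn <- assignToGenes(ss, genes)
  expect_true(i %in% asn$gContain)           # fully inside
  expect_true(i %in% asn$gAlso)              # overlapping genes: both
  expect_false(i %in% asn$gPartial)          # spacer sticks out: excluded
  ## intergenic candidates are preserved under the reserved key
  expect_setequal(c(unlist(asn[c("gContain", "gAlso", "gPartial")]),
                    asn[["__intergenic__"]]) |> unique() |> sort(),
                  seq_len(length(ss)))
})

test_that("selectManual takes the k lowest-GC candidates with stable ties", {
  sim <- simulateGenome(smallSimConfig(9))
  ss <- enumerateSpacers(sim$genome, designConfig())
  man <- selectManual(ss, sim$genes, designConfig())
  e <- as.data.frame(man)
  asn <- assignToGenes(ss, sim$genes)
  gc <- gcFraction(ss)
  for (g in unique(e$gene_id)) {
    sel <- e[e$gene_id == g, ]
    expect_identical(sel$rank, seq_len(nrow(sel)))
    expect_false(is.unsorted(sel$gc_fraction))
    ## no unselected candidate in the gene beats a selected one
    pool <- gc[asn[[g]]]
    if (length(pool) > nrow(sel))
      expect_lte(max(sel$gc_fraction),
                 min(sort(pool, decreasing = FALSE)[-seq_len(nrow(sel))]) +
                   1e-12)
    ## every selected spacer is fully inside its gene
    gi <- sim$genes[sim$genes$gene_id == g]
    expect_true(all(sel$spacer_start >= GenomicRanges::start(gi) - 1L &
                      sel$spacer_end <= GenomicRanges::end(gi)))
  }
  ## every gene with at least one candidate appears
  withCand <- names(asn)[vapply(asn, length, 1L) > 0]
  expect_setequal(unique(e$gene_id),
                  setdiff(withCand, "__intergenic__"))
})

test_that("selectManual emits short manuals with a warning", {
  ## one gene containing exactly one candidate
  gseq <- randomDna(200, 0.25, 4)
  gseq <- gsub("TTA", "GCA", gseq, fixed = TRUE)
  gseq <- gsub("TAA", "GCA", gseq, fixed = TRUE)   # scrub chance PAMs
  substr(gseq, 61, 63) <- "TTA"
  genome <- Biostrings::DNAStringSet(c(c1 = gseq))
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(50, 150),
                                  gene_id = "gOnly")
  ss <- enumerateSpacers(genome, designConfig())
  expect_warning(man <- selectManual(ss, genes, designConfig()),
                 "fewer than 3")
  e <- as.data.frame(man)
  expect_identical(e$rank, seq_len(nrow(e)))
  expect_lt(nrow(e), 3L)
})

test_that("efficiency classification follows the GC rule with low boundary", {
  expect_identical(classifyEfficiency(c(0.40, 0.53, 0.50)),
                   c("high", "low", "low"))
  expect_error(classifyEfficiency(1.2), "\\[0, 1\\]")
})

test_that("truncation keeps the PAM-proximal bases and recomputes scores", {
  sim <- simulateGenome(smallSimConfig(2, genomeLength = 15000L))
  ss <- enumerateSpacers(sim$genome, designConfig())
  tr <- truncateSpacers(ss, 27L)
  expect_equal(tr@spacerLength, 27L)
  expect_identical(S4Vectors::mcols(spacerRanges(tr))$spacer_seq,
                   substr(S4Vectors::mcols(spacerRanges(ss))$spacer_seq,
                          1, 27))
  ## coordinates: '+' keeps its start (PAM side), '-' keeps its end
  og <- spacerRanges(ss); ng <- spacerRanges(tr)
  plus <- as.character(GenomicRanges::strand(og)) == "+"
  expect_equal(GenomicRanges::start(ng)[plus],
               GenomicRanges::start(og)[plus])
  expect_equal(GenomicRanges::end(ng)[!plus], GenomicRanges::end(og)[!plus])
  ## the genomic slice still matches the stored guide sequence
  gseq <- as.character(sim$genome[[1]])
  k <- which(!plus)[1]
  fwd <- substr(gseq, GenomicRanges::start(ng)[k], GenomicRanges::end(ng)[k])
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd))),
    S4Vectors::mcols(ng)$spacer_seq[k])
  ## recomputed GC/Tm agree with direct computation
  expect_equal(gcFraction(tr), gcFraction(S4Vectors::mcols(ng)$spacer_seq))
  ## dropping G/C-only tails can never raise the Wallace Tm
  gcTail <- which(substr(S4Vectors::mcols(og)$spacer_seq, 28, 30) %in%
                    c("GGG", "GGC", "GCG", "CGG", "GCC", "CGC", "CCG",
                      "CCC"))
  if (length(gcTail)) {
    before <- meltingTemp(S4Vectors::mcols(og)$spacer_seq[gcTail],
                          method = "wallace")
    after <- meltingTemp(S4Vectors::mcols(ng)$spacer_seq[gcTail],
                         method = "wallace")
    expect_true(all(after <= before))
  }
  expect_error(truncateSpacers(ss, 26L), ">= 27")
  expect_error(designConfig(spacerLength = 26L), ">= 27")
})
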