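## Independent oracles used across the suite. These deliberately avoid the
## package's production code paths (no Biostrings matching, no Rcpp).

## Needleman-Wunsch identity oracle: plain R dynamic program, match +1 /
## mismatch 0 / linear gap -1, maximizing matches among score-optimal
## alignments; identity = matches / shorter length.
nwIdentityOracle <- function(a, b) {
  A <- strsplit(a, NULL)[[1]]
  B <- strsplit(b, NULL)[[1]]
  m <- length(A); n <- length(B)
  S <- matrix(0L, m + 1, n + 1)
  M <- matrix(0L, m + 1, n + 1)
  S[, 1] <- -(0:m)
  S[1, ] <- -(0:n)
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    mt <- as.integer(A[i - 1] == B[j - 1])
    sd <- S[i - 1, j - 1] + mt
    su <- S[i - 1, j] - 1L
    sl <- S[i, j - 1] - 1L
    S[i, j] <- max(sd, su, sl)
    mm <- -1L
    if (sd == S[i, j]) mm <- max(mm, M[i - 1, j - 1] + mt)
    if (su == S[i, j]) mm <- max(mm, M[i - 1, j])
    if (sl == S[i, j]) mm <- max(mm, M[i, j - 1])
    M[i, j] <- mm
  }
  M[m + 1, n + 1] / min(m, n)
}

## Exhaustive split-point oracle for junction reads on a small reference:
## enumerates every (split, prefix placement, suffix placement) with exact
## full-length matches of both parts and a positive gap, and returns the
## leftmost-normalized deletion plus the number of shift-equivalent
## placements (= microhomology + 1).
splitOracle <- function(read, ref, minFlank = 30L) {
  n <- nchar(read)
  rlen <- nchar(ref)
  found <- list()
  for (s in minFlank:(n - minFlank)) {
    pre <- substr(read, 1, s)
    suf <- substr(read, s + 1, n)
    pos <- seq_len(rlen - s + 1)
    pL <- pos[substring(ref, pos, pos + s - 1) == pre]
    pos2 <- seq_len(rlen - (n - s) + 1)
    pR <- pos2[substring(ref, pos2, pos2 + (n - s) - 1) == suf]
    for (i in pL) for (j in pR) {
      ds0 <- (i - 1) + s          # 0-based half-open deletion
      de0 <- j - 1
      if (de0 > ds0)
        found[[length(found) + 1]] <- c(ds0, de0)
    }
  }
  if (!length(found)) return(NULL)
  fm <- unique(do.call(rbind, found))
  fm <- fm[order(fm[, 1]), , drop = FALSE]
  list(del_start = fm[1, 1], del_end = fm[1, 2],
       n_placements = nrow(fm))
}

## Random DNA of given length/GC under local seed.
randomDna <- function(n, gc = 0.5, seed = 1) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

randomProtein <- function(n, seed = 1) {
  withr::with_seed(seed, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]], n, replace = TRUE),
    collapse = ""))
}

## Junction-read fixture on a 600 bp reference: true deletion (200, 450)
## (0-based half-open), 60 bp flanks, engineered microhomology of exactly
## `m` bases ("ACG..." copied to both junction sides) and no chance
## shift ambiguity beyond it.
makeJunctionFixture <- function(seed = 42, m = 0) {
  v <- strsplit(randomDna(600, 0.5, seed), NULL)[[1]]
  ds <- 200; de <- 450                      # 0-based
  alphabet <- c("A", "C", "G", "T")
  if (m > 0) {
    motif <- rep_len(c("A", "C", "G"), m)
    v[ds + seq_len(m)] <- motif             # bases at ds.. (1-based ds+1)
    v[de + seq_len(m)] <- motif
  }
  ## forbid accidental extension of the shift window on either side
  if (v[ds] == v[de]) v[de] <- setdiff(alphabet, c(v[de - 1], v[ds]))[1]
  if (v[ds + m + 1] == v[de + m + 1])
    v[de + m + 1] <- setdiff(alphabet, c(v[ds + m + 1], v[de + m + 2]))[1]
  ref <- paste(v, collapse = "")
  read <- paste0(substr(ref, 200 - 60 + 1, 200), substr(ref, 451, 450 + 60))
  list(ref = Biostrings::DNAStringSet(c(chr = ref)), read = read,
       del_start = ds, del_end = de, m = m)
}

## Mirror a design problem: reverse-complement the genome and flip the
## features, used for the strand-symmetry property.
mirrorGenome <- function(genome) {
  Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(genome)), names(genome)))
}

mirrorFeatures <- function(genes, genome) {
  clen <- Biostrings::width(genome)[match(
    as.character(GenomicRanges::seqnames(genes)), names(genome))]
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(clen - GenomicRanges::end(genes) + 1L,
                     clen - GenomicRanges::start(genes) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                    "-", "+"),
    gene_id = genes$gene_id,
    seqlengths = setNames(Biostrings::width(genome), names(genome)))
}

## Small feasible simulation setup used by several tests.
smallSimConfig <- function(seed, genomeLength = 20000L)
  simConfig(seed = seed, genomeLength = genomeLength, nGenes = 10L,
            geneLengthRange = c(300L, 1200L))

## Compare a GuideManual against the naive oracle manual, full precision.
expectManualEqualsOracle <- function(manual, oracleManual) {
  md <- as.data.frame(manual)
  cols <- c("gene_id", "rank", "contig", "strand", "spacer_start",
            "spacer_end", "pam", "spacer_seq")
  rownames(md) <- NULL
  om <- oracleManual
  rownames(om) <- NULL
  expect_identical(md[, cols], om[, cols])
  expect_equal(md$gc_fraction, om$gc_fraction, tolerance = 1e-12)
}
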