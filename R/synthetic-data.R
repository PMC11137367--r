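## Seeded synthetic data with recorded truth: genomes with planted TTA PAM
## sites and non-overlapping gene annotations, Cas3-style deletion events
## with NHEJ junction reads (microhomology / insertion), and protein
## homolog families planted at target identities. Everything is
## deterministic under a fixed seed; the caller's RNG state is restored on
## exit.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters
#'
#' Defaults emulate the study system at bench scale: a single-contig
#' bacterial genome at 44% GC (the target organism's genome-wide GC is in
#' the mid-forties), ~50 genes of 0.3-2.4 kb, one extra planted TTA PAM
#' per kb (TTA also occurs abundantly by chance at this GC), Cas3-style
#' bidirectional deletion extents drawn log-uniform between 1 kb and
#' 210 kb (observed deletions span ~1 kb to ~209 kb) truncated at contig
#' bounds, NHEJ junctions carrying 1-5 bp microhomology with probability
#' 0.3 or a 1-5 bp non-templated insertion with probability 0.1, and
#' 400 bp Sanger-like junction flanks.
#'
#' @param seed integer RNG seed; identical seed gives byte-identical
#'   output.
#' @param genomeLength contig length in bases.
#' @param gcBackground background GC fraction in (0, 1).
#' @param nGenes number of non-overlapping genes to place.
#' @param geneLengthRange integer range of gene lengths (bases).
#' @param pamPlantRate planted TTA sites per kb (in addition to chance
#'   occurrences).
#' @param spacerLength,perGene guide-design parameters recorded in the
#'   truth manual (see [designConfig()]).
#' @param extentRange range of the log-uniform per-side deletion extents
#'   (bases).
#' @param microhomologyProb,microhomologyLenRange probability and length
#'   range of junction microhomology.
#' @param insertionProb,insertionLenRange probability and length range of
#'   non-templated junction insertions (drawn only when no microhomology).
#' @param flankReadLen bases of reference sequence on each side of the
#'   junction in a simulated read.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, genomeLength = 100000L,
                      gcBackground = 0.44, nGenes = 50L,
                      geneLengthRange = c(300L, 2400L), pamPlantRate = 1,
                      spacerLength = 30L, perGene = 3L,
                      extentRange = c(1e3, 210e3),
                      microhomologyProb = 0.3,
                      microhomologyLenRange = c(1L, 5L),
                      insertionProb = 0.1, insertionLenRange = c(1L, 5L),
                      flankReadLen = 400L) {
  stopifnot(genomeLength > 0, gcBackground > 0, gcBackground < 1,
            nGenes >= 0, all(geneLengthRange > 0),
            geneLengthRange[1] <= geneLengthRange[2], pamPlantRate >= 0,
            all(extentRange > 0), extentRange[1] <= extentRange[2],
            microhomologyProb >= 0, microhomologyProb <= 1,
            insertionProb >= 0, insertionProb <= 1,
            all(microhomologyLenRange >= 1), all(insertionLenRange >= 1),
            flankReadLen >= 1)
  structure(list(seed = as.integer(seed),
                 genomeLength = as.integer(genomeLength),
                 gcBackground = gcBackground, nGenes = as.integer(nGenes),
                 geneLengthRange = as.integer(geneLengthRange),
                 pamPlantRate = pamPlantRate,
                 spacerLength = as.integer(spacerLength),
                 perGene = as.integer(perGene),
                 extentRange = extentRange,
                 microhomologyProb = microhomologyProb,
                 microhomologyLenRange = as.integer(microhomologyLenRange),
                 insertionProb = insertionProb,
                 insertionLenRange = as.integer(insertionLenRange),
                 flankReadLen = as.integer(flankReadLen)),
            class = "SimConfig")
}

.revcompChar <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), NULL),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Naive reference spacer scan
#'
#' A deliberately simple, position-by-position substring scan for
#' PAM-anchored spacers on both strands, independent of the production
#' scanner in [enumerateSpacers()] (no pattern-matching library, no range
#' machinery). Used by the simulator to record design truth and by the
#' test suite as the exhaustive oracle.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param pam PAM string (default `"TTA"`).
#' @param spacerLength spacer length (default 30).
#' @return data.frame with columns `contig`, `strand`, `spacer_start`
#'   (0-based half-open), `spacer_end`, `pam`, `spacer_seq`,
#'   `gc_fraction`, sorted by (contig, start, strand `+` first).
#' @export
naiveSpacerScan <- function(genome, pam = "TTA", spacerLength = 30L) {
  L <- as.integer(spacerLength)
  w <- nchar(pam)
  rcpam <- .revcompChar(pam)
  rows <- list()
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    n <- nchar(s)
    if (n < w) next
    win <- substring(s, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
    ## forward PAM at p (1-based): spacer on [p+w, p+w+L-1]
    a <- which(win == pam) + w
    a <- a[a + L - 1L <= n]
    if (length(a)) {
      sq <- substring(s, a, a + L - 1L)
      ok <- !grepl("[^ACGT]", sq)
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(genome)[ci], strand = "+",
          spacer_start = a[ok] - 1L, spacer_end = a[ok] + L - 1L,
          pam = pam, spacer_seq = sq[ok], stringsAsFactors = FALSE)
    }
    ## reverse-strand PAM shows as revcomp(pam) at q: spacer on
    ## forward interval [q-L, q-1], reported reverse-complemented
    q <- which(win == rcpam)
    q <- q[q - L >= 1L]
    if (length(q)) {
      fwd <- substring(s, q - L, q - 1L)
      ok <- !grepl("[^ACGT]", fwd)
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(genome)[ci], strand = "-",
          spacer_start = q[ok] - L - 1L, spacer_end = q[ok] - 1L,
          pam = pam, spacer_seq = .revcompChar(fwd[ok]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), strand = character(),
                      spacer_start = integer(), spacer_end = integer(),
                      pam = character(), spacer_seq = character(),
                      gc_fraction = numeric()))
  df <- do.call(rbind, rows)
  df$gc_fraction <- vapply(df$spacer_seq, function(x)
    sum(strsplit(x, NULL)[[1]] %in% c("G", "C")) / nchar(x), numeric(1),
    USE.NAMES = FALSE)
  df[order(match(df$contig, names(genome)), df$spacer_start,
           match(df$strand, c("+", "-")), method = "radix"), ,
     drop = FALSE]
}

#' Naive reference guide manual
#'
#' Exhaustive scan-and-sort oracle for the per-gene lowest-GC selection:
#' [naiveSpacerScan()] plus a direct containment filter and a
#' (GC, start, strand) sort, independent of [selectManual()].
#'
#' @inheritParams naiveSpacerScan
#' @param genes `GRanges` with a `gene_id` column (1-based closed).
#' @param perGene guides to keep per gene (default 3).
#' @return data.frame with the manual columns (coordinates 0-based
#'   half-open), genes in coordinate order.
#' @export
naiveGuideManual <- function(genome, genes, pam = "TTA",
                             spacerLength = 30L, perGene = 3L) {
  sc <- naiveSpacerScan(genome, pam, spacerLength)
  ord <- order(as.integer(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  rows <- list()
  for (gi in ord) {
    g0 <- GenomicRanges::start(genes)[gi] - 1L      # 0-based half-open
    g1 <- GenomicRanges::end(genes)[gi]
    cid <- as.character(GenomicRanges::seqnames(genes))[gi]
    sub <- sc[sc$contig == cid & sc$spacer_start >= g0 &
                sc$spacer_end <= g1, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$gc_fraction, sub$spacer_start,
                     match(sub$strand, c("+", "-")), method = "radix"), ,
               drop = FALSE]
    sub <- utils::head(sub, perGene)
    sub$gene_id <- genes$gene_id[gi]
    sub$rank <- seq_len(nrow(sub))
    rows[[length(rows) + 1L]] <- sub
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), rank = integer(),
                      contig = character(), strand = character(),
                      spacer_start = integer(), spacer_end = integer(),
                      pam = character(), spacer_seq = character(),
                      gc_fraction = numeric()))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[, c("gene_id", "rank", "contig", "strand", "spacer_start",
         "spacer_end", "pam", "spacer_seq", "gc_fraction")]
}

#' Simulate a genome with planted PAMs and gene annotations
#'
#' Bases are i.i.d. at the background GC; TTA PAM sites are planted at
#' known, non-overlapping positions on top of chance occurrences;
#' non-overlapping genes are placed with recorded coordinates. The truth
#' list records every planted PAM and the per-gene lowest-GC guide
#' candidates computed by [naiveGuideManual()] at generation time.
#'
#' @param config a [simConfig()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param contigName name of the single contig (default `"ctg1"`).
#' @return list with `genome` (DNAStringSet), `genes` (GRanges), `truth`
#'   (list with `pam_sites`, 0-based positions, and `manual`, the naive
#'   oracle manual), and `config`.
#' @export
simulateGenome <- function(config = simConfig(), seed = config$seed,
                           contigName = "ctg1") {
  glen <- config$genomeLength
  .withSeed(seed, {
    gc <- config$gcBackground
    v <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    ## plant PAMs at mutually non-overlapping positions
    nPlant <- max(0L, as.integer(round(config$pamPlantRate * glen / 1e3)))
    pamPos <- integer()
    if (nPlant > 0L && glen >= 3L) {
      cand <- sort(sample.int(glen - 2L, min(nPlant * 2L, glen - 2L)))
      keep <- !logical(length(cand))
      last <- -10L
      for (i in seq_along(cand)) {
        if (cand[i] - last < 3L) keep[i] <- FALSE else last <- cand[i]
      }
      pamPos <- utils::head(cand[keep], nPlant)
      for (p in pamPos) { v[p] <- "T"; v[p + 1L] <- "T"; v[p + 2L] <- "A" }
    }
    ## non-overlapping genes via stick-breaking of the leftover space
    genes <- GenomicRanges::GRanges(
      seqlengths = setNames(glen, contigName))
    if (config$nGenes > 0L) {
      lens <- sample(seq(config$geneLengthRange[1],
                         config$geneLengthRange[2]),
                     config$nGenes, replace = TRUE)
      if (sum(lens) > 0.85 * glen)
        stop("infeasible gene packing: ", config$nGenes, " genes of total ",
             sum(lens), " bp exceed 85% of a ", glen, " bp genome",
             call. = FALSE)
      leftover <- glen - sum(lens)
      offs <- sort(floor(runif(config$nGenes, 0, leftover + 1)))
      starts <- offs + cumsum(c(0L, lens[-length(lens)])) + 1L
      genes <- GenomicRanges::GRanges(
        contigName, IRanges::IRanges(starts, starts + lens - 1L),
        strand = sample(c("+", "-"), config$nGenes, replace = TRUE),
        gene_id = sprintf("SYNG_%05d", 10L * seq_len(config$nGenes)),
        locus_tag = sprintf("SYNG_%05d", 10L * seq_len(config$nGenes)),
        type = "gene", seqlengths = setNames(glen, contigName))
    }
    genome <- Biostrings::DNAStringSet(
      setNames(paste(v, collapse = ""), contigName))
    manual <- naiveGuideManual(genome, genes, pam = "TTA",
                               spacerLength = config$spacerLength,
                               perGene = config$perGene)
    list(genome = genome, genes = genes,
         truth = list(pam_sites = data.frame(contig = contigName,
                                             pam_start = pamPos - 1L),
                      manual = manual),
         config = config)
  })
}

#' Draw one Cas3-style deletion interval around a cut site
#'
#' The degradation extends from the cut site in both directions; each
#' extent is drawn log-uniform over `extentRange` (or fixed via
#' `leftExtent`/`rightExtent`) and clipped at the contig bounds, so the
#' interval always contains the cut site.
#'
#' @param genomeLength contig length (bases).
#' @param cutSite cut position, 0-based.
#' @param config a [simConfig()].
#' @param leftExtent,rightExtent optional fixed extents (bases).
#' @return integer vector `c(del_start, del_end)`, 0-based half-open.
#' @export
simulateDeletionEvent <- function(genomeLength, cutSite,
                                  config = simConfig(),
                                  leftExtent = NULL, rightExtent = NULL) {
  stopifnot(cutSite >= 0, cutSite <= genomeLength)
  drawExt <- function() {
    r <- config$extentRange
    round(exp(runif(1, log(r[1]), log(r[2]))))
  }
  le <- if (is.null(leftExtent)) drawExt() else leftExtent
  re <- if (is.null(rightExtent)) drawExt() else rightExtent
  c(del_start = max(0L, as.integer(cutSite - le)),
    del_end = min(as.integer(genomeLength), as.integer(cutSite + re)))
}

#' Simulate junction reads for Cas3-style deletions
#'
#' Draws `nReads` deletion events on the first contig, plants junction
#' microhomology by locally editing the reference (the `m` bases just
#' right of the deletion end are made identical to the `m` bases just
#' right of the deletion start) or a non-templated insertion, and emits
#' one junction read per event from the final edited genome:
#' `flank` bases left of the junction + insertion + `flank` bases right.
#'
#' Truth records are *realized*, not merely planted: after all edits,
#' each event's breakpoints are leftmost-normalized against the final
#' genome and the microhomology length is recomputed by direct base
#' comparison, so chance homology at random junctions is accounted for.
#' Events whose flanks would run off the contig are skipped and counted.
#'
#' @param genome a named [Biostrings::DNAStringSet]; the first contig is
#'   used.
#' @param config a [simConfig()].
#' @param nReads number of junction reads to generate.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `reads` (DNAStringSet), `truth` (data.frame:
#'   `read_id`, `contig`, `del_start`, `del_end` 0-based half-open
#'   leftmost-normalized, `length_bp`, `microhomology_len`,
#'   `insertion_seq`, `event_type`), `genome` (the edited DNAStringSet to
#'   call against) and `n_skipped`.
#' @export
simulateJunctionReads <- function(genome, config = simConfig(),
                                  nReads = 200L, seed = config$seed) {
  stopifnot(is(genome, "DNAStringSet"), length(genome) >= 1L)
  cname <- names(genome)[1]
  v <- strsplit(as.character(genome[[1]]), NULL)[[1]]
  glen <- length(v)
  flank <- config$flankReadLen
  margin <- flank + 10L
  .withSeed(seed, {
    events <- list()
    attempts <- 0L
    skipped <- 0L
    while (length(events) < nReads && attempts < 50L * nReads) {
      attempts <- attempts + 1L
      cut <- sample.int(glen - 1L, 1L)
      de <- simulateDeletionEvent(glen, cut, config)
      ds0 <- de[[1]]; de0 <- de[[2]]
      if (ds0 < margin || de0 + margin > glen || de0 - ds0 < 20L) {
        skipped <- skipped + 1L
        next
      }
      u <- runif(1)
      if (u < config$microhomologyProb) {
        m <- sample(seq(config$microhomologyLenRange[1],
                        config$microhomologyLenRange[2]), 1L)
        ins <- ""
        type <- "microhomology"
      } else if (u < config$microhomologyProb + config$insertionProb) {
        m <- 0L
        ilen <- sample(seq(config$insertionLenRange[1],
                           config$insertionLenRange[2]), 1L)
        ins <- paste(sample(c("A", "C", "G", "T"), ilen, replace = TRUE),
                     collapse = "")
        type <- "insertion"
      } else {
        m <- 0L; ins <- ""; type <- "clean"
      }
      events[[length(events) + 1L]] <-
        list(ds0 = ds0, de0 = de0, m = m, ins = ins, type = type)
    }
    if (length(events) < nReads)
      warning("only ", length(events), " of ", nReads,
              " requested events could be placed", call. = FALSE)
    ## pass 2: apply all microhomology edits to the master sequence
    for (ev in events) {
      if (ev$m > 0L) {
        idx <- seq_len(ev$m)
        v[ev$de0 + idx] <- v[ev$ds0 + idx]
      }
    }
    s2 <- paste(v, collapse = "")
    ## pass 3: realized truth on the final genome + reads from it
    reads <- character(length(events))
    rows <- vector("list", length(events))
    for (k in seq_along(events)) {
      ev <- events[[k]]
      reads[k] <- paste0(substr(s2, ev$ds0 - flank + 1L, ev$ds0), ev$ins,
                         substr(s2, ev$de0 + 1L, ev$de0 + flank))
      ## realized truth: canonical representation of the junction.
      ## Insertion bases matching the adjacent deleted reference are
      ## absorbed into the flanks (the minimal-insertion form a split
      ## aligner reports); junctions without an insertion are
      ## leftmost-normalized with the realized microhomology window.
      ds0 <- ev$ds0; de0 <- ev$de0; ins <- ev$ins
      while (nchar(ins) && ds0 + 1L < de0 &&
             v[ds0 + 1L] == substr(ins, 1L, 1L)) {
        ds0 <- ds0 + 1L; ins <- substring(ins, 2L)
      }
      while (nchar(ins) && ds0 < de0 - 1L &&
             v[de0] == substr(ins, nchar(ins), nchar(ins))) {
        de0 <- de0 - 1L; ins <- substr(ins, 1L, nchar(ins) - 1L)
      }
      mReal <- 0L
      if (!nchar(ins)) {
        while (ds0 > 0L && v[ds0] == v[de0]) { # leftmost normalization
          ds0 <- ds0 - 1L; de0 <- de0 - 1L
        }
        while (de0 + mReal < glen && mReal < (de0 - ds0) &&
               v[ds0 + mReal + 1L] == v[de0 + mReal + 1L])
          mReal <- mReal + 1L
      }
      type <- if (nchar(ins)) "insertion" else
        if (mReal > 0L) "microhomology" else "clean"
      rows[[k]] <- data.frame(
        read_id = sprintf("read_%04d", k), contig = cname,
        del_start = ds0, del_end = de0, length_bp = de0 - ds0,
        microhomology_len = mReal, insertion_seq = ins,
        event_type = type, planted_type = ev$type,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    list(reads = Biostrings::DNAStringSet(setNames(reads, truth$read_id)),
         truth = truth,
         genome = Biostrings::DNAStringSet(setNames(s2, cname)),
         n_skipped = skipped)
  })
}

#' Plant a protein homolog family at target identities
#'
#' Each family member is the seed with point substitutions (uniform over
#' the 19 alternative residues) at distinct positions, chosen so the
#' realized [globalIdentity()] to the seed lies within +/- 0.02 of its
#' target; realized identities are recorded as truth.
#'
#' @param seedProtein a single amino-acid sequence.
#' @param n family size.
#' @param targetIdentities numeric vector in (0, 1], recycled to `n`.
#' @param seed RNG seed.
#' @param prefix id prefix for the generated members.
#' @return list with `proteins` (AAStringSet) and `realized` (data.frame:
#'   `id`, `target`, `realized`).
#' @export
plantHomologFamily <- function(seedProtein, n, targetIdentities,
                               seed = 1L, prefix = "hom") {
  if (is(seedProtein, "XStringSet")) seedProtein <-
      as.character(seedProtein)[1]
  seedProtein <- as.character(seedProtein)
  L <- nchar(seedProtein)
  stopifnot(n >= 1, all(targetIdentities > 0), all(targetIdentities <= 1))
  if (L < 25L)
    stop("seed too short to hit identity targets within +/- 0.02; ",
         "use a longer seed (>= 25 aa)", call. = FALSE)
  targets <- rep_len(targetIdentities, n)
  sv <- strsplit(seedProtein, NULL)[[1]]
  .withSeed(seed, {
    seqs <- character(n)
    realized <- numeric(n)
    for (i in seq_len(n)) {
      k <- max(0L, min(L, as.integer(round((1 - targets[i]) * L))))
      ok <- FALSE
      for (iter in seq_len(60L)) {
        w <- sv
        if (k > 0L) {
          pos <- sample.int(L, k)
          for (p in pos) w[p] <- sample(setdiff(.AA20, sv[p]), 1L)
        }
        cand <- paste(w, collapse = "")
        idn <- globalIdentity(seedProtein, cand)
        if (abs(idn - targets[i]) <= 0.02) {
          seqs[i] <- cand; realized[i] <- idn; ok <- TRUE; break
        }
        k <- max(0L, min(L, k + if (idn > targets[i]) 1L else -1L))
      }
      if (!ok)
        stop("could not reach target identity ", targets[i],
             " within +/- 0.02; use a longer seed", call. = FALSE)
    }
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    list(proteins = Biostrings::AAStringSet(setNames(seqs, ids)),
         realized = data.frame(id = ids, target = targets,
                               realized = realized,
                               stringsAsFactors = FALSE))
  })
}
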