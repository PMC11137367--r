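## Deletion breakpoint inference from Sanger junction reads, interval
## aggregation, and genome-coverage / non-essential-gene statistics.
##
## Calling model: a junction read is a prefix that aligns upstream of the
## deletion and a suffix that aligns downstream on the same contig and
## orientation. Both flanks are anchored by an exact seed (the first /
## last minFlank bases, allowing up to maxMismatchRate * minFlank seed
## mismatches) and extended by exact matching. With prefix support `a` at
## genome offset pL and suffix support `b` ending at genome offset pE
## (read length n):
##   overlap = a + b - n
##   overlap >= 0: microhomology m = overlap; the junction is
##     shift-equivalent over m + 1 placements and is reported leftmost:
##     del_start = pL + (n - b), del_end = pE - b   (0-based half-open)
##   overlap < 0: an insertion of the unaligned middle bases;
##     del_start = pL + a, del_end = pE - b
## Exact (first-mismatch) extension keeps the microhomology arithmetic
## well-defined; a mismatch-tolerant extension could drift past the
## junction through chance matches.

## exact forward extension of read[from..] against contig[at..] (1-based)
.extendRight <- function(read, contig, from, at) {
  maxlen <- min(nchar(read) - from + 1L, nchar(contig) - at + 1L)
  if (maxlen <= 0L) return(0L)
  r <- charToRaw(substr(read, from, from + maxlen - 1L))
  g <- charToRaw(substr(contig, at, at + maxlen - 1L))
  neq <- which(r != g)
  if (length(neq)) neq[1L] - 1L else maxlen
}

## exact backward extension of read[..upto] against contig[..at] (1-based)
.extendLeft <- function(read, contig, upto, at) {
  maxlen <- min(upto, at)
  if (maxlen <= 0L) return(0L)
  r <- charToRaw(substr(read, upto - maxlen + 1L, upto))
  g <- charToRaw(substr(contig, at - maxlen + 1L, at))
  neq <- which(rev(r != g))
  if (length(neq)) neq[1L] - 1L else maxlen
}

.seedHits <- function(seed, genome, maxMismatch) {
  hits <- list()
  for (ci in seq_along(genome)) {
    m <- Biostrings::matchPattern(seed, genome[[ci]],
                                  max.mismatch = maxMismatch,
                                  with.indels = FALSE)
    if (length(m)) {
      mm <- vapply(seq_along(m), function(k) {
        sum(charToRaw(as.character(m[[k]])) != charToRaw(seed))
      }, integer(1))
      hits[[length(hits) + 1L]] <- data.frame(
        contig = ci, start = BiocGenerics::start(m), mismatch = mm)
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[h$mismatch == min(h$mismatch), , drop = FALSE]
  utils::head(h[order(h$contig, h$start), , drop = FALSE], 8L)
}

.inferOne <- function(read, genome, minFlank, maxMismatchRate) {
  n <- nchar(read)
  if (n < 2L * minFlank)
    return(list(status = "unmapped_flank",
                reason = "read shorter than 2*minFlank"))
  mm <- floor(maxMismatchRate * minFlank)
  left <- .seedHits(substr(read, 1L, minFlank), genome, mm)
  right <- .seedHits(substr(read, n - minFlank + 1L, n), genome, mm)
  if (is.null(left) || is.null(right))
    return(list(status = "unmapped_flank",
                reason = "no confident anchor for a flank"))
  if (!length(intersect(left$contig, right$contig)))
    return(list(status = "translocation_like",
                reason = "flank anchors on different contigs"))
  best <- NULL
  for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
    if (left$contig[i] != right$contig[j]) next
    cseq <- as.character(genome[[left$contig[i]]])
    pL <- left$start[i]                       # 1-based genome pos of read[1]
    a <- .extendRight(read, cseq, 1L, pL)
    pEnd <- right$start[j] + minFlank - 1L    # 1-based pos of read[n]
    b <- .extendLeft(read, cseq, n, pEnd)
    if (a < minFlank || b < minFlank) next
    ov <- a + b - n
    if (ov >= 0L) {                           # microhomology (possibly 0)
      ds0 <- (pL - 1L) + (n - b)              # 0-based half-open
      de0 <- pEnd - b
      ins <- ""
      mh <- ov
    } else {                                  # junction insertion
      ds0 <- (pL - 1L) + a
      de0 <- pEnd - b
      ins <- substr(read, a + 1L, n - b)
      mh <- 0L
    }
    if (de0 <= ds0) next                      # no gap between anchors
    cand <- list(contig = left$contig[i], ds0 = ds0, de0 = de0,
                 mh = as.integer(mh), ins = ins, a = a, b = b)
    if (is.null(best) || (a + b) > (best$a + best$b) ||
        ((a + b) == (best$a + best$b) && ds0 < best$ds0))
      best <- cand
  }
  if (is.null(best)) {
    ## anchors found but no positive gap on any same-contig pairing
    return(list(status = "no_deletion",
                reason = "read is contiguous reference (no deletion)"))
  }
  c(list(status = "ok"), best)
}

#' Infer a deletion from a single junction read
#'
#' See the calling model in the package vignette: both read flanks are
#' anchored on the same contig, the optimal split is computed, and the
#' breakpoints are reported leftmost-normalized with explicit
#' microhomology (`microhomology_len`) or junction insertion
#' (`insertion_seq`). Failure modes raise classed errors:
#' `grnakit_unmapped_flank` (no confident anchor),
#' `grnakit_translocation_like` (anchors on different contigs; such events
#' are reported, not called), `grnakit_no_deletion` (the read is a
#' contiguous reference slice).
#'
#' @param read a character string, [Biostrings::DNAString], or
#'   length-1 `DNAStringSet`.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param minFlank minimum aligned bases supporting each side (default 30).
#' @param maxMismatchRate tolerated mismatch rate in the seed anchors
#'   (default 0.05, Sanger-quality).
#' @param readId read identifier stored in the call.
#' @return a single-call [DeletionCallSet].
#' @export
inferDeletion <- function(read, genome, minFlank = 30L,
                          maxMismatchRate = 0.05, readId = "read1") {
  if (is(read, "XStringSet")) read <- as.character(read)[1]
  if (is(read, "XString")) read <- as.character(read)
  res <- .inferOne(read, genome, as.integer(minFlank), maxMismatchRate)
  if (res$status != "ok") {
    cls <- paste0("grnakit_", sub("_like", "_like", res$status))
    stop(structure(class = c(cls, "error", "condition"),
                   list(message = paste0(res$reason, " [", readId, "]"),
                        call = NULL)))
  }
  gr <- GenomicRanges::GRanges(
    names(genome)[res$contig],
    IRanges::IRanges(res$ds0 + 1L, res$de0),
    read_id = readId, microhomology_len = res$mh,
    insertion_seq = res$ins, left_flank_len = res$a,
    right_flank_len = res$b)
  methods::new("DeletionCallSet", calls = gr)
}

#' Infer deletions from a set of junction reads
#'
#' Applies the single-read caller to every read; reads that fail (unmapped
#' flank, translocation-like anchors, or no deletion) are skipped and
#' collected, with reasons, in `metadata(deletionRanges(x))$skipped`.
#'
#' @param reads a named [Biostrings::DNAStringSet] (e.g. from
#'   [readGenome()] on a junction-read FASTA).
#' @inheritParams inferDeletion
#' @return a [DeletionCallSet].
#' @export
inferDeletions <- function(reads, genome, minFlank = 30L,
                           maxMismatchRate = 0.05) {
  stopifnot(is(reads, "XStringSet"))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  calls <- list()
  skip <- list()
  rch <- as.character(reads)
  for (k in seq_along(rch)) {
    res <- .inferOne(rch[k], genome, as.integer(minFlank), maxMismatchRate)
    if (res$status == "ok") {
      calls[[length(calls) + 1L]] <- data.frame(
        contig = names(genome)[res$contig], ds0 = res$ds0, de0 = res$de0,
        mh = res$mh, ins = res$ins, a = res$a, b = res$b, id = ids[k],
        stringsAsFactors = FALSE)
    } else {
      skip[[length(skip) + 1L]] <- data.frame(
        read_id = ids[k], status = res$status, reason = res$reason,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls)) {
    df <- do.call(rbind, calls)
    gr <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$ds0 + 1L, df$de0),
      read_id = df$id, microhomology_len = df$mh, insertion_seq = df$ins,
      left_flank_len = df$a, right_flank_len = df$b)
  } else {
    gr <- GenomicRanges::GRanges(
      read_id = character(), microhomology_len = integer(),
      insertion_seq = character(), left_flank_len = integer(),
      right_flank_len = integer())
  }
  S4Vectors::metadata(gr)$skipped <- if (length(skip))
    do.call(rbind, skip) else
    data.frame(read_id = character(), status = character(),
               reason = character())
  methods::new("DeletionCallSet", calls = gr)
}

#' Union of deletion intervals
#'
#' Standard per-contig interval union (sorted, disjoint). The union length
#' is invariant to call order and to splitting intervals into adjacent
#' pieces.
#'
#' @param x a [DeletionCallSet] or `GRanges`.
#' @return a reduced `GRanges` (strand ignored).
#' @export
unionIntervals <- function(x) {
  gr <- if (is(x, "DeletionCallSet")) deletionRanges(x) else x
  stopifnot(is(gr, "GRanges"))
  GenomicRanges::reduce(GenomicRanges::granges(gr), ignore.strand = TRUE)
}

#' Genome coverage of a deletion set
#'
#' @param x a [DeletionCallSet], `GRanges`, or a plain number of deleted
#'   bases (e.g. a published cumulative deletion length).
#' @param genome a [Biostrings::DNAStringSet], or the total genome length
#'   in bases (e.g. [PTG_GENOME_LENGTH_BP]).
#' @return list with `union_bp`, `union_kb` (3 decimals), `percent`
#'   (2 decimals) and `percent_rounded` (nearest integer, the style used
#'   when quoting "x% of the total genomic length").
#' @examples
#' genomeCoverageStats(468145, 3.9e6)
#' @export
genomeCoverageStats <- function(x, genome) {
  total <- if (is.numeric(genome)) genome else genomeLength(genome)
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("genome must be a DNAStringSet or a positive total length",
         call. = FALSE)
  union_bp <- if (is.numeric(x)) {
    if (length(x) != 1L || x < 0) stop("x must be a single >= 0 length",
                                       call. = FALSE)
    x
  } else sum(as.numeric(GenomicRanges::width(unionIntervals(x))))
  pct <- 100 * union_bp / total
  list(union_bp = union_bp,
       union_kb = round(union_bp / 1e3, 3),
       percent = round(pct, 2),
       percent_rounded = as.integer(round(pct)))
}

#' Operationally non-essential genes
#'
#' Genes whose interval is fully contained in the union of recovered
#' deletion intervals: deletion of the whole gene was survivable, so the
#' gene is operationally dispensable. Partial overlap is deliberately not
#' enough (a partially degraded gene is not proven dispensable).
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param intervals a [DeletionCallSet] or `GRanges` of deletions.
#' @return character vector of gene ids, sorted by genomic coordinate.
#' @export
callNonessential <- function(genes, intervals) {
  u <- unionIntervals(intervals)
  ov <- GenomicRanges::findOverlaps(genes, u, type = "within",
                                    ignore.strand = TRUE)
  hit <- genes[unique(S4Vectors::queryHits(ov))]
  hit <- hit[order(as.integer(GenomicRanges::seqnames(hit)),
                   GenomicRanges::start(hit))]
  hit$gene_id
}

#' Per-guide maximum deletion report
#'
#' Summarizes deletion lengths per guide: number of calls and the
#' min/median/max of the length spectrum, in kb with 3 decimals.
#'
#' @param calls a [DeletionCallSet].
#' @param guide character/factor of guide identifiers, one per call.
#' @return data.frame with columns `guide_id`, `n_calls`, `min_kb`,
#'   `median_kb`, `max_kb`.
#' @export
maxDeletionReport <- function(calls, guide) {
  gr <- deletionRanges(calls)
  stopifnot(length(guide) == length(gr), length(gr) > 0L)
  w <- GenomicRanges::width(gr)
  sp <- split(w, as.character(guide))
  out <- data.frame(
    guide_id = names(sp),
    n_calls = vapply(sp, length, integer(1)),
    min_kb = vapply(sp, function(v) round(min(v) / 1e3, 3), numeric(1)),
    median_kb = vapply(sp, function(v) round(stats::median(v) / 1e3, 3),
                       numeric(1)),
    max_kb = vapply(sp, function(v) round(max(v) / 1e3, 3), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$guide_id), , drop = FALSE]
}
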