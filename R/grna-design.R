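## Guide design: genome-wide PAM-anchored spacer enumeration, GC/Tm
## scoring, and the per-gene lowest-GC selection manual.
##
## PAM orientation follows the type I convention: the PAM lies immediately
## 5' of the protospacer on the protospacer's own strand. For a plus-strand
## candidate the PAM therefore sits just left of the spacer interval on the
## forward strand; for a minus-strand candidate the forward genome shows
## the reverse complement of the PAM just right of the interval.

.checkDnaVec <- function(x, what = "sequence") {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L)
    stop(what, " must be a non-empty character vector or XStringSet",
         call. = FALSE)
  if (any(!nzchar(x)))
    stop("empty ", what, call. = FALSE)
  if (any(grepl("[^ACGT]", x)))
    stop(what, " contains ambiguous or non-DNA characters ",
         "(only A/C/G/T allowed)", call. = FALSE)
  x
}

.gcFracChar <- function(x) {
  x <- .checkDnaVec(x)
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x),
                                   letters = c("G", "C"))
  unname(rowSums(f) / nchar(x))
}

#' @rdname gcFraction
#' @export
setMethod("gcFraction", "character", function(x) .gcFracChar(x))

#' @rdname gcFraction
#' @export
setMethod("gcFraction", "DNAStringSet",
          function(x) .gcFracChar(as.character(x)))

.meltingTempChar <- function(x, method) {
  x <- .checkDnaVec(x)
  method <- match.arg(method, c("auto", "gc_formula", "wallace"))
  n <- nchar(x)
  gc <- .gcFracChar(x)
  wallace <- 2 * (n - gc * n) + 4 * (gc * n)
  gcform <- 81.5 + 0.41 * (100 * gc) - 675 / n
  switch(method,
         wallace = wallace,
         gc_formula = gcform,
         auto = ifelse(n >= 14L, gcform, wallace))
}

#' @rdname meltingTemp
#' @export
setMethod("meltingTemp", "character",
          function(x, method = c("auto", "gc_formula", "wallace"))
            .meltingTempChar(x, method))

#' @rdname meltingTemp
#' @export
setMethod("meltingTemp", "DNAStringSet",
          function(x, method = c("auto", "gc_formula", "wallace"))
            .meltingTempChar(as.character(x), method))

#' Design parameters
#'
#' @param pamSet character vector of PAM sequences to scan for (default
#'   `"TTA"`, the type I-B PAM used for guide selection).
#' @param spacerLength protospacer length in nt; must be >= 27, the
#'   validated floor below which cleavage is not guaranteed. Default 30.
#' @param perGene number of guides to select per gene (default 3).
#' @param gcHighCutoff GC fraction below which a guide is classed
#'   high-efficiency (default 0.50; a guide exactly at the cutoff is
#'   classed low).
#' @param tmMethod Tm estimator passed to [meltingTemp()]. Tm is reported
#'   for information only and never used for ranking.
#' @return a list of class `DesignConfig`.
#' @export
designConfig <- function(pamSet = "TTA", spacerLength = 30L, perGene = 3L,
                         gcHighCutoff = 0.50,
                         tmMethod = c("auto", "gc_formula", "wallace")) {
  pamSet <- toupper(pamSet)
  if (length(pamSet) == 0L || any(grepl("[^ACGT]", pamSet)) ||
      any(!nzchar(pamSet)))
    stop("pamSet must be one or more A/C/G/T strings", call. = FALSE)
  spacerLength <- as.integer(spacerLength)
  if (is.na(spacerLength) || spacerLength < 27L)
    stop("spacerLength must be >= 27 (spacers shorter than 27 nt are not ",
         "validated to retain cleavage activity)", call. = FALSE)
  perGene <- as.integer(perGene)
  if (is.na(perGene) || perGene < 1L)
    stop("perGene must be >= 1", call. = FALSE)
  if (!is.numeric(gcHighCutoff) || gcHighCutoff <= 0 || gcHighCutoff > 1)
    stop("gcHighCutoff must be in (0, 1]", call. = FALSE)
  structure(list(pamSet = pamSet, spacerLength = spacerLength,
                 perGene = perGene, gcHighCutoff = gcHighCutoff,
                 tmMethod = match.arg(tmMethod)),
            class = "DesignConfig")
}

#' Enumerate PAM-anchored spacer candidates genome-wide
#'
#' Scans both strands of every contig for every PAM in the configuration.
#' Each PAM occurrence with a full-length spacer window immediately 3' of
#' the PAM (on the PAM's strand) inside the contig yields exactly one
#' candidate; windows containing `N` (or any non-ACGT base) are dropped.
#' Candidates are sorted by (contig, forward-strand start, strand with `+`
#' first).
#'
#' @param genome a named [Biostrings::DNAStringSet] ([readGenome()]).
#' @param config a [designConfig()].
#' @return a [SpacerSet].
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "GGTTAACCTTAGG"))
#' # (toy contig; real spacers need >= 27 nt windows)
#' @export
enumerateSpacers <- function(genome, config = designConfig()) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  L <- config$spacerLength
  rows <- list()
  for (ci in seq_along(genome)) {
    cname <- names(genome)[ci]
    cseq <- as.character(genome[[ci]])
    clen <- nchar(cseq)
    for (pam in config$pamSet) {
      w <- nchar(pam)
      ## plus strand: PAM at [p, p+w-1], spacer at [p+w, p+w+L-1]
      hits <- Biostrings::matchPattern(pam, genome[[ci]])
      p <- BiocGenerics::start(hits)
      s <- p + w
      keep <- (s + L - 1L) <= clen
      if (any(keep)) {
        s <- s[keep]
        seqs <- substring(cseq, s, s + L - 1L)
        ok <- !grepl("[^ACGT]", seqs)
        if (any(ok))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = cname, strand = "+", start = s[ok],
            end = s[ok] + L - 1L, pam = pam, spacer_seq = seqs[ok],
            stringsAsFactors = FALSE)
      }
      ## minus strand: forward genome shows revcomp(PAM) at [q, q+w-1];
      ## the protospacer occupies forward interval [q-L, q-1]
      rcpam <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(pam)))
      hits <- Biostrings::matchPattern(rcpam, genome[[ci]])
      q <- BiocGenerics::start(hits)
      s <- q - L
      keep <- s >= 1L
      if (any(keep)) {
        s <- s[keep]
        fwd <- substring(cseq, s, s + L - 1L)
        ok <- !grepl("[^ACGT]", fwd)
        if (any(ok)) {
          gseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(fwd[ok])))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = cname, strand = "-", start = s[ok],
            end = s[ok] + L - 1L, pam = pam, spacer_seq = gseq,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    ord <- order(match(df$contig, names(genome)), df$start,
                 match(df$strand, c("+", "-")), method = "radix")
    df <- df[ord, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$start, df$end), strand = df$strand,
      pam = df$pam, spacer_seq = df$spacer_seq,
      gc_fraction = gcFraction(df$spacer_seq),
      tm_c = meltingTemp(df$spacer_seq, config$tmMethod),
      seqlengths = setNames(Biostrings::width(genome), names(genome)))
  } else {
    gr <- GenomicRanges::GRanges(
      seqlengths = setNames(Biostrings::width(genome), names(genome)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      pam = character(), spacer_seq = character(),
      gc_fraction = numeric(), tm_c = numeric())
  }
  methods::new("SpacerSet", ranges = gr, spacerLength = L,
               pamSet = config$pamSet)
}

#' Assign spacer candidates to genes by containment
#'
#' A candidate is assigned to every gene whose interval fully contains the
#' spacer interval (a cut anywhere within a gene disrupts it, so
#' containment is required, not mere overlap; candidates inside two
#' overlapping genes are assigned to both). Candidates contained in no
#' gene are collected under the reserved key `"__intergenic__"`.
#'
#' @param spacers a [SpacerSet].
#' @param genes `GRanges` with a `gene_id` metadata column
#'   ([readGeneFeatures()]).
#' @return named list mapping `gene_id` (plus `"__intergenic__"`) to
#'   integer indices into `spacers`.
#' @export
assignToGenes <- function(spacers, genes) {
  stopifnot(is(spacers, "SpacerSet"), is(genes, "GRanges"))
  ov <- GenomicRanges::findOverlaps(spacerRanges(spacers), genes,
                                    type = "within", ignore.strand = TRUE)
  ids <- genes$gene_id
  out <- split(S4Vectors::queryHits(ov),
               ids[S4Vectors::subjectHits(ov)])
  out <- lapply(out, function(i) sort(unique(i)))
  inter <- setdiff(seq_len(length(spacers)),
                   unique(S4Vectors::queryHits(ov)))
  out[["__intergenic__"]] <- inter
  out
}

#' Classify guide efficiency from spacer GC content
#'
#' Encodes the observed categorical rule: guides with spacer GC content
#' below the cutoff (default 50%) fall in the high-efficiency class;
#' guides at or above the cutoff in the low-efficiency class. The boundary
#' value is classed low because the high class is defined strictly below
#' the cutoff.
#'
#' @param gc numeric vector of GC fractions in `[0, 1]`.
#' @param gcHighCutoff GC fraction cutoff (default 0.50).
#' @return character vector, `"high"` or `"low"`.
#' @examples
#' classifyEfficiency(c(0.40, 0.50, 0.53))  # high, low, low
#' @export
classifyEfficiency <- function(gc, gcHighCutoff = 0.50) {
  if (!is.numeric(gc) || any(is.na(gc)) || any(gc < 0 | gc > 1))
    stop("gc must be numeric in [0, 1]", call. = FALSE)
  ifelse(gc < gcHighCutoff, "high", "low")
}

#' Select the per-gene lowest-GC guides (the selection manual)
#'
#' For every gene with at least one fully contained candidate, selects the
#' `perGene` candidates with the smallest spacer GC fraction. Ties are
#' broken deterministically by (GC, forward-strand start, `+` before `-`).
#' Genes with fewer than `perGene` candidates contribute all of them (a
#' warning lists such genes). Each entry carries the categorical
#' efficiency class from [classifyEfficiency()].
#'
#' @param spacers a [SpacerSet] ([enumerateSpacers()]).
#' @param genes `GRanges` with a `gene_id` column.
#' @param config a [designConfig()].
#' @return a [GuideManual].
#' @export
selectManual <- function(spacers, genes, config = designConfig()) {
  asn <- assignToGenes(spacers, genes)
  asn[["__intergenic__"]] <- NULL
  ## keep genes in coordinate order
  ord <- order(as.integer(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  geneIds <- genes$gene_id[ord]
  geneIds <- geneIds[geneIds %in% names(asn)]
  gr <- spacerRanges(spacers)
  gc <- S4Vectors::mcols(gr)$gc_fraction
  st <- GenomicRanges::start(gr)
  sd <- match(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  short <- character()
  rows <- vector("list", length(geneIds))
  for (i in seq_along(geneIds)) {
    idx <- asn[[geneIds[i]]]
    o <- idx[order(gc[idx], st[idx], sd[idx], method = "radix")]
    if (length(o) < config$perGene) short <- c(short, geneIds[i])
    o <- utils::head(o, config$perGene)
    sub <- gr[o]
    rows[[i]] <- S4Vectors::DataFrame(
      gene_id = geneIds[i], rank = seq_along(o),
      contig = as.character(GenomicRanges::seqnames(sub)),
      strand = as.character(GenomicRanges::strand(sub)),
      spacer_start = GenomicRanges::start(sub) - 1L,
      spacer_end = GenomicRanges::end(sub),
      pam = S4Vectors::mcols(sub)$pam,
      spacer_seq = S4Vectors::mcols(sub)$spacer_seq,
      gc_fraction = S4Vectors::mcols(sub)$gc_fraction,
      tm_c = S4Vectors::mcols(sub)$tm_c,
      efficiency_class = classifyEfficiency(
        S4Vectors::mcols(sub)$gc_fraction, config$gcHighCutoff))
  }
  if (length(short))
    warning("gene(s) with fewer than ", config$perGene, " candidates: ",
            paste(short, collapse = ", "), call. = FALSE)
  ent <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(gene_id = character(), rank = integer(),
                         contig = character(), strand = character(),
                         spacer_start = integer(), spacer_end = integer(),
                         pam = character(), spacer_seq = character(),
                         gc_fraction = numeric(), tm_c = numeric(),
                         efficiency_class = character())
  methods::new("GuideManual", entries = ent)
}

#' Truncate spacers at the PAM-distal end
#'
#' Shortens every candidate to `newLength` nt by trimming the PAM-distal
#' end (the 3' end of the guide-oriented spacer), keeping the PAM-proximal
#' bases; coordinates, GC fraction and Tm are recomputed. Truncation below
#' 27 nt is refused: shorter spacers are not validated to retain cleavage
#' activity.
#'
#' @param spacers a [SpacerSet].
#' @param newLength target length, `27 <= newLength <= spacerLength`.
#' @param tmMethod Tm estimator for the recomputed values.
#' @return a [SpacerSet] of the new length.
#' @export
truncateSpacers <- function(spacers, newLength,
                            tmMethod = c("auto", "gc_formula", "wallace")) {
  stopifnot(is(spacers, "SpacerSet"))
  newLength <- as.integer(newLength)
  if (is.na(newLength) || newLength < 27L)
    stop("newLength must be >= 27: spacers shorter than 27 nt are not ",
         "validated to retain cleavage function", call. = FALSE)
  if (newLength > spacers@spacerLength)
    stop("newLength exceeds current spacer length", call. = FALSE)
  gr <- spacerRanges(spacers)
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  newStart <- ifelse(plus, GenomicRanges::start(gr),
                     GenomicRanges::end(gr) - newLength + 1L)
  newEnd <- newStart + newLength - 1L
  ## guide-oriented sequence always starts PAM-proximal
  newSeq <- substr(S4Vectors::mcols(gr)$spacer_seq, 1L, newLength)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::IRanges(newStart, newEnd),
    strand = GenomicRanges::strand(gr),
    pam = S4Vectors::mcols(gr)$pam, spacer_seq = newSeq,
    gc_fraction = gcFraction(newSeq),
    tm_c = meltingTemp(newSeq, match.arg(tmMethod)),
    seqinfo = GenomeInfoDb::seqinfo(gr))
  methods::new("SpacerSet", ranges = out, spacerLength = newLength,
               pamSet = spacers@pamSet)
}

#' One-call guide design
#'
#' [enumerateSpacers()] followed by [selectManual()].
#'
#' @inheritParams selectManual
#' @param genome a named [Biostrings::DNAStringSet].
#' @return a [GuideManual].
#' @export
designGuides <- function(genome, genes, config = designConfig()) {
  selectManual(enumerateSpacers(genome, config), genes, config)
}
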