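## Accessors, subsetting, coercion and show methods for the S4 containers.

#' @rdname SpacerSet-class
#' @export
setMethod("spacerRanges", "SpacerSet", function(x) x@ranges)

#' @rdname SpacerSet-class
#' @export
setMethod("spacerSeqs", "SpacerSet", function(x)
  Biostrings::DNAStringSet(S4Vectors::mcols(x@ranges)$spacer_seq))

#' @rdname SpacerSet-class
#' @export
setMethod("gcFraction", "SpacerSet", function(x)
  S4Vectors::mcols(x@ranges)$gc_fraction)

#' @rdname SpacerSet-class
#' @param method ignored for `SpacerSet` (values are precomputed).
#' @export
setMethod("meltingTemp", "SpacerSet", function(x, method)
  S4Vectors::mcols(x@ranges)$tm_c)

#' @rdname SpacerSet-class
#' @export
setMethod("length", "SpacerSet", function(x) length(x@ranges))

#' @rdname SpacerSet-class
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "SpacerSet", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x, ranges = x@ranges[i])
})

#' @rdname SpacerSet-class
#' @export
setMethod("show", "SpacerSet", function(object) {
  cat("SpacerSet with", length(object), "candidate(s)\n")
  cat("  spacer length:", object@spacerLength, "nt; PAM set:",
      paste(object@pamSet, collapse = ","), "\n")
  if (length(object)) {
    gc <- gcFraction(object)
    cat(sprintf("  GC fraction: min %.3f / median %.3f / max %.3f\n",
                min(gc), stats::median(gc), max(gc)))
  }
  invisible(NULL)
})

#' @rdname SpacerSet-class
#' @param row.names,optional passed on to [base::as.data.frame()]
#' @export
setMethod("as.data.frame", "SpacerSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@ranges
    data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      spacer_start = GenomicRanges::start(gr) - 1L,  # 0-based half-open out
      spacer_end = GenomicRanges::end(gr),
      pam = S4Vectors::mcols(gr)$pam,
      spacer_seq = S4Vectors::mcols(gr)$spacer_seq,
      gc_fraction = S4Vectors::mcols(gr)$gc_fraction,
      tm_c = S4Vectors::mcols(gr)$tm_c,
      stringsAsFactors = FALSE, row.names = row.names)
  })

#' @rdname GuideManual-class
#' @export
setMethod("manualEntries", "GuideManual", function(x) x@entries)

#' @rdname GuideManual-class
#' @export
setMethod("length", "GuideManual", function(x) nrow(x@entries))

#' @rdname GuideManual-class
#' @param row.names,optional,... passed on to [base::as.data.frame()]
#' @export
setMethod("as.data.frame", "GuideManual",
  function(x, row.names = NULL, optional = FALSE, ...)
    as.data.frame(x@entries, row.names = row.names, optional = optional))

#' @rdname GuideManual-class
#' @export
setMethod("show", "GuideManual", function(object) {
  e <- object@entries
  cat("GuideManual:", nrow(e), "entries across",
      length(unique(e$gene_id)), "gene(s)\n")
  if (nrow(e)) {
    cat(sprintf("  efficiency classes: %d high / %d low\n",
                sum(e$efficiency_class == "high"),
                sum(e$efficiency_class == "low")))
  }
  invisible(NULL)
})

#' @rdname DeletionCallSet-class
#' @export
setMethod("deletionRanges", "DeletionCallSet", function(x) x@calls)

#' @rdname DeletionCallSet-class
#' @export
setMethod("length", "DeletionCallSet", function(x) length(x@calls))

#' @rdname DeletionCallSet-class
#' @param row.names,optional,... passed on to [base::as.data.frame()]
#' @export
setMethod("as.data.frame", "DeletionCallSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@calls
    data.frame(
      read_id = S4Vectors::mcols(gr)$read_id,
      contig = as.character(GenomicRanges::seqnames(gr)),
      del_start = GenomicRanges::start(gr) - 1L,  # 0-based half-open out
      del_end = GenomicRanges::end(gr),
      length_bp = GenomicRanges::width(gr),
      microhomology_len = S4Vectors::mcols(gr)$microhomology_len,
      insertion_seq = S4Vectors::mcols(gr)$insertion_seq,
      left_flank_len = S4Vectors::mcols(gr)$left_flank_len,
      right_flank_len = S4Vectors::mcols(gr)$right_flank_len,
      stringsAsFactors = FALSE, row.names = row.names)
  })

#' @rdname DeletionCallSet-class
#' @export
setMethod("show", "DeletionCallSet", function(object) {
  gr <- object@calls
  cat("DeletionCallSet with", length(gr), "call(s)\n")
  if (length(gr)) {
    w <- GenomicRanges::width(gr)
    cat(sprintf("  lengths: %.3f / %.3f / %.3f kb (min/median/max)\n",
                min(w) / 1e3, stats::median(w) / 1e3, max(w) / 1e3))
    cat(sprintf("  with microhomology: %d; with insertion: %d\n",
                sum(S4Vectors::mcols(gr)$microhomology_len > 0L),
                sum(nchar(S4Vectors::mcols(gr)$insertion_seq) > 0L)))
  }
  sk <- S4Vectors::metadata(gr)$skipped
  if (!is.null(sk) && nrow(sk))
    cat("  skipped reads:", nrow(sk), "(see metadata(deletionRanges(x)))\n")
  invisible(NULL)
})
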