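## Central S4 containers. Coordinates are held as 1-based closed
## GRanges/IRanges (the Bioconductor convention) everywhere inside the
## package; the 0-based half-open convention used by the TSV/BED interfaces
## is produced only by the writers in io.R.

#' SpacerSet: PAM-anchored protospacer candidates
#'
#' Wraps a [GenomicRanges::GRanges] of protospacer intervals (forward-strand
#' coordinates, 1-based closed) whose metadata columns carry, for each
#' candidate, the PAM sequence (`pam`), the protospacer in guide orientation
#' (`spacer_seq`, reverse-complemented for minus-strand candidates), the GC
#' fraction of the spacer (`gc_fraction`, PAM excluded) and the predicted
#' melting temperature (`tm_c`, degrees Celsius).
#'
#' @slot ranges `GRanges` of protospacer intervals with the metadata columns
#'   described above.
#' @slot spacerLength integer, the common protospacer length (>= 27 nt).
#' @slot pamSet character vector of PAM sequences scanned for.
#'
#' @seealso [enumerateSpacers()], [selectManual()], [truncateSpacers()]
#' @export
setClass("SpacerSet",
  representation(ranges = "GRanges", spacerLength = "integer",
                 pamSet = "character"))

setValidity("SpacerSet", function(object) {
  msg <- character()
  gr <- object@ranges
  need <- c("pam", "spacer_seq", "gc_fraction", "tm_c")
  miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):",
                        paste(miss, collapse = ", ")))
  if (length(object@spacerLength) != 1L || is.na(object@spacerLength) ||
      object@spacerLength < 27L)
    msg <- c(msg, "spacerLength must be a single integer >= 27")
  if (!length(msg) && length(gr)) {
    if (!all(GenomicRanges::width(gr) == object@spacerLength))
      msg <- c(msg, "all spacer widths must equal spacerLength")
    gc <- S4Vectors::mcols(gr)$gc_fraction
    if (any(gc < 0 | gc > 1))
      msg <- c(msg, "gc_fraction must lie in [0, 1]")
    if (!all(nchar(S4Vectors::mcols(gr)$spacer_seq) == object@spacerLength))
      msg <- c(msg, "spacer_seq lengths must equal spacerLength")
    if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "strand must be + or - for every candidate")
  }
  if (length(msg)) msg else TRUE
})

#' GuideManual: the per-gene lowest-GC guide selection manual
#'
#' One row per selected guide: for every annotated gene the k candidates
#' with the lowest spacer GC content, ranked from lowest GC up, together
#' with the categorical efficiency class (`high` below the GC cutoff,
#' `low` at or above it).
#'
#' @slot entries A [S4Vectors::DataFrame] with columns `gene_id`, `rank`,
#'   `contig`, `strand`, `spacer_start`, `spacer_end` (0-based half-open,
#'   the interface convention), `pam`, `spacer_seq`, `gc_fraction`, `tm_c`,
#'   `efficiency_class`.
#'
#' @seealso [selectManual()], [writeGuideManual()]
#' @export
setClass("GuideManual", representation(entries = "DataFrame"))

.MANUAL_COLS <- c("gene_id", "rank", "contig", "strand", "spacer_start",
                  "spacer_end", "pam", "spacer_seq", "gc_fraction", "tm_c",
                  "efficiency_class")

setValidity("GuideManual", function(object) {
  e <- object@entries
  msg <- character()
  miss <- setdiff(.MANUAL_COLS, colnames(e))
  if (length(miss))
    msg <- c(msg, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(e)) {
    if (any(e$spacer_start < 0 | e$spacer_end <= e$spacer_start))
      msg <- c(msg, "spacer intervals must satisfy 0 <= start < end")
    for (g in unique(e$gene_id)) {
      r <- sort(e$rank[e$gene_id == g])
      if (!identical(as.integer(r), seq_along(r)))
        msg <- c(msg, paste0("ranks for gene ", g,
                             " are not consecutive from 1"))
      gc <- e$gc_fraction[e$gene_id == g][order(e$rank[e$gene_id == g])]
      if (is.unsorted(gc))
        msg <- c(msg, paste0("gc_fraction not non-decreasing with rank for ",
                             g))
    }
  }
  if (length(msg)) msg else TRUE
})

#' DeletionCallSet: deletion intervals inferred from junction reads
#'
#' Wraps a [GenomicRanges::GRanges] of leftmost-normalized deletion
#' intervals (1-based closed internally). Metadata columns: `read_id`,
#' `microhomology_len` (bases identical at both junction sides; the call is
#' shift-equivalent over `microhomology_len + 1` placements),
#' `insertion_seq` (non-templated bases at the junction, possibly empty),
#' `left_flank_len` / `right_flank_len` (aligned bases supporting each
#' side). Per-read failures collected by [inferDeletions()] live in
#' `metadata(x)$skipped`.
#'
#' @slot calls `GRanges` with the metadata columns described above.
#'
#' @seealso [inferDeletions()], [unionIntervals()], [writeDeletionCalls()]
#' @export
setClass("DeletionCallSet", representation(calls = "GRanges"))

setValidity("DeletionCallSet", function(object) {
  gr <- object@calls
  msg <- character()
  need <- c("read_id", "microhomology_len", "insertion_seq",
            "left_flank_len", "right_flank_len")
  miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):",
                        paste(miss, collapse = ", ")))
  if (!length(msg) && length(gr)) {
    if (any(GenomicRanges::width(gr) < 1L))
      msg <- c(msg, "deletion length must be >= 1")
    if (any(S4Vectors::mcols(gr)$microhomology_len < 0L))
      msg <- c(msg, "microhomology_len must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
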