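#' @rdname SpacerSet-class
#' @param x,object a `SpacerSet`
#' @export
setGeneric("spacerRanges", function(x) standardGeneric("spacerRanges"))

#' @rdname SpacerSet-class
#' @export
setGeneric("spacerSeqs", function(x) standardGeneric("spacerSeqs"))

#' Compute or extract GC fraction
#'
#' For DNA sequences, the fraction of G and C bases, `(#G + #C) / length`;
#' for a [SpacerSet], the stored per-candidate GC fraction of the spacer
#' (PAM excluded).
#'
#' @param x a character vector of unambiguous DNA sequences, a
#'   [Biostrings::DNAStringSet], or a `SpacerSet`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' gcFraction(c("ATAT", "GGCC", "ATGC"))  # 0, 1, 0.5
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))

#' Compute or extract DNA melting temperature
#'
#' Two classical estimators: `"wallace"`, `2*(#A + #T) + 4*(#G + #C)`
#' (short oligos), and `"gc_formula"`, `81.5 + 0.41 * %GC - 675 / N`
#' (longer oligos). `"auto"` (the default) uses the GC formula for
#' sequences of 14 nt and longer and the Wallace rule otherwise. Both are
#' monotone increasing in GC content at fixed length. For a [SpacerSet],
#' returns the stored per-candidate Tm.
#'
#' @param x character vector of unambiguous DNA sequences, a
#'   [Biostrings::DNAStringSet], or a `SpacerSet`.
#' @param method one of `"auto"`, `"gc_formula"`, `"wallace"`.
#' @return numeric vector, degrees Celsius.
#' @examples
#' meltingTemp("ACGT", method = "wallace")  # 12
#' @export
setGeneric("meltingTemp",
  function(x, method = c("auto", "gc_formula", "wallace"))
    standardGeneric("meltingTemp"))

#' @rdname GuideManual-class
#' @param x,object a `GuideManual`
#' @export
setGeneric("manualEntries", function(x) standardGeneric("manualEntries"))

#' @rdname DeletionCallSet-class
#' @param x,object a `DeletionCallSet`
#' @export
setGeneric("deletionRanges", function(x) standardGeneric("deletionRanges"))
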