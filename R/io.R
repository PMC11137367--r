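## Readers and writers. The package-internal coordinate frame is 1-based
## closed (GRanges); GFF3 is already 1-based inclusive, while BED and the
## manual/calls TSVs use 0-based half-open coordinates, converted here and
## nowhere else.

.IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V")
.AA20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.checkFastaIds <- function(x, path) {
  if (length(x) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  names(x) <- ids
  x
}

#' Read a genome (nucleotide FASTA)
#'
#' Sequences are uppercased, `U` is converted to `T`, record ids are
#' truncated at the first whitespace and must be unique. Any character
#' outside the IUPAC DNA alphabet is an error naming the offending record.
#' `N` is accepted in genomes; candidate spacers and PAM windows containing
#' `N` are discarded downstream.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet] (one element per contig).
#' @seealso [genomeLength()], [readProteins()]
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- .checkFastaIds(Biostrings::readBStringSet(path), path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence for record(s): ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "),
         call. = FALSE)
  chr <- chartr("u", "t", toupper(as.character(x)))
  chr <- chartr("U", "T", chr)
  bad <- vapply(chr, function(s)
    grepl(paste0("[^", paste(.IUPAC_DNA, collapse = ""), "]"), s), logical(1))
  if (any(bad))
    stop("non-IUPAC DNA character in record(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  Biostrings::DNAStringSet(setNames(chr, names(x)))
}

#' Read a protein set (amino-acid FASTA)
#'
#' Uppercased; alphabet restricted to the 20 standard residues plus `X`;
#' ids unique and non-empty.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::AAStringSet].
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- .checkFastaIds(Biostrings::readBStringSet(path), path)
  chr <- toupper(as.character(x))
  if (any(!nzchar(chr)))
    stop("empty sequence in ", path, call. = FALSE)
  bad <- vapply(chr, function(s)
    grepl(paste0("[^", paste(.AA20X, collapse = ""), "]"), s), logical(1))
  if (any(bad))
    stop("illegal amino-acid character in record(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  Biostrings::AAStringSet(setNames(chr, names(x)))
}

#' Total genome length in bases
#'
#' @param genome a [Biostrings::DNAStringSet] as returned by [readGenome()].
#' @return total number of bases across contigs.
#' @export
genomeLength <- function(genome) sum(as.numeric(Biostrings::width(genome)))

#' Read gene features from GFF3
#'
#' GFF3 coordinates are 1-based inclusive and are kept as such in the
#' returned [GenomicRanges::GRanges]. The gene identifier is taken from the
#' `locus_tag` attribute when present, else `ID`, else `Name`; a feature
#' with none of the three is an error. When a genome is supplied, features
#' on unknown contigs or extending beyond a contig end are rejected.
#'
#' @param path GFF3 file.
#' @param featureTypes feature types (column 3) to keep; default `"gene"`.
#' @param genome optional [Biostrings::DNAStringSet] to validate against.
#' @return `GRanges` with metadata columns `gene_id` and `type`.
#' @export
readGeneFeatures <- function(path, featureTypes = "gene", genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% featureTypes]
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% colnames(mc)) as.character(mc[[col]]) else
      rep(NA_character_, length(gr))
  }
  gene_id <- pick("locus_tag")
  gene_id <- ifelse(is.na(gene_id) | !nzchar(gene_id), pick("ID"), gene_id)
  gene_id <- ifelse(is.na(gene_id) | !nzchar(gene_id), pick("Name"), gene_id)
  if (any(is.na(gene_id) | !nzchar(gene_id)))
    stop("feature without locus_tag/ID/Name attribute in ", path,
         call. = FALSE)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr),
    gene_id = gene_id, type = as.character(gr$type))
  if (!is.null(genome)) {
    cid <- as.character(GenomicRanges::seqnames(out))
    unknown <- !(cid %in% names(genome))
    if (any(unknown))
      stop("feature(s) on contig absent from genome: ",
           paste(unique(cid[unknown]), collapse = ", "), call. = FALSE)
    lens <- Biostrings::width(genome)[match(cid, names(genome))]
    if (any(GenomicRanges::end(out) > lens))
      stop("feature(s) extend beyond contig end", call. = FALSE)
  }
  sort(out, ignore.strand = TRUE)
}

#' Write / read plain BED3 intervals
#'
#' BED is 0-based half-open; `writeIntervalsBed()` converts from the
#' 1-based `GRanges` representation and `readIntervalsBed()` converts back,
#' so `readIntervalsBed(writeIntervalsBed(x))` reproduces `x`.
#'
#' @param gr a `GRanges` (strand and metadata are not written; BED3 only).
#' @param path output/input file.
#' @return `writeIntervalsBed()` returns `path` invisibly;
#'   `readIntervalsBed()` returns a `GRanges`.
#' @export
writeIntervalsBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeIntervalsBed
#' @export
readIntervalsBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "start",
                                                       "end"))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Write / read a tree in newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; output is
#' a single line terminated by `;`.
#'
#' @param tree an [ape] `phylo` object.
#' @param path file path.
#' @return `writeTreeNewick()` returns `path` invisibly;
#'   `readTreeNewick()` returns a `phylo`.
#' @export
writeTreeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeTreeNewick
#' @export
readTreeNewick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' Write / read the guide selection manual as TSV
#'
#' Columns (in order): `gene_id`, `rank`, `contig`, `strand`,
#' `spacer_start`, `spacer_end` (0-based half-open), `pam`, `spacer_seq`,
#' `gc_percent` (one decimal), `tm_c` (one decimal), `efficiency_class`.
#' Reading converts `gc_percent` back to a fraction; because the TSV keeps
#' one decimal of percent, `writeGuideManual(readGuideManual(f))`
#' reproduces `f` byte for byte.
#'
#' @param manual a [GuideManual].
#' @param path file path.
#' @return `writeGuideManual()` returns `path` invisibly;
#'   `readGuideManual()` returns a `GuideManual`.
#' @export
writeGuideManual <- function(manual, path) {
  e <- as.data.frame(manual)
  out <- data.frame(
    gene_id = e$gene_id, rank = e$rank, contig = e$contig,
    strand = e$strand, spacer_start = e$spacer_start,
    spacer_end = e$spacer_end, pam = e$pam, spacer_seq = e$spacer_seq,
    gc_percent = sprintf("%.1f", 100 * e$gc_fraction),
    tm_c = sprintf("%.1f", e$tm_c),
    efficiency_class = e$efficiency_class,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGuideManual
#' @export
readGuideManual <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = c(
    gene_id = "character", rank = "integer", contig = "character",
    strand = "character", spacer_start = "integer", spacer_end = "integer",
    pam = "character", spacer_seq = "character", gc_percent = "numeric",
    tm_c = "numeric", efficiency_class = "character"))
  ent <- S4Vectors::DataFrame(
    gene_id = df$gene_id, rank = df$rank, contig = df$contig,
    strand = df$strand, spacer_start = df$spacer_start,
    spacer_end = df$spacer_end, pam = df$pam, spacer_seq = df$spacer_seq,
    gc_fraction = df$gc_percent / 100, tm_c = df$tm_c,
    efficiency_class = df$efficiency_class)
  methods::new("GuideManual", entries = ent)
}

#' Write / read deletion calls as TSV
#'
#' Columns: `read_id`, `contig`, `del_start`, `del_end` (0-based
#' half-open), `length_bp`, `microhomology_len`, `insertion_seq`,
#' `left_flank_len`, `right_flank_len`. Round-trips exactly.
#'
#' @param calls a [DeletionCallSet].
#' @param path file path.
#' @return `writeDeletionCalls()` returns `path` invisibly;
#'   `readDeletionCalls()` returns a `DeletionCallSet`.
#' @export
writeDeletionCalls <- function(calls, path) {
  df <- as.data.frame(calls)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDeletionCalls
#' @export
readDeletionCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = c(
    read_id = "character", contig = "character", del_start = "integer",
    del_end = "integer", length_bp = "integer",
    microhomology_len = "integer", insertion_seq = "character",
    left_flank_len = "integer", right_flank_len = "integer"))
  df$insertion_seq[is.na(df$insertion_seq)] <- ""
  gr <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$del_start + 1L, df$del_end),
    read_id = df$read_id, microhomology_len = df$microhomology_len,
    insertion_seq = df$insertion_seq, left_flank_len = df$left_flank_len,
    right_flank_len = df$right_flank_len)
  methods::new("DeletionCallSet", calls = gr)
}
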