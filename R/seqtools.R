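# Deterministic sequence arithmetic: cDNA intervals and amplicon lengths,
# frameshift codon computation, and junction-targeting siRNA duplex design
# with phosphorothioate annotation.
#
# cDNA coordinates use the HGVS-style c. numbering: 1-based inclusive with
# c.1 at the A of the start codon, so codon k spans c.(3k-2)..c.(3k).

#' Construct a cDNA interval
#'
#' @param start,end 1-based inclusive cDNA coordinates, `1 <= start <= end`.
#' @return A list of class `"cdna_interval"`.
#' @export
cdna_interval <- function(start, end) {
  check_scalar(start, "start", lower = 1)
  check_scalar(end, "end", lower = 1)
  if (start > end) stop("interval start exceeds end", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "cdna_interval")
}

#' Length of a cDNA interval in bases
#'
#' @param interval a [cdna_interval()] (or list with `start`, `end`).
#' @return `end - start + 1`.
#' @examples
#' interval_length(cdna_interval(2180, 2361))  # 182-bp amplicon
#' @export
interval_length <- function(interval) {
  if (!is.list(interval)) stop("interval must be a cdna_interval", call. = FALSE)
  if (interval$start > interval$end) stop("invalid interval", call. = FALSE)
  interval$end - interval$start + 1L
}

#' Codon at which a deletion-induced frameshift begins
#'
#' The 1-based index of the codon containing the first deleted cDNA base,
#' i.e. `ceiling(deletion_start / 3)`.  For an in-frame reading starting at
#' c.1, this is the first residue affected by the truncating frameshift.
#'
#' @param deletion_start cDNA coordinate (>= 1) of the first deleted base.
#' @return Integer codon/residue index.
#' @examples
#' frameshift_codon(2208)  # 736
#' @export
frameshift_codon <- function(deletion_start) {
  check_scalar(deletion_start, "deletion_start", lower = 1)
  as.integer(ceiling(deletion_start / 3))
}

#' PCR product length after an internal deletion
#'
#' Length of the amplicon minus the deleted bases, for a deletion fully
#' contained in the amplicon.  Note: for the exon-12 deletion
#' (c.2208-c.2327) inside the c.2180-c.2361 amplicon this arithmetic gives
#' 62 bp while gel annotations sometimes quote 63 bp; the function returns
#' the arithmetic value.
#'
#' @param amplicon,deletion [cdna_interval()]s with
#'   `deletion` contained in `amplicon`.
#' @return Integer base count.
#' @export
deletion_product_length <- function(amplicon, deletion) {
  if (deletion$start < amplicon$start || deletion$end > amplicon$end) {
    stop("deletion must be fully contained in the amplicon", call. = FALSE)
  }
  interval_length(amplicon) - interval_length(deletion)
}

rna_of <- function(dna) chartr("T", "U", dna)

revcomp_dna <- function(dna) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]), collapse = "")
}

# Render a 19-base RNA core with phosphorothioate stars on the first and
# last 3 internucleotide linkages of the core, then the 3' TT overhang
# (deoxythymidine, written as DNA "TT").
render_strand <- function(core_rna, overhang = "TT") {
  bases <- strsplit(core_rna, "")[[1]]
  n <- length(bases)
  starred <- c(1:3, (n - 3):(n - 1))  # linkage after base i gets a star
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out, bases[i], if (i %in% starred) "*")
  }
  paste0(paste(out, collapse = ""), overhang)
}

#' Design a junction-targeting siRNA duplex
#'
#' Given a 19-base DNA target (sense) sequence, produces the annotated
#' sense and antisense strands of the duplex: the RNA transliteration of
#' the target (sense) and of its reverse complement (antisense), each with
#' phosphorothioate marks (`*`) on the first and last three linkages and a
#' 3' TT (deoxythymidine) overhang.  The duplex cores are perfectly
#' complementary.
#'
#' @param target_dna 19-character string over `A`, `C`, `G`, `T`.
#' @return A list of class `"duplex_design"` with `target_dna`,
#'   `sense_core`, `antisense_core` (plain RNA, 19 nt), `sense_strand`,
#'   `antisense_strand` (annotated, with stars and TT overhang), and
#'   `overhang`.
#' @examples
#' design_sirna("AAAGAGATGCAGAGTCCTC")$sense_strand
#' # "A*A*A*GAGAUGCAGAGUC*C*U*CTT"
#' @export
design_sirna <- function(target_dna) {
  if (!is.character(target_dna) || length(target_dna) != 1L) {
    stop("target must be a single string", call. = FALSE)
  }
  target_dna <- toupper(target_dna)
  if (nchar(target_dna) != 19L) {
    stop("target must be exactly 19 bases (N19 motif)", call. = FALSE)
  }
  if (grepl("[^ACGT]", target_dna)) {
    stop("target may contain only A, C, G, T", call. = FALSE)
  }
  sense_core <- rna_of(target_dna)
  antisense_core <- rna_of(revcomp_dna(target_dna))
  structure(
    list(target_dna = target_dna,
         sense_core = sense_core,
         antisense_core = antisense_core,
         sense_strand = render_strand(sense_core),
         antisense_strand = render_strand(antisense_core),
         overhang = "TT"),
    class = "duplex_design")
}

#' Target window around a splice junction
#'
#' On the spliced (exon-skipped) transcript, returns the `flank` bases
#' ending at the last base before the junction and the `flank` bases
#' starting just after it — the +/- window from which junction-spanning
#' siRNA candidates are drawn.
#'
#' @param exon_end_coord cDNA coordinate of the last base of the upstream
#'   exon (must exceed `flank`).
#' @param flank window half-width in bases (default 20).
#' @return A list with `upstream` and `downstream` [cdna_interval()]s.
#' @export
junction_target_window <- function(exon_end_coord, flank = 20) {
  check_scalar(flank, "flank", lower = 1)
  check_scalar(exon_end_coord, "exon_end_coord", lower = flank,
               strict_lower = TRUE)
  list(upstream = cdna_interval(exon_end_coord - flank + 1, exon_end_coord),
       downstream = cdna_interval(exon_end_coord + 1, exon_end_coord + flank))
}
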