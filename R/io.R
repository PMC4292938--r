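# Shared plumbing: TSV readers/writers, bundled fixtures, and the
# end-to-end pipeline driver.

#' Read a feature x sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids, and a
#' numeric body.  `#`-prefixed comment lines are skipped.  Non-numeric
#' cells and ragged rows are reported with their row and column.
#'
#' @param path file path.
#' @return Numeric matrix with feature and sample ids as dimnames, in file
#'   order.
#' @export
read_expression_tsv <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expected feature id column plus samples",
                           call. = FALSE)
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row %d (feature %s), column %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write an expression matrix as TSV
#'
#' Canonical formatting (up to 15 significant digits) so that
#' write -> read round-trips are lossless for the values the pipeline
#' produces.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param feature_col name of the feature id column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, feature_col = "feature_id") {
  x <- as.matrix(x)
  df <- data.frame(rownames(x),
                   apply(x, 2, function(col) sprintf("%.15g", col)),
                   check.names = FALSE)
  names(df) <- c(feature_col, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled CD22 fixtures
#'
#' Returns the package's bundled reference data for the CD22 delta-E12
#' system: the ten probe-to-exon alignment records of the exon-10-14
#' probeset 217422_s_at (verbatim printed format, parsed), the three
#' 19-mer siRNA target sequences with the annotated duplex and scrambled
#' strands, and the RT-PCR primer/deletion cDNA coordinates.
#'
#' @return A list with `probe_alignments` (data frame), `alignment_lines`
#'   (verbatim character vector), `sirna` (data frame), `sirna_targets`
#'   (character vector of the 3 target 19-mers), and `primers` (data
#'   frame with cDNA coordinates).
#' @export
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "exonskipr",
                                  mustWork = TRUE)
  lines <- readLines(path("cd22_probe_alignments.txt"), encoding = "UTF-8")
  sirna <- read.delim(path("cd22_sirna.tsv"), colClasses = "character")
  primers <- read.delim(path("cd22_primers.tsv"))
  list(probe_alignments = parse_probe_alignments(lines),
       alignment_lines = lines,
       sirna = sirna,
       sirna_targets = sirna$sequence[sirna$role == "target_dna"],
       primers = primers)
}

#' Run the full synthetic-to-incidence pipeline
#'
#' Orchestrates: probe-level simulation, the preprocessing stack
#' (norm-exp background correction, quantile normalization, log2), the
#' exon-skipping index on the indexed probeset, the reference interval,
#' and incidence calling — optionally writing every intermediate as TSV.
#'
#' @param spec a [cohort_spec()]; defaults to [default_cohort_spec()].
#' @param target_exon label of the skipped exon in the simulated chip
#'   (the simulator labels its target probes `"Exon 12"`).
#' @param ci_level reference interval confidence level.
#' @param out_dir optional directory for intermediate TSVs.
#' @return A list with `index` (per-sample values), `groups`,
#'   `interval`, `incidence` (an `"index_result"`), `anova`
#'   (two-group one-way ANOVA on the index), and `spec`.
#' @export
run_pipeline <- function(spec = default_cohort_spec(),
                         target_exon = "Exon 12",
                         ci_level = 0.95,
                         out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ds <- simulate_probe_intensities(spec)
  prep <- rma_preprocess(ds$intensities)

  # exon map from the simulator's truth labels (3 target + 7 flanking;
  # the 11th probe stays unassigned and only feeds the centering)
  eg <- ds$truth$exon_group
  mapped <- names(eg)[eg %in% c("target", "flanking")]
  align <- data.frame(
    probe_id = mapped,
    exon_label = ifelse(eg[mapped] == "target", target_exon, "Exon flank"))
  emap <- build_exon_map(align, target_exon)

  idx_probes <- names(eg)[ds$probeset_ids == "PSX"]
  idx <- exon_skip_index(prep$probe_log2[idx_probes, , drop = FALSE], emap)

  ref_idx <- idx[ds$group_labels == "reference"]
  case_idx <- idx[ds$group_labels == "case"]
  interval <- reference_interval(ref_idx, level = ci_level)
  incidence <- call_incidence(case_idx, interval)
  anova <- one_way_anova(list(reference = ref_idx, case = case_idx))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_expression_tsv(ds$intensities,
                         file.path(out_dir, "probe_raw.tsv"), "probe_id")
    write_expression_tsv(prep$probe_log2,
                         file.path(out_dir, "probe_log2.tsv"), "probe_id")
    write.table(data.frame(sample_id = ds$sample_ids,
                           group = ds$group_labels,
                           index = as.numeric(idx)),
                file.path(out_dir, "index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(index = idx,
       groups = setNames(ds$group_labels, ds$sample_ids),
       interval = interval,
       incidence = incidence,
       anova = anova,
       spec = spec)
}
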