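# File-format readers and writers. Internal convention: 0-based half-open
# intervals, chromosome labels "1".."22" (autosomes only; X/Y rows are
# dropped on read with a message). Tabular formats are TSV; the segment
# TSVs are 1-based inclusive on disk (SEG-like), BED is native 0-based
# half-open.

.normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

.drop_xy <- function(df, path) {
  chrom <- .normalize_chrom(df$chrom)
  xy <- chrom %in% c("X", "Y", "x", "y", "23", "24")
  if (any(xy)) {
    message("dropped ", sum(xy), " X/Y row(s) from ", basename(path))
  }
  df$chrom <- chrom
  df[!xy, , drop = FALSE]
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
}

.check_intervals <- function(df, path, by_sample = TRUE) {
  if (any(df$start < 0) || any(df$end < df$start)) {
    stop("file ", path, " has negative or inverted coordinates")
  }
  key <- if (by_sample) paste(df$sample, df$chrom, df$start, df$end)
         else paste(df$chrom, df$start, df$end)
  if (anyDuplicated(key)) stop("file ", path, " has duplicate interval rows")
  invisible(df)
}

#' Read a relative (SEG-like) segment table
#'
#' Expects a TSV with header `sample, chrom, start, end, value`, 1-based
#' inclusive coordinates; converted to 0-based half-open on read.
#'
#' @param path File path.
#' @return data.frame with `sample`, `chrom`, `start`, `end`, `value`.
#' @export
read_segments <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  .require_cols(df, c("sample", "chrom", "start", "end", "value"), path)
  df$start <- df$start - 1L
  df <- .drop_xy(df, path)
  .check_intervals(df, path)
  df[, c("sample", "chrom", "start", "end", "value")]
}

#' Write a relative segment table (1-based inclusive TSV)
#' @param segments Internal segment data.frame.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1L
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an allele-specific segment table
#'
#' TSV with header `sample, chrom, start, end, nA, nB`, 1-based inclusive.
#'
#' @param path File path.
#' @return data.frame with `sample`, `chrom`, `start`, `end`, `nA`, `nB`.
#' @export
read_allelic <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  .require_cols(df, c("sample", "chrom", "start", "end", "nA", "nB"), path)
  df$start <- df$start - 1L
  df <- .drop_xy(df, path)
  .check_intervals(df, path)
  if (any(df$nA < 0 | df$nB < 0)) stop("file ", path, " has negative allele counts")
  df[, c("sample", "chrom", "start", "end", "nA", "nB")]
}

#' Write an allele-specific segment table (1-based inclusive TSV)
#' @param segments Internal allelic segment data.frame.
#' @param path Output path.
#' @export
write_allelic <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1L
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read gene annotation from BED
#'
#' BED columns `chrom, start, end, name[, score, strand]`; strand is
#' ignored. Coordinates are kept 0-based half-open. An optional 7th column
#' `arm` is read if present (as written by [write_bed()]).
#'
#' @param path File path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` and `arm`
#'   (NA when absent).
#' @export
read_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(df) < 4L) stop("file ", path, " is not BED-like (needs >= 4 columns)")
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  df$arm <- if (ncol(df) >= 7L) as.character(df[[7L]]) else NA_character_
  df <- .drop_xy(df, path)
  .check_intervals(df, path, by_sample = FALSE)
  if (anyDuplicated(df$gene_id)) stop("file ", path, " has duplicate gene ids")
  df[, c("gene_id", "chrom", "start", "end", "arm")]
}

#' Write gene annotation as BED (score 0, strand ".", arm in column 7)
#' @param genes Gene annotation data.frame.
#' @param path Output path.
#' @export
write_bed <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, ".", if (!is.null(genes$arm)) genes$arm else NA)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix (genes x samples TSV)
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (names(df)[1L] != "gene_id") stop("file ", path, " must start with a gene_id column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write a log2 expression matrix as TSV
#' @param expr Matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata (TSV)
#' @param path File path.
#' @return data.frame with at least `sample`, `msi`, `cms`.
#' @export
read_metadata <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  .require_cols(df, c("sample", "msi", "cms"), path)
  if (anyDuplicated(df$sample)) stop("file ", path, " has duplicate sample ids")
  df
}

#' Write sample metadata as TSV
#' @param metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  data.table::fwrite(metadata, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write a full synthetic cohort to a directory
#'
#' Emits the exact input formats the readers consume, plus the ground truth
#' as JSON.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(cohort$rel_segments, file.path(dir, "relative_segments.tsv"))
  write_allelic(cohort$allelic_segments, file.path(dir, "allelic_segments.tsv"))
  write_bed(cohort$genes, file.path(dir, "genes.bed"))
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    truth[c("gene_roles", "sample_truth", "amps", "amp_hazard_ratio", "config")],
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory path.
#' @return A list with `genes`, `rel_segments`, `allelic_segments`, `expr`,
#'   `metadata` (no truth).
#' @export
read_cohort <- function(dir) {
  list(
    genes = read_bed(file.path(dir, "genes.bed")),
    rel_segments = read_segments(file.path(dir, "relative_segments.tsv")),
    allelic_segments = read_allelic(file.path(dir, "allelic_segments.tsv")),
    expr = read_expression(file.path(dir, "expression.tsv")),
    metadata = read_metadata(file.path(dir, "metadata.tsv"))
  )
}
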