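#' Construct a peak set
#'
#' A `peak_set` bundles one sample's nascent-transcript peak records with the
#' sample-level metadata needed for normalization: the sample label and the
#' total number of aligned reads (sequence tags) in that sample's library.
#' Coordinates are stored 0-based half-open, so `length = end - start`.
#'
#' @param records data.frame with columns `peak_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `raw_reads`. `start`/`end` are 0-based
#'   half-open; `strand` is `"+"` or `"-"`; `raw_reads` is a nonnegative count.
#' @param total_aligned_reads positive count of aligned reads in the library.
#' @param sample_label character scalar naming the sample.
#' @return An object of class `peak_set`.
#' @examples
#' ps <- peak_set(
#'   data.frame(peak_id = "p1", gene_id = "FUS", chrom = "chr16",
#'              start = 99L, end = 600L, strand = "+", raw_reads = 12L),
#'   total_aligned_reads = 1e7, sample_label = "ctrl")
#' ps
#' @export
peak_set <- function(records, total_aligned_reads, sample_label = "sample") {
  stopifnot(is.data.frame(records))
  needed <- c("peak_id", "gene_id", "chrom", "start", "end", "strand", "raw_reads")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("peak_set records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, needed, drop = FALSE]
  if (!is.numeric(total_aligned_reads) || length(total_aligned_reads) != 1L ||
      is.na(total_aligned_reads) || total_aligned_reads <= 0) {
    stop("total_aligned_reads must be a single positive count")
  }
  if (anyDuplicated(records$peak_id)) {
    stop("peak_id values must be unique within a peak_set")
  }
  if (nrow(records) > 0L) {
    if (any(records$raw_reads < 0)) stop("raw_reads must be nonnegative")
    if (!all(records$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(records$end <= records$start)) {
      stop("all records must satisfy end > start (0-based half-open)")
    }
  }
  rownames(records) <- NULL
  structure(
    list(sample_label = as.character(sample_label),
         total_aligned_reads = as.numeric(total_aligned_reads),
         records = records),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> sample '%s': %d peaks, %s total aligned reads\n",
              x$sample_label, nrow(x$records),
              format(x$total_aligned_reads, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$records)

#' @export
as.data.frame.peak_set <- function(x, ...) x$records

## Column-name heuristics for the HOMER dialect -------------------------------

.match_column <- function(selector, cols, what) {
  if (is.numeric(selector)) {
    idx <- as.integer(selector)
    if (idx < 1L || idx > length(cols)) {
      stop(sprintf("%s column index %d out of range (file has %d columns)",
                   what, idx, length(cols)))
    }
    return(idx)
  }
  idx <- which(cols == selector)
  if (length(idx) == 0L) idx <- grep(selector, cols, ignore.case = TRUE)
  if (length(idx) == 0L) {
    stop(sprintf("required %s column '%s' not found (columns: %s)",
                 what, selector, paste(cols, collapse = ", ")))
  }
  idx[1L]
}

#' Read a HOMER-style peak table
#'
#' Parses the tab-delimited output of HOMER's `findPeaks` (GRO-seq style).
#' Comment/header lines begin with `#`; if the final comment line is a
#' tab-delimited header (as HOMER writes), column names are taken from it,
#' otherwise the canonical order `PeakID, chr, start, end, strand, tag count`
#' is assumed. Input coordinates are 1-based inclusive and converted to the
#' internal 0-based half-open convention (`start - 1`, `end`), under which
#' transcript length is simply `end - start`. Records whose converted `end`
#' is not greater than `start` are dropped with a message.
#'
#' HOMER peak files only carry gene names when annotated, so the gene column
#' is configurable; likewise the analysis-facing "raw read count" column is not
#' fixed by the dialect and can be selected by name or index.
#'
#' @param path path to the peak file.
#' @param total_aligned_reads the library's total aligned read (tag) count;
#'   this is tag-directory metadata, never inferred from the peak table.
#' @param sample_label sample name stored in the result.
#' @param count_column column (name, regex, or index) holding the per-peak
#'   read count. Default: a column matching `"Tag Count"`, else column 6.
#' @param gene_column column holding gene identifiers. Default: a column
#'   matching `"Gene Name"` if present, else the PeakID column is reused.
#' @return A [peak_set()].
#' @export
read_homer_peaks <- function(path, total_aligned_reads, sample_label = basename(path),
                             count_column = NULL, gene_column = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^#", lines)
  data_idx <- which(!is_comment & nzchar(trimws(lines)))

  cols <- NULL
  comment_lines <- lines[is_comment]
  if (length(comment_lines) > 0L) {
    last <- comment_lines[length(comment_lines)]
    if (grepl("\t", last)) {
      cols <- strsplit(sub("^#", "", last), "\t", fixed = TRUE)[[1L]]
    }
  }

  if (length(data_idx) == 0L) {
    return(peak_set(
      data.frame(peak_id = character(), gene_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), raw_reads = numeric()),
      total_aligned_reads, sample_label))
  }

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  ncol_data <- max(lengths(fields))
  if (is.null(cols)) {
    cols <- c("PeakID", "chr", "start", "end", "strand", "Tag Count")
    if (ncol_data > length(cols)) {
      cols <- c(cols, paste0("V", seq.int(length(cols) + 1L, ncol_data)))
    }
  }
  if (ncol_data > length(cols)) {
    stop("data rows have more fields than the header declares")
  }

  i_id     <- .match_column("PeakID", cols, "peak id")
  i_chr    <- .match_column("^chr", cols, "chromosome")
  i_start  <- .match_column("^start$", cols, "start")
  i_end    <- .match_column("^end$", cols, "end")
  i_strand <- .match_column("^strand$", cols, "strand")
  i_count  <- if (is.null(count_column)) {
    idx <- grep("Tag Count", cols, ignore.case = TRUE)
    if (length(idx) > 0L) idx[1L] else min(6L, length(cols))
  } else .match_column(count_column, cols, "read count")
  i_gene <- if (is.null(gene_column)) {
    idx <- grep("Gene Name", cols, ignore.case = TRUE)
    if (length(idx) > 0L) idx[1L] else i_id
  } else .match_column(gene_column, cols, "gene")

  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")

  start_raw <- get(i_start); end_raw <- get(i_end); count_raw <- get(i_count)
  start1 <- suppressWarnings(as.numeric(start_raw))
  end1   <- suppressWarnings(as.numeric(end_raw))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric coordinate at line %d of %s: '%s'/'%s'",
                 data_idx[bad[1L]], path, start_raw[bad[1L]], end_raw[bad[1L]]))
  }
  raw_reads <- suppressWarnings(as.numeric(count_raw))
  if (anyNA(raw_reads)) {
    bad <- which(is.na(raw_reads))[1L]
    stop(sprintf("non-numeric read count at line %d of %s: '%s'",
                 data_idx[bad], path, count_raw[bad]))
  }

  rec <- data.frame(
    peak_id = get(i_id), gene_id = get(i_gene), chrom = get(i_chr),
    start = as.integer(start1) - 1L,   # 1-based inclusive -> 0-based half-open
    end = as.integer(end1),
    strand = get(i_strand), raw_reads = raw_reads,
    stringsAsFactors = FALSE)

  drop <- rec$end <= rec$start
  if (any(drop)) {
    message(sprintf("read_homer_peaks: dropped %d record(s) with end <= start", sum(drop)))
    rec <- rec[!drop, , drop = FALSE]
  }
  peak_set(rec, total_aligned_reads, sample_label)
}

#' Write a peak set in the HOMER 1-based inclusive dialect
#'
#' Inverse of [read_homer_peaks()]: internal 0-based half-open coordinates are
#' exported as 1-based inclusive, so a write/read round trip is the identity.
#'
#' @param x a [peak_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_homer_peaks <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  con <- file(path, open = "wb")  # binary: force LF endings everywhere
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample=%s total_aligned_reads=%s", x$sample_label,
            format(x$total_aligned_reads, scientific = FALSE)),
    "#PeakID\tchr\tstart\tend\tstrand\tTag Count\tGene Name"), con, sep = "\n")
  r <- x$records
  if (nrow(r) > 0L) {
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s",
                       r$peak_id, r$chrom, r$start + 1L, r$end, r$strand,
                       format(r$raw_reads, scientific = FALSE, trim = TRUE),
                       r$gene_id), con, sep = "\n")
  }
  invisible(path)
}

#' Export retained peaks as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. The score field carries `raw_reads`.
#'
#' @inheritParams write_homer_peaks
#' @export
write_peaks_bed <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  r <- x$records
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(r) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       r$chrom, r$start, r$end, r$peak_id,
                       format(r$raw_reads, scientific = FALSE, trim = TRUE),
                       r$strand), con, sep = "\n")
  }
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines are skipped; surrounding whitespace is
#' stripped; duplicates are removed; case is preserved (matching downstream is
#' exact and case-sensitive).
#'
#' @param path path to the list.
#' @return character vector of unique identifiers (possibly empty, with a
#'   warning for an empty file).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) warning("gene list is empty: ", path)
  x
}

#' Write a scored-transcript table
#'
#' Tab-delimited, UTF-8, LF endings, header
#' `gene  peak_score  length  binding_surface_score  is_target`. Numeric
#' columns are written with 15 significant digits so that a write/read round
#' trip preserves values well beyond 12 significant digits.
#'
#' @param transcripts data.frame of scored transcripts (as produced by
#'   [score_transcripts()]): columns `gene_id`, `peak_score`, `length`,
#'   `binding_surface_score`, `is_target`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_scored_table <- function(transcripts, path) {
  needed <- c("gene_id", "peak_score", "length", "binding_surface_score", "is_target")
  missing_cols <- setdiff(needed, names(transcripts))
  if (length(missing_cols) > 0L) {
    stop("scored table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("gene\tpeak_score\tlength\tbinding_surface_score\tis_target", con, sep = "\n")
  if (nrow(transcripts) > 0L) {
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s",
                       transcripts$gene_id,
                       formatC(transcripts$peak_score, digits = 15, format = "g"),
                       as.integer(transcripts$length),
                       formatC(transcripts$binding_surface_score, digits = 15, format = "g"),
                       ifelse(transcripts$is_target, "TRUE", "FALSE")), con, sep = "\n")
  }
  invisible(path)
}

#' Read a scored-transcript table written by [write_scored_table()]
#'
#' @param path path to the table.
#' @return data.frame with columns `gene_id`, `peak_score`, `length`,
#'   `binding_surface_score`, `is_target`.
#' @export
read_scored_table <- function(path) {
  if (!file.exists(path)) stop("scored table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "integer",
                                         "numeric", "logical"))
  names(df) <- c("gene_id", "peak_score", "length", "binding_surface_score", "is_target")
  df
}
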