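#' Normalize a peak's read count to 10 million aligned reads
#'
#' The peak score is `raw_reads * 1e7 / total_aligned_reads`: the read count
#' the peak would have carried had the library contained exactly ten million
#' aligned reads. This puts samples of different sequencing depth on a common
#' scale before filtering and scoring.
#'
#' @param raw_reads nonnegative read count(s) of the peak region(s).
#' @param total_aligned_reads positive total aligned reads of the library.
#' @return numeric peak score(s), reads per 10 million aligned reads.
#' @examples
#' compute_peak_score(20, 2e8)   # 1.0
#' @export
compute_peak_score <- function(raw_reads, total_aligned_reads) {
  if (!is.numeric(total_aligned_reads) || any(is.na(total_aligned_reads)) ||
      any(total_aligned_reads <= 0)) {
    stop("total_aligned_reads must be positive")
  }
  if (any(raw_reads < 0)) stop("raw_reads must be nonnegative")
  raw_reads * 1e7 / total_aligned_reads
}

#' Binding surface score
#'
#' `log2(peak_score * length)`: a nascent transcript's capacity to tether an
#' RNA-binding protein scales with both how long it is (binding is
#' length-dependent) and how highly it is expressed, so the product of
#' normalized expression and peak-region length is taken as the "binding
#' surface", reported in log2 units.
#'
#' @param peak_score positive peak score(s) (reads per 10 million).
#' @param length positive transcript (peak-region) length(s) in bases.
#' @return numeric score(s) in log2 units.
#' @examples
#' binding_surface_score(2, 1024)   # log2(2048) = 11
#' binding_surface_score(0.1, 10)   # log2(1) = 0
#' @export
binding_surface_score <- function(peak_score, length) {
  if (any(peak_score <= 0)) {
    stop("peak_score must be positive (zero-read peaks are undefined; filter first)")
  }
  if (any(length < 1)) stop("length must be >= 1")
  log2(peak_score * length)
}

#' Discard transcripts with peak score below a threshold
#'
#' Peaks whose score is *strictly smaller* than `min_score` are discarded;
#' a score exactly equal to the threshold is retained. Input order is
#' preserved and the number removed is reported via `message()`.
#'
#' @param transcripts data.frame with at least a `peak_score` column.
#' @param min_score nonnegative threshold; default 0.1 (i.e. 1e-8 of the
#'   library, the score below which a peak is not considered real signal).
#' @return the retained rows of `transcripts`, order preserved.
#' @export
filter_peaks <- function(transcripts, min_score = 0.1) {
  if (!is.numeric(min_score) || length(min_score) != 1L || is.na(min_score) ||
      min_score < 0) {
    stop("min_score must be a single nonnegative number")
  }
  keep <- transcripts$peak_score >= min_score
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message(sprintf("filter_peaks: discarded %d peak(s) with score < %g",
                    n_removed, min_score))
  }
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict scored transcripts to a target gene set
#'
#' Keeps transcripts whose `gene_id` is in `targets` (exact, case-sensitive
#' string match), sets `is_target = TRUE` on the returned rows, and preserves
#' input order. An empty intersection is valid and reported via `message()`.
#'
#' @param transcripts data.frame with `gene_id` (and optionally `is_target`).
#' @param targets character vector of target gene identifiers.
#' @return the matching rows with `is_target` set `TRUE`.
#' @export
subset_by_targets <- function(transcripts, targets) {
  keep <- transcripts$gene_id %in% targets
  out <- transcripts[keep, , drop = FALSE]
  out$is_target <- rep(TRUE, nrow(out))
  if (nrow(out) == 0L) message("subset_by_targets: no transcripts matched the target set")
  rownames(out) <- NULL
  out
}

#' Score a sample's peaks end to end
#'
#' Composite of the per-peak operations: removes zero-read peaks (their
#' binding surface score is undefined and they cannot pass the score filter),
#' computes peak scores normalized to 10 million aligned reads, applies the
#' `min_score` filter, computes binding surface scores, and flags target
#' genes. Each peak region is scored independently even when a gene has
#' several peaks; set `aggregate_by_gene = TRUE` to instead collapse to one
#' record per gene (summed peak score, maximum length) before scoring.
#'
#' @param x a [peak_set()].
#' @param min_score score filter threshold, default 0.1.
#' @param targets optional character vector of target gene ids; used only to
#'   set the `is_target` flag (use [subset_by_targets()] to restrict).
#' @param aggregate_by_gene collapse multiple peaks of one gene first
#'   (default `FALSE`: the unit of analysis is the peak).
#' @return data.frame of scored transcripts: `gene_id`, `peak_score`,
#'   `length`, `binding_surface_score`, `is_target`.
#' @export
score_transcripts <- function(x, min_score = 0.1, targets = NULL,
                              aggregate_by_gene = FALSE) {
  stopifnot(inherits(x, "peak_set"))
  r <- x$records
  nz <- r$raw_reads > 0
  if (any(!nz)) {
    message(sprintf("score_transcripts: removed %d zero-read peak(s)", sum(!nz)))
    r <- r[nz, , drop = FALSE]
  }
  df <- data.frame(
    gene_id = r$gene_id,
    peak_score = compute_peak_score(r$raw_reads, x$total_aligned_reads),
    length = as.integer(r$end - r$start),
    stringsAsFactors = FALSE)
  if (aggregate_by_gene && nrow(df) > 0L) {
    sp <- split(df, df$gene_id)
    df <- do.call(rbind, lapply(sp, function(d) {
      data.frame(gene_id = d$gene_id[1L],
                 peak_score = sum(d$peak_score),
                 length = max(d$length),
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(match(df$gene_id, unique(r$gene_id))), , drop = FALSE]
  }
  df <- filter_peaks(df, min_score)
  df$binding_surface_score <- if (nrow(df) > 0L) {
    binding_surface_score(df$peak_score, df$length)
  } else numeric(0)
  df$is_target <- if (is.null(targets)) rep(FALSE, nrow(df)) else df$gene_id %in% targets
  rownames(df) <- NULL
  df
}

#' Empirical cumulative distribution table
#'
#' Values sorted ascending with cumulative fraction `k/n` at the k-th sorted
#' value; duplicated values appear with their multiplicity, so the final
#' fraction at a repeated value reflects the full step height. Fractions are
#' strictly positive, nondecreasing, and end at exactly 1.
#'
#' @param values numeric vector, at least one value, no NAs.
#' @return data.frame with columns `value` and `fraction`.
#' @export
cumulative_distribution <- function(values) {
  if (length(values) == 0L) stop("cumulative_distribution requires at least one value")
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  data.frame(value = sort(values), fraction = seq_len(n) / n)
}

#' Summarize a sample's scored transcripts
#'
#' @param transcripts data.frame of scored transcripts (already filtered).
#' @return list with `n_peaks`, `total_binding_surface`, `mean_peak_score`,
#'   `mean_binding_surface`; the means are `NA` (flagged undefined) when the
#'   collection is empty.
#' @export
summarize_sample <- function(transcripts) {
  n <- nrow(transcripts)
  if (n == 0L) {
    return(list(n_peaks = 0L, total_binding_surface = 0,
                mean_peak_score = NA_real_, mean_binding_surface = NA_real_))
  }
  list(n_peaks = n,
       total_binding_surface = sum(transcripts$binding_surface_score),
       mean_peak_score = mean(transcripts$peak_score),
       mean_binding_surface = mean(transcripts$binding_surface_score))
}
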