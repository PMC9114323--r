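.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

.input_checksum <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && !dir.exists(x)) {
    unname(tools::md5sum(x))
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- list.files(x, full.names = TRUE)
    as.list(tools::md5sum(files[!dir.exists(files)]))
  } else "in-memory"
}

#' Write a cell image set as a directory of TIFF files
#'
#' One 32-bit TIFF per channel (`<name>.tif`) plus `cell_labels.tif`,
#' `nucleus_labels.tif` and `background_roi.tif`. The inverse of
#' [read_cell_image_dir()].
#'
#' @param images a [cell_image_set()].
#' @param dir destination directory (created if needed).
#' @param scale full-scale intensity for [write_image_tiff()].
#' @return `dir`, invisibly.
#' @export
write_cell_image_dir <- function(images, dir, scale = 65535) {
  stopifnot(inherits(images, "cell_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(images$channels)) {
    write_image_tiff(images$channels[[nm]], file.path(dir, paste0(nm, ".tif")), scale)
  }
  write_image_tiff(images$cell_labels, file.path(dir, "cell_labels.tif"), scale)
  write_image_tiff(images$nucleus_labels, file.path(dir, "nucleus_labels.tif"), scale)
  write_image_tiff(images$background_roi * 1, file.path(dir, "background_roi.tif"), scale)
  invisible(dir)
}

#' Read a cell image set written by [write_cell_image_dir()]
#'
#' @param dir directory holding the TIFF files.
#' @param scale full-scale intensity used at write time.
#' @return a [cell_image_set()].
#' @export
read_cell_image_dir <- function(dir, scale = 65535) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  masks <- c("cell_labels.tif", "nucleus_labels.tif", "background_roi.tif")
  if (!all(masks %in% basename(files))) {
    stop("directory must contain ", paste(masks, collapse = ", "))
  }
  ch_files <- files[!basename(files) %in% masks]
  channels <- lapply(ch_files, read_image_tiff, scale = scale)
  names(channels) <- sub("\\.tif$", "", basename(ch_files))
  cell_image_set(
    channels = channels,
    cell_labels = read_image_tiff(file.path(dir, "cell_labels.tif"), scale, integer = TRUE),
    nucleus_labels = read_image_tiff(file.path(dir, "nucleus_labels.tif"), scale, integer = TRUE),
    background_roi = read_image_tiff(file.path(dir, "background_roi.tif"), scale, integer = TRUE) > 0)
}

.as_peak_set <- function(x, total_aligned_reads, label, count_column, gene_column) {
  if (inherits(x, "peak_set")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (is.null(total_aligned_reads)) {
      stop("total_aligned_reads is required when reading peaks from a file")
    }
    return(read_homer_peaks(x, total_aligned_reads, label,
                            count_column = count_column, gene_column = gene_column))
  }
  stop("expected a peak_set or a file path")
}

#' Run the nascent-transcript scoring pipeline on a control/affected pair
#'
#' Reads (or accepts) both samples' peak sets, scores and filters them,
#' optionally restricts to a target gene list, and writes the full set of
#' artifacts to `out_dir`: scored-transcript tables, ECDF tables of the
#' binding surface score, per-sample summaries, a group-comparison report
#' (TSV and JSON; Mann-Whitney on binding surface scores and on peak scores,
#' plus the percent reduction of mean peak score), and a provenance record
#' (config echo, input checksums, stage counts). Stage counts (parsed,
#' zero-read removed, filtered, retained) are also logged via `message()`.
#'
#' @param control,affected [peak_set()] objects or paths to HOMER-style peak
#'   files.
#' @param out_dir output directory (created if needed).
#' @param total_aligned_reads length-2 numeric (control, affected); required
#'   only when reading from files.
#' @param min_score peak-score filter threshold (default 0.1).
#' @param targets optional target gene list: a character vector or a path
#'   readable by [read_gene_list()].
#' @param alternative sidedness of the rank-sum tests (default two-sided).
#' @param count_column,gene_column passed to [read_homer_peaks()].
#' @return invisibly, a list with the scored tables, summaries and
#'   `group_comparison` objects.
#' @export
run_peak_pipeline <- function(control, affected, out_dir,
                              total_aligned_reads = NULL, min_score = 0.1,
                              targets = NULL, alternative = "two.sided",
                              count_column = NULL, gene_column = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list(control = .input_checksum(control),
                    affected = .input_checksum(affected))
  tar_a <- if (length(total_aligned_reads) >= 1L) total_aligned_reads[[1L]] else NULL
  tar_b <- if (length(total_aligned_reads) >= 2L) total_aligned_reads[[2L]] else tar_a
  ps_a <- .as_peak_set(control, tar_a, "control", count_column, gene_column)
  ps_b <- .as_peak_set(affected, tar_b, "affected", count_column, gene_column)

  target_genes <- NULL
  if (!is.null(targets)) {
    target_genes <- if (is.character(targets) && length(targets) == 1L &&
                        file.exists(targets)) read_gene_list(targets) else targets
  }

  stage_counts <- list()
  score_one <- function(ps, tag) {
    n_parsed <- nrow(ps$records)
    n_zero <- sum(ps$records$raw_reads == 0)
    scored <- score_transcripts(ps, min_score = min_score, targets = target_genes)
    stage_counts[[tag]] <<- list(parsed = n_parsed, zero_read_removed = n_zero,
                                 filtered_out = n_parsed - n_zero - nrow(scored),
                                 retained = nrow(scored))
    message(sprintf("%s: parsed %d, zero-read %d, below min_score %d, retained %d",
                    tag, n_parsed, n_zero, n_parsed - n_zero - nrow(scored),
                    nrow(scored)))
    scored
  }
  sc_a <- score_one(ps_a, "control")
  sc_b <- score_one(ps_b, "affected")

  write_scored_table(sc_a, file.path(out_dir, "scored_control.tsv"))
  write_scored_table(sc_b, file.path(out_dir, "scored_affected.tsv"))

  summaries <- rbind(
    data.frame(sample = "control", as.data.frame(summarize_sample(sc_a))),
    data.frame(sample = "affected", as.data.frame(summarize_sample(sc_b))))
  .write_tsv(summaries, file.path(out_dir, "summaries.tsv"))

  results <- list(scored_control = sc_a, scored_affected = sc_b,
                  summaries = summaries)
  comparisons <- list()

  if (nrow(sc_a) > 0L && nrow(sc_b) > 0L) {
    .write_tsv(cumulative_distribution(sc_a$binding_surface_score),
               file.path(out_dir, "ecdf_control.tsv"))
    .write_tsv(cumulative_distribution(sc_b$binding_surface_score),
               file.path(out_dir, "ecdf_affected.tsv"))
    comparisons$binding_surface <- rank_sum_test(
      sc_a$binding_surface_score, sc_b$binding_surface_score,
      alternative = alternative, labels = c("control", "affected"))
    comparisons$peak_score <- rank_sum_test(
      sc_a$peak_score, sc_b$peak_score,
      alternative = alternative, labels = c("control", "affected"))
    if (!is.null(target_genes)) {
      ta <- subset_by_targets(sc_a, target_genes)
      tb <- subset_by_targets(sc_b, target_genes)
      write_scored_table(ta, file.path(out_dir, "scored_control_targets.tsv"))
      write_scored_table(tb, file.path(out_dir, "scored_affected_targets.tsv"))
      if (nrow(ta) > 0L && nrow(tb) > 0L) {
        comparisons$binding_surface_targets <- rank_sum_test(
          ta$binding_surface_score, tb$binding_surface_score,
          alternative = alternative, labels = c("control", "affected"))
        comparisons$peak_score_targets <- rank_sum_test(
          ta$peak_score, tb$peak_score,
          alternative = alternative, labels = c("control", "affected"))
      }
      results$targets_control <- ta
      results$targets_affected <- tb
    }
    report_df <- do.call(rbind, c(
      Map(function(nm, gc) data.frame(quantity = nm, as.data.frame(gc)),
          names(comparisons), comparisons),
      list(make.row.names = FALSE)))
    .write_tsv(report_df, file.path(out_dir, "comparison.tsv"))
    .write_json(lapply(comparisons, function(gc) unclass(gc)),
                file.path(out_dir, "comparison.json"))
  } else {
    message("no retained transcripts in at least one sample; writing empty report")
    .write_tsv(data.frame(), file.path(out_dir, "comparison.tsv"))
    .write_json(list(), file.path(out_dir, "comparison.json"))
  }
  results$comparisons <- comparisons

  .write_json(list(
    config = list(min_score = min_score, alternative = alternative,
                  total_aligned_reads = list(control = ps_a$total_aligned_reads,
                                             affected = ps_b$total_aligned_reads),
                  n_targets = length(target_genes)),
    input_checksums = checksums,
    stage_counts = stage_counts),
    file.path(out_dir, "provenance.json"))
  invisible(results)
}

#' Run the per-cell fluorescence quantification pipeline
#'
#' Quantifies every condition's image set with [quantify_cells()], writes a
#' per-cell CSV and a per-condition summary CSV, compares the
#' cytoplasmic-to-nuclear ratio of `compare_channel` across conditions
#' (Mann-Whitney for two conditions; Kruskal-Wallis plus Dunn's pairwise
#' z-tests for more), and optionally writes a Pearson correlation report for
#' the per-cell ratios of two channels.
#'
#' @param conditions named list: each element a [cell_image_set()] or a
#'   directory readable by [read_cell_image_dir()].
#' @param out_dir output directory (created if needed).
#' @param channels channels to measure (default: all channels of the first
#'   condition).
#' @param dapi_channel optional DAPI channel name, passed to
#'   [quantify_cells()].
#' @param compare_channel channel whose `cn_ratio` is compared across
#'   conditions (default: first measured channel).
#' @param correlate optional length-2 character vector of channel names whose
#'   per-cell ratios are correlated within each condition.
#' @param background_correct passed to [quantify_cells()].
#' @return invisibly, a list with `measurements`, `summary`, `comparison`
#'   (a `group_comparison`, a [dunn_test()] result, or NULL), and
#'   `correlations`.
#' @export
run_image_pipeline <- function(conditions, out_dir, channels = NULL,
                               dapi_channel = NULL, compare_channel = NULL,
                               correlate = NULL, background_correct = TRUE) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- lapply(conditions, .input_checksum)
  sets <- lapply(conditions, function(x) {
    if (inherits(x, "cell_image_set")) x else read_cell_image_dir(x)
  })
  if (is.null(channels)) channels <- names(sets[[1L]]$channels)
  if (is.null(compare_channel)) compare_channel <- channels[[1L]]

  meas <- Map(function(s, nm) {
    m <- quantify_cells(s, channels_to_measure = channels,
                        dapi_channel = dapi_channel,
                        background_correct = background_correct)
    if (nrow(m) > 0L) cbind(condition = nm, m) else m
    }, sets, names(sets))
  nonempty_meas <- unname(meas[vapply(meas, nrow, 0L) > 0L])
  all_meas <- if (length(nonempty_meas) > 0L) {
    do.call(rbind, c(nonempty_meas, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(all_meas) || nrow(all_meas) == 0L) {
    warning("no cells measured in any condition")
    utils::write.csv(.empty_measurements(), file.path(out_dir, "per_cell.csv"),
                     row.names = FALSE)
    return(invisible(list(measurements = .empty_measurements(), summary = NULL,
                          comparison = NULL, correlations = NULL)))
  }
  utils::write.csv(all_meas, file.path(out_dir, "per_cell.csv"), row.names = FALSE)

  agg <- function(d) data.frame(
    n_cells = length(unique(d$cell_id)),
    mean_cn_ratio = mean(d$cn_ratio, na.rm = TRUE),
    median_cn_ratio = stats::median(d$cn_ratio, na.rm = TRUE),
    mean_dapi_normalized_total = mean(d$dapi_normalized_total, na.rm = TRUE),
    mean_nuclear_concentration = mean(d$nuclear_concentration, na.rm = TRUE))
  sp <- split(all_meas, list(all_meas$condition, all_meas$channel), drop = TRUE)
  summary_df <- do.call(rbind, c(Map(function(nm, d) {
    data.frame(group = nm, channel = d$channel[1L], condition = d$condition[1L],
               agg(d))
  }, names(sp), sp), list(make.row.names = FALSE)))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)

  cmp <- NULL
  ratios_by_cond <- lapply(names(sets), function(nm) {
    d <- all_meas[all_meas$condition == nm & all_meas$channel == compare_channel, ]
    d$cn_ratio[is.finite(d$cn_ratio)]
  })
  names(ratios_by_cond) <- names(sets)
  nonempty <- vapply(ratios_by_cond, length, 0L) > 0L
  if (sum(nonempty) == 2L) {
    pair <- ratios_by_cond[nonempty]
    cmp <- rank_sum_test(pair[[1L]], pair[[2L]], labels = names(pair))
    .write_json(unclass(cmp), file.path(out_dir, "comparison.json"))
  } else if (sum(nonempty) > 2L) {
    vals <- unlist(ratios_by_cond[nonempty], use.names = FALSE)
    grp <- rep(names(ratios_by_cond)[nonempty],
               vapply(ratios_by_cond[nonempty], length, 0L))
    cmp <- dunn_test(vals, grp)
    .write_tsv(cmp$pairwise, file.path(out_dir, "comparison_pairwise.tsv"))
  } else {
    message("single condition: summary only, no comparison")
  }

  correlations <- NULL
  if (!is.null(correlate)) {
    stopifnot(length(correlate) == 2L)
    correlations <- Map(function(nm, d) {
      a <- d$cn_ratio[d$channel == correlate[1L]][order(d$cell_id[d$channel == correlate[1L]])]
      b <- d$cn_ratio[d$channel == correlate[2L]][order(d$cell_id[d$channel == correlate[2L]])]
      ratio_correlation(a, b)
    }, names(sets), split(all_meas, all_meas$condition)[names(sets)])
    .write_json(correlations, file.path(out_dir, "correlation.json"))
  }

  .write_json(list(
    config = list(channels = channels, dapi_channel = dapi_channel,
                  compare_channel = compare_channel,
                  background_correct = background_correct),
    input_checksums = checksums,
    n_cells = lapply(meas, function(m) length(unique(m$cell_id)))),
    file.path(out_dir, "provenance.json"))

  invisible(list(measurements = all_meas, summary = summary_df,
                 comparison = cmp, correlations = correlations))
}
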