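# Fixtures are built in code at test time.

write_toy_homer_file <- function(path, rows,
                                 header = "#PeakID\tchr\tstart\tend\tstrand\tTag Count\tGene Name") {
  writeLines(c("# HOMER Peaks", "# cmd = findPeaks tags/ -style groseq", header,
               rows), path)
  path
}

random_peak_set <- function(n, total_aligned_reads = 1e7, label = "s") {
  start <- sample.int(1e6, n)
  peak_set(data.frame(
    peak_id = sprintf("pk%03d", seq_len(n)),
    gene_id = sprintf("GENE%03d", sample.int(max(2L, n %/% 2L), n, replace = TRUE)),
    chrom = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
    start = start,
    end = start + sample.int(5000, n),
    strand = sample(c("+", "-"), n, replace = TRUE),
    raw_reads = sample.int(500, n),
    stringsAsFactors = FALSE), total_aligned_reads, label)
}

# A 14x14 field with one square cell (not touching the border): whole cell
# rows/cols 3..10, nucleus rows/cols 5..8, background ROI rows/cols 12..14.
# Intensities: `nuclear` inside the nucleus, `cyto` in the cytoplasmic rim,
# plus `offset` everywhere.
one_cell_image <- function(nuclear = 10, cyto = 5, offset = 0,
                           dapi = 50, shape = c(14L, 14L)) {
  lab <- matrix(0L, shape[1], shape[2])
  nuc <- matrix(0L, shape[1], shape[2])
  lab[3:10, 3:10] <- 1L
  nuc[5:8, 5:8] <- 1L
  bg <- matrix(FALSE, shape[1], shape[2])
  bg[12:14, 12:14] <- TRUE
  sig <- matrix(0, shape[1], shape[2])
  sig[lab == 1L] <- cyto
  sig[nuc == 1L] <- nuclear
  dapi_ch <- matrix(0, shape[1], shape[2])
  dapi_ch[nuc == 1L] <- dapi
  cell_image_set(channels = list(signal = sig + offset, dapi = dapi_ch + offset),
                 cell_labels = lab, nucleus_labels = nuc, background_roi = bg)
}
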