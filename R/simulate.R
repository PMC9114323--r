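## Run `code` under a local RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the paired peak-table simulator
#'
#' Defaults emulate the structure the peak analysis assumes: transcript
#' lengths and expression levels log-normally distributed over several orders
#' of magnitude (lengths log10 mean 3.5 / sd 0.6, i.e. a median around 3 kb;
#' expression log10 mean 2 / sd 1), a multiplicative between-condition
#' expression reduction of 10% (the effect size the analysis is meant to
#' detect), a designated target-gene subset (30% of genes), and a library of
#' 1e7 aligned reads so peak scores equal raw read counts. Replicate-level
#' noise is multiplicative log-normal with natural-log sd 0.02, modelling the
#' technical variability of deeply sequenced nascent-RNA libraries; set
#' `noise_model = "poisson"` for count-level realism instead.
#'
#' @param n_transcripts number of transcripts (peak regions) per condition.
#' @param length_log_mean,length_log_sd log10 parameters of transcript length.
#' @param expression_log_mean,expression_log_sd log10 parameters of the
#'   per-transcript base expression (expected reads).
#' @param noise_model `"lognormal"` (default) or `"poisson"`.
#' @param noise_log_sd natural-log sd of the lognormal replicate noise.
#' @param effect_fraction multiplicative expression reduction in the affected
#'   condition, in `[0, 1)`.
#' @param target_fraction fraction of genes designated as RBP targets.
#' @param total_aligned_reads library size recorded in each peak set.
#' @param paired if `TRUE` (default), the two conditions share per-transcript
#'   base expressions and lengths, so the affected condition is the control
#'   scaled by `1 - effect_fraction` plus replicate noise — the design that
#'   makes the global effect recoverable to a fraction of a percentage point.
#'   If `FALSE`, the affected condition's lengths and expressions are drawn
#'   independently from the (scaled) population — the independent-samples
#'   null under which two-sample rank tests are exactly calibrated.
#' @param seed integer RNG seed.
#' @return a `peak_sim_config` list.
#' @export
peak_sim_config <- function(n_transcripts = 2000, length_log_mean = 3.5,
                            length_log_sd = 0.6, expression_log_mean = 2,
                            expression_log_sd = 1,
                            noise_model = c("lognormal", "poisson"),
                            noise_log_sd = 0.02, effect_fraction = 0.10,
                            target_fraction = 0.30,
                            total_aligned_reads = 1e7, paired = TRUE,
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (effect_fraction < 0 || effect_fraction >= 1) {
    stop("effect_fraction must lie in [0, 1)")
  }
  if (target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must lie in [0, 1]")
  }
  if (n_transcripts < 1) stop("n_transcripts must be positive")
  if (total_aligned_reads <= 0) stop("total_aligned_reads must be positive")
  if (noise_log_sd < 0) stop("noise_log_sd must be nonnegative")
  structure(as.list(environment()), class = "peak_sim_config")
}

#' Simulate a control/affected pair of peak sets with known ground truth
#'
#' Each transcript gets a length and a base expression drawn log-normally.
#' In the default paired design the two conditions are independent replicate
#' draws around a shared per-transcript base: the control keeps the base
#' level and the affected condition is scaled by `1 - effect_fraction`, so
#' the expected ratio of mean peak scores is exactly `1 - effect_fraction`
#' and the global effect is recoverable very tightly. Pairing, however, makes
#' the two samples strongly dependent across conditions, so two-sample rank
#' tests applied to a paired pair are conservative; for calibration studies
#' of those tests use `paired = FALSE`, under which the affected condition is
#' an independent draw from the (scaled) population and a zero effect makes
#' the two conditions fully exchangeable with an exactly uniform rank-sum
#' p-value. Lognormal replicate noise has log-median 1. A random
#' `target_fraction` of gene ids forms the target set. Deterministic for a
#' fixed seed.
#'
#' @param config a [peak_sim_config()].
#' @return list with elements `control` and `affected` (both [peak_set()]s),
#'   and `truth` (effect fraction, target genes, per-transcript lengths and
#'   base expression).
#' @export
simulate_peak_pair <- function(config = peak_sim_config()) {
  stopifnot(inherits(config, "peak_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_transcripts
    draw_len <- function() pmax(1L, as.integer(round(
      10^stats::rnorm(n, config$length_log_mean, config$length_log_sd))))
    draw_base <- function() 10^stats::rnorm(n, config$expression_log_mean,
                                            config$expression_log_sd)
    draw <- function(mu) {
      if (config$noise_model == "poisson") {
        stats::rpois(n, mu)
      } else {
        round(mu * exp(stats::rnorm(n, 0, config$noise_log_sd)))
      }
    }
    len <- draw_len()
    base <- draw_base()
    reads_ctrl <- draw(base)
    if (config$paired) {
      len_aff <- len
      reads_aff <- draw(base * (1 - config$effect_fraction))
    } else {
      len_aff <- draw_len()
      reads_aff <- draw(draw_base() * (1 - config$effect_fraction))
    }

    gene_id <- sprintf("G%05d", seq_len(n))
    chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
    start <- as.integer(sample.int(1e8, n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_targets <- round(config$target_fraction * n)
    targets <- sort(sample(gene_id, n_targets))

    rec <- function(reads, lens) data.frame(
      peak_id = sprintf("P%05d", seq_len(n)), gene_id = gene_id, chrom = chrom,
      start = start, end = start + lens, strand = strand, raw_reads = reads,
      stringsAsFactors = FALSE)

    list(control = peak_set(rec(reads_ctrl, len), config$total_aligned_reads, "control"),
         affected = peak_set(rec(reads_aff, len_aff), config$total_aligned_reads, "affected"),
         truth = list(effect_fraction = config$effect_fraction,
                      target_genes = targets, lengths = len,
                      base_expression = base))
  })
}

#' Configuration for the synthetic cell-image simulator
#'
#' Defaults render a field a confocal section might show: 50 non-overlapping
#' round cells in a 512x512 frame, nuclei of radius 8 px inside cells of
#' radius 16 px, nuclear stain intensity 100 (arbitrary units) over a uniform
#' camera background of 10, per-pixel Gaussian noise of sd 5 (5% of the
#' nuclear signal), and a true cytoplasmic-to-nuclear integrated-density
#' ratio of 0.5 — a predominantly nuclear protein such as FUS in unstressed
#' cells.
#'
#' @param n_cells number of cells to place.
#' @param image_shape integer length-2: rows, columns (pixels).
#' @param true_cn_ratio ground-truth ratio of cytoplasmic to nuclear
#'   integrated density (>= 0).
#' @param nuclear_intensity signal intensity inside the nucleus.
#' @param background_level uniform background offset added everywhere.
#' @param noise_sd sd of additive Gaussian noise (clipped at 0).
#' @param nucleus_radius,cell_radius radii in pixels; `cell_radius` must
#'   exceed `nucleus_radius`.
#' @param dapi_intensity DAPI channel intensity inside the nucleus.
#' @param seed integer RNG seed.
#' @return a `cell_sim_config` list.
#' @export
cell_sim_config <- function(n_cells = 50, image_shape = c(512L, 512L),
                            true_cn_ratio = 0.5, nuclear_intensity = 100,
                            background_level = 10, noise_sd = 5,
                            nucleus_radius = 8, cell_radius = 16,
                            dapi_intensity = 100, seed = 1L) {
  if (cell_radius <= nucleus_radius || nucleus_radius <= 0) {
    stop("need cell_radius > nucleus_radius > 0")
  }
  if (true_cn_ratio < 0) stop("true_cn_ratio must be nonnegative")
  if (noise_sd < 0 || background_level < 0) {
    stop("noise_sd and background_level must be nonnegative")
  }
  if (n_cells < 1) stop("n_cells must be positive")
  image_shape <- as.integer(image_shape)
  structure(as.list(environment()), class = "cell_sim_config")
}

#' Simulate a labelled multi-channel cell image with known ground truth
#'
#' Renders disk-shaped cells (a nuclear disk inside a cytoplasmic annulus)
#' at non-overlapping positions found by rejection sampling (bounded at
#' 10,000 proposals). The signal channel carries `nuclear_intensity` in the
#' nucleus and a per-cell cytoplasmic intensity chosen so that the ratio of
#' cytoplasmic to nuclear integrated density equals `true_cn_ratio` exactly
#' before background and noise; the DAPI channel stains nuclei only. A
#' uniform `background_level` is added everywhere, then Gaussian noise of sd
#' `noise_sd`, clipped at 0. Exact whole-cell and nucleus label masks and a
#' staining-free background ROI are emitted alongside. Cells are placed clear
#' of the border (border-cell exclusion is exercised with hand-built masks,
#' not simulated fields). Deterministic for a fixed seed.
#'
#' @param config a [cell_sim_config()].
#' @return list with `images` (a [cell_image_set()] with channels `signal`
#'   and `dapi`) and `truth` (the true ratio, per-cell centers, areas and
#'   cytoplasmic intensity).
#' @export
simulate_cell_image <- function(config = cell_sim_config()) {
  stopifnot(inherits(config, "cell_sim_config"))
  .with_seed(config$seed, {
    nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
    rc <- config$cell_radius; rn <- config$nucleus_radius
    margin <- rc + 2
    if (nr <= 2 * margin || nc <= 2 * margin) stop("image too small for cell_radius")

    centers <- matrix(numeric(0), ncol = 2)
    attempts <- 0L
    while (nrow(centers) < config$n_cells) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop(sprintf(
          "could not place %d non-overlapping cells of radius %g in a %dx%d image within 10000 attempts",
          config$n_cells, rc, nr, nc))
      }
      cand <- c(stats::runif(1, margin + 1, nr - margin),
                stats::runif(1, margin + 1, nc - margin))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
              (2 * rc + 2)^2)) {
        centers <- rbind(centers, cand)
      }
    }

    row_ix <- matrix(seq_len(nr), nr, nc)
    col_ix <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cell_labels <- matrix(0L, nr, nc)
    nucleus_labels <- matrix(0L, nr, nc)
    signal <- matrix(0, nr, nc)
    dapi <- matrix(0, nr, nc)
    min_d2 <- matrix(Inf, nr, nc)
    cyto_intensity <- nuclear_area <- cyto_area <- numeric(config$n_cells)

    for (k in seq_len(config$n_cells)) {
      d2 <- (row_ix - centers[k, 1])^2 + (col_ix - centers[k, 2])^2
      min_d2 <- pmin(min_d2, d2)
      cell_m <- d2 <= rc^2
      nuc_m <- d2 <= rn^2
      cyto_m <- cell_m & !nuc_m
      cell_labels[cell_m] <- k
      nucleus_labels[nuc_m] <- k
      nuclear_area[k] <- sum(nuc_m)
      cyto_area[k] <- sum(cyto_m)
      # cytoplasm intensity giving the target ratio of integrated densities
      cyto_intensity[k] <- config$true_cn_ratio * config$nuclear_intensity *
        nuclear_area[k] / cyto_area[k]
      signal[nuc_m] <- config$nuclear_intensity
      signal[cyto_m] <- cyto_intensity[k]
      dapi[nuc_m] <- config$dapi_intensity
    }

    background_roi <- min_d2 > (rc + 3)^2
    noisy <- function(ch) {
      ch <- ch + config$background_level
      if (config$noise_sd > 0) {
        ch <- ch + stats::rnorm(length(ch), 0, config$noise_sd)
      }
      matrix(pmax(ch, 0), nr, nc)
    }

    list(images = cell_image_set(
           channels = list(signal = noisy(signal), dapi = noisy(dapi)),
           cell_labels = cell_labels, nucleus_labels = nucleus_labels,
           background_roi = background_roi),
         truth = list(true_cn_ratio = config$true_cn_ratio, centers = centers,
                      nuclear_area = nuclear_area, cyto_area = cyto_area,
                      cyto_intensity = cyto_intensity))
  })
}

#' Simulate paired per-cell ratios with a target correlation
#'
#' Draws standard bivariate normal pairs with population correlation
#' `r_target` and maps both coordinates through `exp()` (log-normal ratios,
#' always positive). At `r_target = 1` the two vectors are identical, so the
#' sample Pearson r is exactly 1; away from the extremes the exp mapping
#' attenuates the linear correlation slightly, which is the intended
#' behaviour of ratio-scale data.
#'
#' @param n_cells number of pairs.
#' @param r_target population correlation on the latent normal scale,
#'   in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param log_mean,log_sd location/scale of the latent normals (defaults:
#'   `log(0.5)` and 0.25, i.e. ratios with median 0.5).
#' @return list with numeric vectors `a` and `b`.
#' @export
simulate_ratio_pairs <- function(n_cells, r_target, seed = 1L,
                                 log_mean = log(0.5), log_sd = 0.25) {
  if (abs(r_target) > 1) stop("|r_target| must be <= 1")
  if (n_cells < 1) stop("n_cells must be positive")
  .with_seed(seed, {
    x <- stats::rnorm(n_cells)
    y <- stats::rnorm(n_cells)
    z <- r_target * x + sqrt(1 - r_target^2) * y
    list(a = exp(log_mean + log_sd * x),
         b = exp(log_mean + log_sd * z))
  })
}
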