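#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives all three generators (protein sets, LFQ
#' matrices, image pairs). Defaults encode the data structure the rest of
#' the pipeline assumes: three protein classes (an FC-like class with
#' planted acidic D/E tracts and larger proteins, a DFC-like class with
#' lysine-rich blocks, smaller proteins and an RRM-like annotation, and a
#' background nuclear class); a labelling-time x bait LFQ design with
#' intensity-dependent (MNAR) censoring; and two-channel Gaussian-spot
#' images with an optional peripheral halo in the second channel.
#'
#' @param seed Integer master seed. Each generator derives its own stream
#'   from `(seed, generator-name)`, so adding a generator never perturbs
#'   the others.
#' @param n_per_class Proteins per class.
#' @param length_dist Named list (`FC_like`, `DFC_like`, `nuclear`) of
#'   `c(mean, sd)` sequence lengths in amino acids.
#' @param tract_spec Named list of planted-block definitions per class:
#'   each `list(residues, block_length, count)`; `NULL` entries plant
#'   nothing.
#' @param background_freqs Named numeric of 20 amino-acid frequencies
#'   summing to 1 (default: Swiss-Prot-like average composition).
#' @param lfq_design Data frame with columns `bait`, `labtime` (minutes),
#'   `n_replicates`; one row per bait x labelling-time condition.
#' @param effect_sizes Data frame `bait`, `labtime`, `shift` (log2 units):
#'   planted enrichment of affected proteins for that condition.
#' @param frac_affected Fraction of proteins carrying each bait's effect.
#' @param n_proteins Number of simulated proteins in the LFQ matrix.
#' @param baseline_mean,baseline_sd Per-protein baseline log2 intensity.
#' @param noise_sd Residual log2 noise SD.
#' @param mnar_mid,mnar_slope Logistic censoring: a value `x` is missing
#'   with probability `plogis((mnar_mid - x)/mnar_slope)`, so missingness
#'   is non-increasing in intensity.
#' @param image_spec List: `size_px`, `pixel_size_um`, `spot_sigma_um`,
#'   `halo_radius_um`, `halo_width_um`, `snr` (peak signal-to-noise;
#'   `Inf` = noise-free), `read_noise_sd`, `max_offset_frac` (the spot is
#'   placed near the field centre with a seeded uniform offset up to this
#'   fraction of the field, emulating acquisitions where the condensate is
#'   not pixel-centred), `background` (uniform background level as a
#'   fraction of the peak, emulating cellular autofluorescence; a nonzero
#'   background keeps the mean-normalized correlation amplitudes in the
#'   regime the colocalization statistic assumes).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_class = 50L,
                       length_dist = list(FC_like = c(600, 150),
                                          DFC_like = c(350, 100),
                                          nuclear = c(450, 120)),
                       tract_spec = list(
                         FC_like = list(residues = c("D", "E"),
                                        block_length = 20L, count = 3L),
                         DFC_like = list(residues = "K",
                                         block_length = 15L, count = 3L),
                         nuclear = NULL),
                       background_freqs = NULL,
                       lfq_design = NULL,
                       effect_sizes = NULL,
                       frac_affected = 0.05,
                       n_proteins = 1000L,
                       baseline_mean = 26, baseline_sd = 2,
                       noise_sd = 0.5,
                       mnar_mid = 24, mnar_slope = 1,
                       image_spec = list()) {
  if (is.null(background_freqs)) {
    f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
           E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
           M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
           Y = 2.92, V = 6.87)
    background_freqs <- f / sum(f)
  }
  if (is.null(lfq_design)) {
    lfq_design <- rbind(
      expand.grid(bait = "A_UP", labtime = c(1, 5, 15), stringsAsFactors = FALSE),
      expand.grid(bait = "A_DOWN", labtime = c(1, 3, 5, 15), stringsAsFactors = FALSE),
      expand.grid(bait = "ITS2", labtime = c(1, 5, 15), stringsAsFactors = FALSE))
    lfq_design$n_replicates <- 4L
  }
  if (is.null(effect_sizes)) {
    eff <- lfq_design[lfq_design$bait != "A_UP", c("bait", "labtime")]
    eff$shift <- 2
    effect_sizes <- eff
  }
  stopifnot(setequal(names(background_freqs), AA20))
  if (abs(sum(background_freqs) - 1) > 1e-9) {
    stop("background_freqs must sum to 1")
  }
  stopifnot(all(unlist(lapply(length_dist, `[`, 1)) >= 1),
            all(lfq_design$n_replicates >= 1),
            n_per_class >= 1, n_proteins >= 1, noise_sd >= 0,
            mnar_slope > 0, frac_affected >= 0, frac_affected <= 1)
  spec <- list(size_px = 128L, pixel_size_um = 0.03, spot_sigma_um = 0.25,
               halo_radius_um = 0.5, halo_width_um = 0.1, snr = 10,
               read_noise_sd = 1, max_offset_frac = 1 / 8,
               background = 0.1)
  spec[names(image_spec)] <- image_spec
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 length_dist = length_dist, tract_spec = tract_spec,
                 background_freqs = background_freqs[AA20],
                 lfq_design = lfq_design, effect_sizes = effect_sizes,
                 frac_affected = frac_affected,
                 n_proteins = as.integer(n_proteins),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, mnar_mid = mnar_mid,
                 mnar_slope = mnar_slope, image_spec = spec),
            class = "sim_config")
}

## place `count` non-overlapping blocks of length `len` uniformly at random
## by rejection; returns start positions
place_blocks <- function(seq_len, len, count) {
  if (len > seq_len) stop("tract longer than sequence (sizing error)")
  for (attempt in 1:1000) {
    starts <- sort(sample.int(seq_len - len + 1L, count, replace = TRUE))
    if (count == 1L || all(diff(starts) >= len)) return(starts)
  }
  stop("could not place ", count, " non-overlapping tracts of length ", len,
       " in a sequence of length ", seq_len, " (sizing error)")
}

#' Simulate protein classes with planted compositional signals
#'
#' Draws three labelled protein classes: `FC_like` sequences carry inserted
#' D/E blocks and come from the longest length distribution; `DFC_like`
#' sequences carry lysine blocks, are shorter, and carry one RRM annotation
#' interval; `nuclear` sequences are drawn from the background composition
#' only.
#'
#' @param cfg A [sim_config()].
#' @return List of [protein_record()]s (`n_per_class` per class), labels
#'   attached.
#' @export
simulate_protein_sets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "proteins"))
  classes <- names(cfg$length_dist)
  records <- list()
  for (cl in classes) {
    ld <- cfg$length_dist[[cl]]
    ts <- cfg$tract_spec[[cl]]
    for (i in seq_len(cfg$n_per_class)) {
      L <- max(50L, as.integer(round(rnorm(1, ld[1], ld[2]))))
      chars <- sample(AA20, L, replace = TRUE, prob = cfg$background_freqs)
      ann <- NULL
      if (!is.null(ts)) {
        starts <- place_blocks(L, ts$block_length, ts$count)
        for (s in starts) {
          chars[s:(s + ts$block_length - 1L)] <-
            sample(ts$residues, ts$block_length, replace = TRUE)
        }
      }
      if (cl == "DFC_like") {
        dlen <- min(L, sample(70:90, 1))
        dstart <- sample.int(L - dlen + 1L, 1)
        ann <- data.frame(category = "RRM", start = dstart,
                          end = dstart + dlen - 1L)
      }
      records[[length(records) + 1L]] <- protein_record(
        id = sprintf("%s_%03d", cl, i),
        sequence = paste(chars, collapse = ""),
        annotations = ann, label = cl)
    }
  }
  records
}

#' Simulate a log2-LFQ matrix with planted bait effects and MNAR censoring
#'
#' Each protein gets a baseline log2 intensity; a seeded subset of proteins
#' per bait carries that bait's configured labelling-time-dependent shifts;
#' Gaussian noise is added; each value is then independently censored to
#' missing with logistic probability decreasing in intensity
#' (missing-not-at-random, emulating low-abundance dropout).
#'
#' @param cfg A [sim_config()].
#' @return Object of class `lfq_sim`: list with `lfq` (proteins x samples
#'   log2 matrix, `NA` = missing), `complete` (pre-censoring matrix),
#'   `design` (data.frame `sample_id`, `bait`, `labtime`, `replicate`),
#'   `truth` (data.frame of every nonzero planted effect: `protein`, `bait`,
#'   `labtime`, `shift`), `baseline`, `peptides`.
#' @export
simulate_lfq <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(cfg$lfq_design) > 0)
  set.seed(derive_seed(cfg$seed, "lfq"))
  des <- cfg$lfq_design
  design <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    data.frame(sample_id = sprintf("%s_t%g_r%d", des$bait[i], des$labtime[i],
                                   seq_len(des$n_replicates[i])),
               bait = des$bait[i], labtime = des$labtime[i],
               replicate = seq_len(des$n_replicates[i]),
               stringsAsFactors = FALSE)
  }))
  n <- cfg$n_proteins
  prot <- sprintf("P%04d", seq_len(n))
  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  baits <- unique(cfg$effect_sizes$bait)
  n_aff <- round(cfg$frac_affected * n)
  truth <- NULL
  effect <- matrix(0, n, nrow(design))
  for (b in baits) {
    aff <- sample.int(n, n_aff)
    eff_b <- cfg$effect_sizes[cfg$effect_sizes$bait == b, , drop = FALSE]
    for (k in seq_len(nrow(eff_b))) {
      cols <- which(design$bait == b & design$labtime == eff_b$labtime[k])
      if (!length(cols) || eff_b$shift[k] == 0) next
      effect[aff, cols] <- effect[aff, cols] + eff_b$shift[k]
      truth <- rbind(truth, data.frame(protein = prot[aff], bait = b,
                                       labtime = eff_b$labtime[k],
                                       shift = eff_b$shift[k]))
    }
  }
  complete <- baseline + effect +
    matrix(rnorm(n * nrow(design), 0, cfg$noise_sd), n)
  p_miss <- plogis((cfg$mnar_mid - complete) / cfg$mnar_slope)
  lfq <- complete
  lfq[matrix(runif(length(lfq)), n) < p_miss] <- NA
  dimnames(lfq) <- dimnames(complete) <- list(prot, design$sample_id)
  peptides <- 2L + rpois(n, 8)
  names(peptides) <- prot
  structure(list(lfq = lfq, complete = complete, design = design,
                 truth = truth %||% data.frame(), baseline = baseline,
                 peptides = peptides),
            class = "lfq_sim")
}

#' Simulate a co-registered two-channel spot image pair
#'
#' Channel A is a 2-D Gaussian spot placed near the field centre (seeded
#' sub-field offset); channel B is either the same spot (`halo = FALSE`) or
#' a Gaussian annulus at the configured halo radius (`halo = TRUE`),
#' emulating reduced labelling in the spot core. Noise is Poisson on the
#' signal plus additive Gaussian read noise; `snr = Inf` disables noise.
#'
#' @param cfg A [sim_config()].
#' @param halo Logical; peripheral halo in channel B.
#' @return Object of class `image_pair`: list with matrices `a`, `b`,
#'   `pixel_size` (um/px), `center_px` (spot centre, x/y in pixels), `halo`.
#' @export
simulate_image_pair <- function(cfg, halo = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  sp <- cfg$image_spec
  sigma_px <- sp$spot_sigma_um / sp$pixel_size_um
  if (sp$size_px < 4 * sigma_px) stop("image size must be >= 4x spot sigma")
  set.seed(derive_seed(cfg$seed, "image"))
  n <- sp$size_px
  ctr <- (n + 1) / 2 + runif(2, -sp$max_offset_frac, sp$max_offset_frac) * n
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  r2 <- (xs - ctr[1])^2 + (ys - ctr[2])^2
  spot <- sp$background + (1 - sp$background) * exp(-r2 / (2 * sigma_px^2))
  if (halo) {
    r0 <- sp$halo_radius_um / sp$pixel_size_um
    w <- sp$halo_width_um / sp$pixel_size_um
    b_sig <- sp$background +
      (1 - sp$background) * exp(-(sqrt(r2) - r0)^2 / (2 * w^2))
  } else {
    b_sig <- spot
  }
  noisy <- function(sig) {
    if (!is.finite(sp$snr)) return(sig)
    peak <- sp$snr^2
    counts <- matrix(rpois(length(sig), peak * sig), nrow(sig)) +
      rnorm(length(sig), 0, sp$read_noise_sd)
    pmax(counts, 0) / peak
  }
  structure(list(a = noisy(spot), b = noisy(b_sig),
                 pixel_size = sp$pixel_size_um, center_px = ctr, halo = halo),
            class = "image_pair")
}

#' Radial mean intensity profile about a centre
#'
#' @param img Numeric matrix.
#' @param center `c(x, y)` centre in pixel coordinates.
#' @param bin_width Radial bin width in pixels.
#' @return Data frame `r` (bin centre, px) and `mean_intensity`.
#' @export
radial_mean_profile <- function(img, center, bin_width = 1) {
  n1 <- nrow(img); n2 <- ncol(img)
  xs <- matrix(seq_len(n1), n1, n2)
  ys <- matrix(seq_len(n1), n1, n2, byrow = TRUE)
  r <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  bin <- floor(r / bin_width)
  m <- tapply(as.vector(img), as.vector(bin), mean)
  data.frame(r = (as.numeric(names(m)) + 0.5) * bin_width,
             mean_intensity = as.numeric(m))
}
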