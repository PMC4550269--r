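# Synthetic-data generators. The defaults are the study conditions the
# analysis assumes: n = 298 subjects with a 96/298 male fraction, a
# standardized gene-score -> ReHo path of -0.176, a ReHo -> trait path of
# 0.139 given the gene score, a direct path of 0.399, an outcome rescaled to
# the 27-189 trait scale with mean 122.4 and SD 15.77, TR 2 s, and a
# 0.01-0.08 Hz band for the coherent signal.

#' Configuration for the synthetic study
#'
#' Collects and validates every generator parameter. Defaults encode the
#' emulated study's conditions; see the methods vignette for the rationale
#' behind values the design itself does not pin down (minor-allele
#' frequencies, weights, noise SDs, coherence coupling).
#'
#' @param n_subjects number of subjects.
#' @param maf scored-locus minor-allele frequencies, each in (0, 0.5].
#' @param pool_maf frequencies for the wider permutation pool.
#' @param weights per-locus score weights (signed).
#' @param path_a,path_b,path_c_prime standardized structural coefficients
#'   (gene -> ReHo, ReHo -> trait | gene, direct gene -> trait).
#' @param gender_effect standardized gender coefficient in both equations.
#' @param p_male Bernoulli probability of gender code 1.
#' @param noise_sd_m,noise_sd_y standardized residual SDs (> 0).
#' @param sps_mean,sps_sd,sps_range affine rescaling of the standardized
#'   outcome onto the trait scale, clipped to `sps_range`.
#' @param grid_dims voxel grid (length 3).
#' @param voxel_mm voxel size in mm.
#' @param n_timepoints frames per run (>= 20).
#' @param tr repetition time, seconds.
#' @param band passband (Hz) of the shared in-cluster signal.
#' @param cluster_ijk integer matrix (voxels x 3, 1-based) of planted-cluster
#'   coordinates; default a 3x3x3 block at the grid centre.
#' @param coupling_k slope of the logistic coherence mapping
#'   `lambda(M) = plogis(coupling_k * M)`.
#' @param seed integer seed; every generator is reproducible given it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 298,
                         maf = seq(0.10, 0.45, length.out = 10),
                         pool_maf = seq(0.05, 0.50, length.out = 98),
                         weights = c(1.5, -1.2, 0.9, 1.1, -0.8,
                                     0.7, -1.4, 1.0, 0.6, -0.9),
                         path_a = -0.176, path_b = 0.139,
                         path_c_prime = 0.399,
                         gender_effect = -0.05, p_male = 96 / 298,
                         noise_sd_m = 0.98, noise_sd_y = 0.90,
                         sps_mean = 122.4, sps_sd = 15.77,
                         sps_range = c(27, 189),
                         grid_dims = c(20, 20, 20), voxel_mm = c(3, 3, 3),
                         n_timepoints = 230, tr = 2, band = c(0.01, 0.08),
                         cluster_ijk = NULL, coupling_k = 1,
                         seed = 1L) {
  if (any(maf <= 0 | maf > 0.5) || any(pool_maf <= 0 | pool_maf > 0.5))
    stop("minor-allele frequencies must lie in (0, 0.5]")
  if (length(weights) != length(maf))
    stop("weights must align with the scored loci")
  if (noise_sd_m <= 0 || noise_sd_y <= 0) stop("residual SDs must be > 0")
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (n_timepoints < 20) stop("need at least 20 time points")
  if (is.null(cluster_ijk)) {
    ctr <- pmax(2L, round(grid_dims / 2))
    cluster_ijk <- as.matrix(expand.grid(ctr[1] + (-1:1), ctr[2] + (-1:1),
                                         ctr[3] + (-1:1)))
  }
  cluster_ijk <- as.matrix(cluster_ijk)
  if (any(cluster_ijk < 1) || any(sweep(cluster_ijk, 2, grid_dims) > 0))
    stop("cluster voxels outside the grid")
  out <- list(n_subjects = n_subjects, maf = maf, pool_maf = pool_maf,
              weights = weights, path_a = path_a, path_b = path_b,
              path_c_prime = path_c_prime, gender_effect = gender_effect,
              p_male = p_male, noise_sd_m = noise_sd_m,
              noise_sd_y = noise_sd_y, sps_mean = sps_mean, sps_sd = sps_sd,
              sps_range = sps_range, grid_dims = grid_dims,
              voxel_mm = voxel_mm, n_timepoints = n_timepoints, tr = tr,
              band = band, cluster_ijk = cluster_ijk,
              coupling_k = coupling_k, seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

#' Generate Hardy--Weinberg genotypes
#'
#' Each locus is drawn as two independent Bernoulli(maf) alleles per subject
#' and coded 1/2/3 by minor-allele count 0/1/2.
#'
#' @param config a [synth_config] (or `n`/`maf` given directly).
#' @param n,maf,locus_prefix overrides for pool generation.
#' @param seed RNG seed (default from config).
#' @return a [genotype_matrix].
#' @export
gen_genotypes <- function(config = synth_config(), n = config$n_subjects,
                          maf = config$maf, locus_prefix = "L",
                          seed = config$seed) {
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (n < 2) stop("need at least 2 subjects")
  set.seed(seed)
  codes <- vapply(maf, function(q) {
    1L + stats::rbinom(n, 2L, q)
  }, integer(n))
  genotype_matrix(codes, subject_ids = sprintf("S%03d", seq_len(n)),
                  locus_ids = paste0(locus_prefix, seq_along(maf)))
}

#' Generate subjects with the planted path structure
#'
#' Builds the standardized gene score X from the genotypes and weights, then
#' draws the latent cluster-coherence variable and the trait:
#' `M = a X + g_e G + N(0, sd_m)`,
#' `Y_std = c' X + b M + g_e G + N(0, sd_y)` with G the standardized gender
#' code, and finally rescales `Y_std` to the trait scale (clipped to the
#' admissible range; the clipping rate is < 1% at the default SDs).
#'
#' @param config a [synth_config].
#' @param genotypes optional pre-generated [genotype_matrix].
#' @param seed RNG seed (default `config$seed + 1`).
#' @return list with `subjects` (data frame: subject_id, gender, gene_score,
#'   sps_total), `m_latent`, `clip_rate`.
#' @export
gen_subjects <- function(config = synth_config(), genotypes = NULL,
                         seed = config$seed + 1L) {
  if (is.null(genotypes)) genotypes <- gen_genotypes(config)
  if (ncol(genotypes) != length(config$weights))
    stop("weights do not align with genotype loci")
  set.seed(seed)
  n <- nrow(genotypes)
  w <- stats::setNames(config$weights, colnames(genotypes))
  score <- compute_gene_score(genotypes, w)
  X <- zscore(score)
  gender <- stats::rbinom(n, 1, config$p_male)
  if (stats::sd(gender) == 0) gender[1] <- 1 - gender[1]  # guard tiny n
  G <- zscore(gender)
  M <- config$path_a * X + config$gender_effect * G +
    stats::rnorm(n, 0, config$noise_sd_m)
  Ystd <- config$path_c_prime * X + config$path_b * M +
    config$gender_effect * G + stats::rnorm(n, 0, config$noise_sd_y)
  sps <- config$sps_mean + config$sps_sd * (Ystd - mean(Ystd)) / stats::sd(Ystd)
  clipped <- sps < config$sps_range[1] | sps > config$sps_range[2]
  sps <- pmin(pmax(sps, config$sps_range[1]), config$sps_range[2])
  list(subjects = data.frame(subject_id = rownames(genotypes),
                             gender = gender, gene_score = score,
                             sps_total = sps),
       m_latent = M, clip_rate = mean(clipped))
}

#' Generate a 4D run with coherence coupled to the latent mediator
#'
#' In-cluster voxels share a band-limited signal in proportion
#' `lambda = plogis(coupling_k * m)`:
#' `series = lambda * shared + (1 - lambda) * private noise`, so the
#' cluster's temporal concordance (Kendall's W) increases monotonically with
#' the latent mediator value. Out-of-cluster voxels are pure white noise.
#' The shared signal is white noise ideally band-passed to `config$band`, so
#' downstream temporal filtering preserves it.
#'
#' @param config a [synth_config].
#' @param m_latent the subject's latent coherence value.
#' @param lambda optionally bypass the logistic mapping with a fixed
#'   coherence share in \[0, 1\].
#' @param seed RNG seed.
#' @return a [bold4d].
#' @export
gen_bold <- function(config = synth_config(), m_latent = 0, lambda = NULL,
                     seed = config$seed + 2L) {
  set.seed(seed)
  d <- config$grid_dims
  T <- config$n_timepoints
  lam <- lambda %||% stats::plogis(config$coupling_k * m_latent)
  if (lam < 0 || lam > 1) stop("lambda must be in [0, 1]")
  arr <- array(stats::rnorm(prod(d) * T), dim = c(d, T))
  shared <- band_limited_series(T, config$tr, config$band)
  cl <- config$cluster_ijk
  lin <- cl[, 1] + d[1] * (cl[, 2] - 1) + d[1] * d[2] * (cl[, 3] - 1)
  flat <- matrix(arr, prod(d), T)
  flat[lin, ] <- lam * matrix(shared, length(lin), T, byrow = TRUE) +
    (1 - lam) * flat[lin, ]
  bold4d(array(flat, c(d, T)), voxel_mm = config$voxel_mm, tr = config$tr)
}

# unit-variance white noise ideally band-passed to [low, high] Hz
band_limited_series <- function(T, tr, band) {
  x <- stats::rnorm(T)
  freqs <- seq.int(0, T - 1) / (T * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("run too short to resolve the passband")
  xf <- stats::fft(x)
  xf[!keep] <- 0
  s <- Re(stats::fft(xf, inverse = TRUE)) / T
  s / stats::sd(s)
}

#' Generate a random-walk motion trace
#'
#' Six-parameter head-motion trace as independent Gaussian random walks:
#' translations in mm, rotations in radians.
#'
#' @param n_timepoints number of frames.
#' @param step_sd_trans per-step SD of each translation (mm).
#' @param step_sd_rot per-step SD of each rotation (radians).
#' @param seed RNG seed.
#' @return a [motion_trace].
#' @export
gen_motion <- function(n_timepoints, step_sd_trans = 0.02,
                       step_sd_rot = 4e-4, seed = 1L) {
  if (n_timepoints < 2) stop("need at least 2 frames")
  set.seed(seed)
  steps <- cbind(matrix(stats::rnorm(n_timepoints * 3, 0, step_sd_trans),
                        n_timepoints, 3),
                 matrix(stats::rnorm(n_timepoints * 3, 0, step_sd_rot),
                        n_timepoints, 3))
  steps[1, ] <- 0
  motion_trace(apply(steps, 2, cumsum))
}

#' Write a complete synthetic study to disk
#'
#' Emits the same formats the pipeline reads: genotype and weight TSVs (with
#' the wider permutation pool), a phenotype TSV, per-subject 4D NIfTI
#' volumes, motion text files, and a grey-matter mask NIfTI. Volumes embed
#' the planted coherent cluster driven by each subject's latent mediator.
#'
#' @param config a [synth_config].
#' @param dir output directory (created if needed).
#' @return invisibly, a list of file paths plus the latent mediator vector.
#' @export
simulate_study <- function(config = synth_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geno <- gen_genotypes(config)
  pool <- gen_genotypes(config, maf = config$pool_maf, locus_prefix = "P",
                        seed = config$seed + 11L)
  subj <- gen_subjects(config, geno)
  paths <- list(
    genotypes = file.path(dir, "genotypes.tsv"),
    pool = file.path(dir, "genotype_pool.tsv"),
    weights = file.path(dir, "weights.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    mask = file.path(dir, "mask.nii.gz"))
  write_tsv_table(data.frame(subject_id = rownames(geno), unclass(geno),
                             check.names = FALSE), paths$genotypes)
  write_tsv_table(data.frame(subject_id = rownames(pool), unclass(pool),
                             check.names = FALSE), paths$pool)
  write_tsv_table(data.frame(locus_id = colnames(geno),
                             weight = config$weights), paths$weights)
  write_tsv_table(subj$subjects, paths$phenotypes)
  mask <- array(TRUE, config$grid_dims)
  write_map(mask * 1, paths$mask, voxel_mm = config$voxel_mm)
  vols <- motion <- character(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    vols[i] <- file.path(dir, sprintf("sub%03d_bold.nii.gz", i))
    motion[i] <- file.path(dir, sprintf("sub%03d_motion.txt", i))
    b <- gen_bold(config, subj$m_latent[i], seed = config$seed + 100L + i)
    write_map(b, vols[i])
    write_motion(gen_motion(config$n_timepoints, seed = config$seed + 5000L + i),
                 motion[i])
  }
  manifest <- data.frame(subject_id = subj$subjects$subject_id,
                         volume = vols, motion = motion)
  paths$manifest <- file.path(dir, "volumes.tsv")
  write_tsv_table(manifest, paths$manifest)
  invisible(c(paths, list(m_latent = subj$m_latent,
                          clip_rate = subj$clip_rate)))
}
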