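# End-to-end pipeline driver and its configuration.

#' Build a validated run configuration
#'
#' File paths plus the numeric settings of every stage. Paths are checked at
#' validation time; numeric settings must lie within their documented ranges.
#' Configurations round-trip losslessly through [read_run_config()] /
#' [write_run_config()] (YAML key-value files).
#'
#' @param genotypes,weights,phenotypes,volumes_manifest,mask file paths
#'   (genotype TSV, weights TSV, phenotype TSV, volume/motion manifest TSV,
#'   grey-matter mask NIfTI).
#' @param snp_pool optional genotype TSV of the wider locus pool for the
#'   permutation threshold.
#' @param wm_mask,csf_mask optional nuisance masks (NIfTI).
#' @param alpha per-step significance level.
#' @param voxel_p voxel-level threshold probability for the Monte-Carlo
#'   correction (default `alpha^3`).
#' @param band temporal passband, Hz.
#' @param fwhm_smooth map smoothing FWHM, mm.
#' @param n_discard leading frames to drop.
#' @param n_mc,n_perm,n_boot iteration counts for the Monte-Carlo threshold,
#'   the permutation threshold (0 disables it), and the bootstrap.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param demean_mode `"subtract"` or `"divide"` map normalization.
#' @param weight_policy permutation score weights: `"refit"` or `"unit"`.
#' @param tr_override TR in seconds when volume headers lack one.
#' @param seed integer master seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genotypes, weights, phenotypes, volumes_manifest, mask,
                       snp_pool = NULL, wm_mask = NULL, csf_mask = NULL,
                       alpha = 0.05, voxel_p = alpha^3,
                       band = c(0.01, 0.08), fwhm_smooth = 4, n_discard = 10,
                       n_mc = 1000, n_perm = 1000, n_boot = 5000,
                       connectivity = 26,
                       demean_mode = c("subtract", "divide"),
                       weight_policy = c("refit", "unit"),
                       tr_override = NULL, seed = 1L) {
  demean_mode <- match.arg(demean_mode)
  weight_policy <- match.arg(weight_policy)
  req <- list(genotypes = genotypes, weights = weights,
              phenotypes = phenotypes, volumes_manifest = volumes_manifest,
              mask = mask)
  for (nm in names(req))
    if (!file.exists(req[[nm]])) stop("missing input file for '", nm, "': ", req[[nm]])
  stopifnot_scalar(alpha, "alpha", 1e-6, 0.5)
  stopifnot_scalar(voxel_p, "voxel_p", 1e-12, 1 - 1e-12)
  stopifnot_scalar(fwhm_smooth, "fwhm_smooth", 0, 50)
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(c(req, list(snp_pool = snp_pool, wm_mask = wm_mask,
                        csf_mask = csf_mask, alpha = alpha, voxel_p = voxel_p,
                        band = band, fwhm_smooth = fwhm_smooth,
                        n_discard = n_discard, n_mc = n_mc, n_perm = n_perm,
                        n_boot = n_boot, connectivity = connectivity,
                        demean_mode = demean_mode,
                        weight_policy = weight_policy,
                        tr_override = tr_override, seed = as.integer(seed))),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (nm in c("genotypes", "weights", "phenotypes", "volumes_manifest",
               "mask", "snp_pool", "wm_mask", "csf_mask"))
    cfg[[nm]] <- rel(cfg[[nm]])
  cfg$band <- as.numeric(cfg$band %||% c(0.01, 0.08))
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full gene--brain--trait mediation pipeline
#'
#' Executes, in fixed order: gene scoring; per-subject temporal
#' preprocessing (discard, detrend, band-pass, nuisance regression with
#' motion and mask signals); ReHo mapping; demeaning and smoothing; the
#' voxel-wise three-step mediation scan; residual smoothness estimation and
#' both cluster-extent thresholds (Monte-Carlo simulation and, when a locus
#' pool is configured, random-gene-score permutation), applying the stricter
#' of the two; ROI extraction from surviving clusters; and the ROI path
#' model with bootstrap CIs and leave-one-out validation. Head-motion
#' summaries are correlated with the gene score and the trait as an artifact
#' check. Every stage is seeded from the master seed, so a run is fully
#' reproducible from its configuration.
#'
#' @param config a [run_config].
#' @param out_dir optional directory for the run report, cluster table and
#'   effect map.
#' @param verbose print stage progress.
#' @return object of class `vox_run`: list with `scores`, `reho_stack`,
#'   `scan`, `thresholds`, `clusters`, `roi_fit`, `boot`, `loo`,
#'   `motion_checks`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (verbose) message(msg)
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  say("seed = %d", config$seed)

  # --- gene score ----------------------------------------------------------
  scores <- stage("score", {
    gtab <- read_tsv_table(config$genotypes)
    geno <- genotype_matrix(as.matrix(gtab[, -1, drop = FALSE]),
                            subject_ids = gtab[[1]])
    w <- read_tsv_table(config$weights)
    compute_gene_score(geno, w)
  })
  phen <- read_tsv_table(config$phenotypes)
  phen$gene_score <- scores[match(phen$subject_id, names(scores))]
  say("scored %d subjects over %d loci", length(scores),
      nrow(read_tsv_table(config$weights)))

  # --- imaging arm ---------------------------------------------------------
  mask <- read_mask(config$mask)
  masks <- list(global = mask)
  if (!is.null(config$wm_mask)) masks$wm <- read_mask(config$wm_mask)
  if (!is.null(config$csf_mask)) masks$csf <- read_mask(config$csf_mask)
  manifest <- read_tsv_table(config$volumes_manifest)
  n <- nrow(manifest)
  stack <- NULL
  motion_sum <- matrix(NA_real_, n, 3,
                       dimnames = list(NULL, c("trans", "rot", "fd")))
  resid_maps <- vector("list", min(n, 10L))
  voxel_mm <- attr(mask, "voxel_mm") %||% c(3, 3, 3)
  affine <- attr(mask, "affine")
  for (i in seq_len(n)) {
    res <- stage(sprintf("preprocess[%s]", manifest$subject_id[i]), {
      vol <- read_bold(manifest$volume[i], tr_override = config$tr_override)
      mot <- read_motion(manifest$motion[i])
      dm <- discard_initial(vol, config$n_discard, mot)
      vol <- detrend_linear(dm$vol)
      vol <- bandpass_filter(vol, config$band[1], config$band[2])
      vol <- regress_nuisance(vol, dm$motion, masks)
      ms <- motion_summary(dm$motion)
      fd <- framewise_displacement(dm$motion)
      rh <- reho_map(vol, mask)
      rh <- gaussian_smooth(normalize_reho(rh, config$demean_mode),
                            config$fwhm_smooth)
      list(rh = rh, msum = c(ms$trans_index, ms$rot_index, fd$mean_fd))
    })
    if (is.null(stack)) stack <- matrix(NA_real_, n, sum(mask))
    stack[i, ] <- res$rh[mask]
    motion_sum[i, ] <- res$msum
    if (i <= length(resid_maps)) resid_maps[[i]] <- unclass(res$rh)
  }
  say("ReHo stack: %d subjects x %d voxels", n, ncol(stack))

  ord <- match(manifest$subject_id, phen$subject_id)
  X <- phen$gene_score[ord]; Y <- phen$sps_total[ord]; G <- phen$gender[ord]

  # motion artifact checks
  motion_checks <- do.call(rbind, lapply(colnames(motion_sum), function(nm) {
    data.frame(index = nm,
               r_gene = stats::cor(motion_sum[, nm], X),
               r_trait = stats::cor(motion_sum[, nm], Y))
  }))

  # --- mediation scan and thresholds ---------------------------------------
  scan <- stage("scan", mediation_scan(X, Y, G, stack, alpha = config$alpha))
  say("scan: c = %.3f (p = %.3g), %d significant voxels", scan$c, scan$p_c,
      sum(scan$sig))
  fwhm_est <- stage("fwhm", {
    centred <- lapply(resid_maps, function(m) m - Reduce(`+`, resid_maps) /
                        length(resid_maps))
    estimate_fwhm(centred, mask, voxel_mm)
  })
  say("estimated FWHM = %.2f x %.2f x %.2f mm", fwhm_est[1], fwhm_est[2],
      fwhm_est[3])
  mc <- stage("mc_threshold",
              cluster_threshold_mc(sum(mask), fwhm = pmax(fwhm_est, 0),
                                   voxel_mm = voxel_mm,
                                   voxel_p = config$voxel_p,
                                   alpha = config$alpha, n_iter = config$n_mc,
                                   connectivity = config$connectivity,
                                   seed = config$seed + 1L))
  thresholds <- list(mc = mc$threshold, perm = NA_integer_)
  if (!is.null(config$snp_pool) && config$n_perm > 0) {
    pool_tab <- read_tsv_table(config$snp_pool)
    pool <- genotype_matrix(as.matrix(pool_tab[, -1, drop = FALSE]),
                            subject_ids = pool_tab[[1]])
    pool <- pool[match(manifest$subject_id, rownames(pool)), , drop = FALSE]
    pm <- stage("perm_threshold",
                cluster_threshold_perm(genotype_matrix(pool), Y, G, stack,
                                       mask, n_perm = config$n_perm,
                                       alpha = config$alpha,
                                       step_alpha = config$alpha,
                                       connectivity = config$connectivity,
                                       weight_policy = config$weight_policy,
                                       seed = config$seed + 2L))
    thresholds$perm <- pm$threshold
  } else say("permutation threshold disabled (no pool or n_perm = 0)")
  applied <- max(unlist(thresholds), na.rm = TRUE)
  which_stricter <- if (is.na(thresholds$perm) ||
                        thresholds$mc >= thresholds$perm) "mc" else "perm"
  say("thresholds: MC = %s, permutation = %s; applying the stricter (%s, %d voxels)",
      thresholds$mc, thresholds$perm, which_stricter, applied)
  thresholds$applied <- applied
  thresholds$stricter <- which_stricter

  # --- clusters and ROI model ----------------------------------------------
  sig_arr <- array(FALSE, dim(mask))
  sig_arr[which(mask)[scan$sig]] <- TRUE
  ab_arr <- array(0, dim(mask))
  ab_arr[which(mask)] <- scan$ab
  clusters <- label_clusters(sig_arr, config$connectivity, values = ab_arr,
                             affine = affine, voxel_mm = voxel_mm)
  keep <- clusters$size_vox > applied
  say("%d cluster(s) found, %d exceeding the %d-voxel threshold",
      nrow(clusters), sum(keep), applied)
  roi_fit <- boot <- loo <- NULL
  if (any(keep)) {
    members <- attr(clusters, "members")[keep]
    roi_vox <- match(unlist(members[1]), which(mask))
    roi <- extract_roi_mean(stack, roi_vox)
    dat <- data.frame(sps = Y, gene = X, gender = G, reho_roi = roi)
    roi_fit <- stage("pathfit",
                     path_model(sps ~ gene + gender, mediator = "reho_roi",
                                data = dat))
    boot <- stage("bootstrap",
                  bootstrap_paths(roi_fit, n_boot = config$n_boot,
                                  seed = config$seed + 3L))
    loo <- stage("loo", loo_validate(roi_fit))
    say("ROI model: a = %.3f, b = %.3f, ab = %.4f (%.2f%% of total), %s; LOO r = %.3f",
        roi_fit$a, roi_fit$b, roi_fit$ab, roi_fit$suppression_pct,
        classify_effect(roi_fit), loo$r)
  } else say("no surviving cluster; ROI model skipped")

  out <- structure(list(scores = scores, phenotypes = phen,
                        reho_stack = stack, mask = mask, scan = scan,
                        fwhm = fwhm_est, thresholds = thresholds,
                        clusters = clusters, roi_fit = roi_fit, boot = boot,
                        loo = loo, motion_checks = motion_checks,
                        seed = config$seed, log = log),
                   class = "vox_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(log, file.path(out_dir, "run_report.txt"))
    write_tsv_table(as.data.frame(clusters), file.path(out_dir, "clusters.tsv"))
    if (!is.null(affine))
      write_map(ab_arr, file.path(out_dir, "mediation_ab.nii.gz"),
                affine = affine, voxel_mm = voxel_mm)
  }
  out
}

#' @export
print.vox_run <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
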