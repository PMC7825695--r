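#' Generate a synthetic patient cohort with exact medication counts
#'
#' Draws per-patient binary usage flags with exactly the requested marginal
#' counts and the requested statin/omega-3 overlap, emulating the structure
#' of the studied 91-patient cohort (42 statin users, 28 omega-3 users, 13
#' using both, 35 ACEI users). Counts may be given as integers or as
#' fractions of `n_patients`.
#'
#' @param n_patients cohort size.
#' @param prevalences named list/vector with entries `statin`, `omega3`,
#'   `acei` (missing entries default to 0); counts or fractions.
#' @param overlap number of patients using both statin and omega-3.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return A data.frame with columns `patient_id`, `statin`, `omega3`,
#'   `acei`.
#' @export
generate_cohort <- function(n_patients = 91,
                            prevalences = list(statin = 42, omega3 = 28, acei = 35),
                            overlap = 13, seed = 1) {
  as_count <- function(x) {
    if (is.null(x)) return(0L)
    if (x > 0 && x < 1) x <- x * n_patients
    as.integer(round(x))
  }
  ns <- as_count(prevalences[["statin"]])
  no <- as_count(prevalences[["omega3"]])
  na_ <- as_count(prevalences[["acei"]])
  overlap <- as.integer(overlap)
  for (nm in c("statin", "omega3", "acei")) {
    cnt <- c(statin = ns, omega3 = no, acei = na_)[[nm]]
    if (cnt > n_patients) {
      stop(sprintf("infeasible cohort: %s count %d exceeds n_patients %d", nm, cnt, n_patients),
        call. = FALSE
      )
    }
  }
  if (overlap > min(ns, no)) {
    stop(sprintf(
      "infeasible cohort: overlap %d exceeds min(statin = %d, omega3 = %d)",
      overlap, ns, no
    ), call. = FALSE)
  }
  if (no - overlap > n_patients - ns) {
    stop("infeasible cohort: omega3-only count exceeds the non-statin pool", call. = FALSE)
  }
  set.seed(substream_seed(seed, 0L, "cohort"))
  statin <- integer(n_patients)
  omega3 <- integer(n_patients)
  acei <- integer(n_patients)
  s_idx <- sample.int(n_patients, ns)
  statin[s_idx] <- 1L
  both <- s_idx[sample.int(length(s_idx), overlap)]
  rest <- setdiff(seq_len(n_patients), s_idx)
  o_only <- rest[sample.int(length(rest), no - overlap)]
  omega3[c(both, o_only)] <- 1L
  acei[sample.int(n_patients, na_)] <- 1L
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    statin = statin, omega3 = omega3, acei = acei,
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic pelvic phantom
#'
#' Describes a T2-weighted-like phantom: an ellipsoidal "prostate gland" ROI
#' containing a nested posterior-crescent "peripheral zone" ROI, textured by
#' a Gaussian random field whose mean, standard deviation and correlation
#' length can shift with a binary label, modulated by a smooth multiplicative
#' bias field plus additive Gaussian noise.
#'
#' The peripheral zone is modelled as the part of the gland outside a
#' concentrically shrunken inner ellipsoid and on the posterior side — an
#' anatomically plausible, trivially parameterised stand-in for the manually
#' contoured zone.
#'
#' @param shape grid size in voxels (default `c(64, 64, 32)`).
#' @param spacing voxel spacing in mm (default `c(1, 1, 2)`, i.e. 2 mm
#'   slices).
#' @param gland_center_mm,gland_radii_mm ellipsoid centre and radii, mm.
#' @param peripheral_shrink inner-ellipsoid scale factor delimiting the
#'   peripheral crescent.
#' @param base_mean,texture_sd,correlation_mm Gaussian-random-field
#'   parameters of the gland texture (intensity units / mm).
#' @param effect list of label-1 shifts: `mean` (additive),
#'   `sd_ratio` (multiplicative on texture sd), `correlation_mm` (additive
#'   on correlation length).
#' @param noise_sd additive white-noise sd, intensity units.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (0 disables it).
#' @param seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 32), spacing = c(1, 1, 2),
                         gland_center_mm = NULL, gland_radii_mm = c(20, 16, 12),
                         peripheral_shrink = 0.6,
                         base_mean = 120, texture_sd = 20, correlation_mm = 3,
                         effect = list(mean = 10, sd_ratio = 1.25, correlation_mm = 0),
                         noise_sd = 5, bias_amplitude = 0.2, seed = 1) {
  stopifnot(all(shape >= 8), all(spacing > 0), all(gland_radii_mm > 0))
  stopifnot(peripheral_shrink > 0, peripheral_shrink < 1)
  if (is.null(gland_center_mm)) gland_center_mm <- (shape - 1) * spacing / 2
  effect <- utils::modifyList(list(mean = 0, sd_ratio = 1, correlation_mm = 0), effect)
  structure(
    list(
      shape = as.integer(shape), spacing = spacing,
      gland_center_mm = gland_center_mm, gland_radii_mm = gland_radii_mm,
      peripheral_shrink = peripheral_shrink, base_mean = base_mean,
      texture_sd = texture_sd, correlation_mm = correlation_mm,
      effect = effect, noise_sd = noise_sd, bias_amplitude = bias_amplitude,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# squared normalised ellipsoid coordinate for every voxel centre
.ellipsoid_r2 <- function(shape, spacing, center, radii) {
  ax <- lapply(1:3, function(a) (((seq_len(shape[a]) - 1) * spacing[a]) - center[a]) / radii[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r2
}

#' Generate one phantom volume with gland and peripheral ROI masks
#'
#' Deterministic in `(spec, label)`: the label enters only through the
#' configured effect (applied to shared random draws), so with a zero effect
#' the two label groups are voxelwise identical.
#'
#' @param spec a [phantom_spec()].
#' @param label binary medication label (0/1).
#' @return A list with `volume` ([image_volume()]), `gland` and
#'   `peripheral` ([roi_mask()] objects).
#' @export
generate_phantom <- function(spec, label = 0) {
  stopifnot(inherits(spec, "phantom_spec"), label %in% c(0, 1))
  d <- spec$shape
  sp <- spec$spacing
  r2 <- .ellipsoid_r2(d, sp, spec$gland_center_mm, spec$gland_radii_mm)
  gland <- array(as.integer(r2 <= 1), dim = d)
  inner <- .ellipsoid_r2(d, sp, spec$gland_center_mm, spec$gland_radii_mm * spec$peripheral_shrink)
  posterior <- array(
    rep(((seq_len(d[2]) - 1) * sp[2]) > spec$gland_center_mm[2], each = d[1]),
    dim = d
  )
  periph <- array(as.integer(gland == 1L & inner > 1 & posterior), dim = d)
  if (sum(gland) == 0L || sum(periph) == 0L) {
    stop("phantom ROI empty after voxelization; enlarge the gland or the grid", call. = FALSE)
  }

  set.seed(substream_seed(spec$seed, 0L, "phantom"))
  z_tex <- array(stats::rnorm(prod(d)), dim = d)
  z_noise <- array(stats::rnorm(prod(d)), dim = d)
  z_bias <- array(stats::rnorm(prod(d)), dim = d)

  mu <- spec$base_mean + if (label == 1) spec$effect$mean else 0
  sdv <- spec$texture_sd * if (label == 1) spec$effect$sd_ratio else 1
  corr <- spec$correlation_mm + if (label == 1) spec$effect$correlation_mm else 0

  tex <- .smooth_gaussian(z_tex, corr, sp)
  tsd <- stats::sd(as.vector(tex))
  tex <- if (tsd > 0) tex / tsd else tex
  # background: darker, mildly textured tissue
  vox <- 0.5 * spec$base_mean + 0.5 * spec$texture_sd * tex
  vox[gland == 1L] <- mu + sdv * tex[gland == 1L]
  # peripheral zone slightly brighter, as on T2-weighted images
  vox[periph == 1L] <- vox[periph == 1L] + 0.1 * spec$base_mean
  if (spec$bias_amplitude > 0) {
    bias <- .smooth_gaussian(z_bias, 8 * spec$correlation_mm + 16, sp)
    bias <- bias / max(abs(bias))
    vox <- vox * (1 + spec$bias_amplitude * bias)
  }
  if (spec$noise_sd > 0) vox <- vox + spec$noise_sd * z_noise
  # keep intensities strictly positive for log-domain preprocessing
  vox <- pmax(vox, 1e-3)
  list(
    volume = image_volume(array(vox, dim = d), sp),
    gland = roi_mask(gland, sp),
    peripheral = roi_mask(periph, sp)
  )
}

#' Specification of a synthetic feature table
#'
#' A statistical stand-in for a patients x features radiomic table: columns
#' are unit-variance Gaussians arranged in correlated blocks, with the first
#' `n_informative` columns shifted by `effect` standard deviations in the
#' label-1 group. Informative columns are placed in singleton blocks so each
#' carries independent signal.
#'
#' @param n_patients,n_features table dimensions.
#' @param n_informative number of label-associated columns.
#' @param effect standardized mean difference of informative columns.
#' @param block_r within-block Pearson correlation of noise columns
#'   (`|block_r| < 1`).
#' @param block_size size of correlated noise blocks (1 = independent).
#' @param prevalence fraction of label-1 patients.
#' @param seed integer seed.
#' @return A `table_spec` list.
#' @export
table_spec <- function(n_patients = 91, n_features = 944, n_informative = 6,
                       effect = 1.2, block_r = 0.5, block_size = 4,
                       prevalence = 42 / 91, seed = 1) {
  stopifnot(
    n_informative <= n_features, prevalence > 0, prevalence < 1,
    abs(block_r) < 1 || (block_r == 1 && block_size >= 1), block_size >= 1
  )
  structure(
    list(
      n_patients = n_patients, n_features = n_features,
      n_informative = n_informative, effect = effect, block_r = block_r,
      block_size = as.integer(block_size), prevalence = prevalence,
      seed = as.integer(seed)
    ),
    class = "table_spec"
  )
}

#' Generate a synthetic feature table and matching labels
#'
#' @param spec a [table_spec()].
#' @return A list with `table` (matrix, radiomics-style column names) and
#'   `labels` (0/1 vector with exactly `round(n * prevalence)` ones).
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  n <- spec$n_patients
  p <- spec$n_features
  set.seed(substream_seed(spec$seed, 0L, "table"))
  n1 <- round(n * spec$prevalence)
  labels <- integer(n)
  labels[sample.int(n, n1)] <- 1L

  x <- matrix(stats::rnorm(n * p), n, p)
  # correlated blocks among the noise columns; informative columns stay
  # independent so each carries its own signal
  noise_cols <- seq_len(p) > spec$n_informative
  if (spec$block_size > 1L && spec$block_r != 0) {
    ids <- which(noise_cols)
    nblk <- ceiling(length(ids) / spec$block_size)
    fac <- matrix(stats::rnorm(n * nblk), n, nblk)
    blk <- rep(seq_len(nblk), each = spec$block_size)[seq_along(ids)]
    r <- spec$block_r
    x[, ids] <- sign(r) * sqrt(abs(r)) * fac[, blk] + sqrt(1 - abs(r)) * x[, ids]
  }
  if (spec$n_informative > 0) {
    inf <- seq_len(spec$n_informative)
    x[labels == 1L, inf] <- x[labels == 1L, inf] + spec$effect
  }
  reg <- feature_registry()
  if (p <= length(reg)) {
    colnames(x) <- reg[seq_len(p)]
  } else {
    colnames(x) <- make.unique(rep_len(reg, p), sep = "_v")
  }
  list(table = x, labels = labels)
}

#' Generate a phantom per patient of a cohort
#'
#' Builds one phantom per cohort row, with the texture effect driven by the
#' patient's flag for `drug`. Every patient gets an independent random
#' substream derived from `spec$seed` and the patient index, so patient `i`
#' is reproducible regardless of cohort size.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param spec a [phantom_spec()]; its `seed` acts as the master seed.
#' @param drug label column that drives the texture effect.
#' @return A list with `volumes`, `glands`, `peripherals` (named by
#'   patient), and the cohort.
#' @export
generate_phantom_cohort <- function(cohort, spec = phantom_spec(), drug = "statin") {
  stopifnot(inherits(spec, "phantom_spec"), drug %in% colnames(cohort))
  vols <- glands <- periphs <- stats::setNames(
    vector("list", nrow(cohort)), cohort$patient_id
  )
  for (i in seq_len(nrow(cohort))) {
    pspec <- spec
    pspec$seed <- substream_seed(spec$seed, i, "patient")
    ph <- generate_phantom(pspec, label = cohort[[drug]][i])
    vols[[i]] <- ph$volume
    glands[[i]] <- ph$gland
    periphs[[i]] <- ph$peripheral
  }
  list(volumes = vols, glands = glands, peripherals = periphs, cohort = cohort)
}

#' Write a synthetic dataset to disk with a checksum manifest
#'
#' Volumes and masks go to NIfTI, labels and feature tables to CSV; a JSON
#' manifest lists every file with its md5 checksum so the dataset can be
#' re-verified after transfer.
#'
#' @param dir output directory (created if needed).
#' @param cohort data.frame from [generate_cohort()].
#' @param phantoms optional named list of [generate_phantom()] outputs.
#' @param table optional feature matrix (rows = patients).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_dataset <- function(dir, cohort = NULL, phantoms = NULL, table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create dataset directory: ", dir, call. = FALSE)
  files <- character(0)
  if (!is.null(cohort)) {
    f <- file.path(dir, "labels.csv")
    utils::write.csv(cohort, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(table)) {
    f <- file.path(dir, "features.csv")
    utils::write.csv(as.data.frame(table), f, row.names = TRUE)
    files <- c(files, f)
  }
  for (nm in names(phantoms)) {
    ph <- phantoms[[nm]]
    fv <- file.path(dir, paste0(nm, "_volume.nii.gz"))
    fg <- file.path(dir, paste0(nm, "_gland.nii.gz"))
    fp <- file.path(dir, paste0(nm, "_peripheral.nii.gz"))
    write_nifti(ph$volume, fv)
    write_nifti(ph$gland, fg)
    write_nifti(ph$peripheral, fp)
    files <- c(files, fv, fg, fp)
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Verify a dataset against its manifest
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A data.frame with per-file `ok`; attribute `valid` is TRUE when
#'   all checksums match.
#' @export
verify_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  now <- unname(tools::md5sum(file.path(dir, mf$file)))
  mf$ok <- !is.na(now) & now == mf$md5
  attr(mf, "valid") <- all(mf$ok)
  mf
}

#' Read back a feature table written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return Numeric matrix with patient row names.
#' @export
read_feature_table <- function(dir) {
  df <- utils::read.csv(file.path(dir, "features.csv"), row.names = 1, check.names = FALSE)
  as.matrix(df)
}
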