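#' Configuration for the synthetic D-PET cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: SUV-like intensities (masked maxima drawn around 32 within
#' 14-65), ellipsoidal tumors with a core-rim metabolic gradient, and two
#' partially independent label-dependent signal channels — (a) the spatial
#' correlation length and core-rim contrast of the intratumoral texture
#' (detectable by handcrafted features) and (b) the number of focal
#' high-uptake spots (a geometric cue suited to image-level models) — plus
#' weakly informative clinical covariates. Class 1 is pathologic complete
#' response.
#'
#' @param n_cases primary-cohort size.
#' @param prevalence probability of label 1 in the primary cohort.
#' @param test2_n,test2_prevalence size and prevalence of the separately
#'   generated second test block (defaults emulate a small imbalanced
#'   temporally separated cohort).
#' @param grid integer length-3 volume shape.
#' @param spacing isotropic voxel size in mm (device spacing is not asserted;
#'   this is a configurable emulation choice).
#' @param suv_mean,suv_range location and admissible range for the per-case
#'   masked-maximum intensity draw (dimensionless SUV-like units).
#' @param tumor_radius_range ellipsoid semi-axis range in mm.
#' @param texture_granularity_by_label per-class texture correlation length
#'   in mm, `c(class0, class1)`.
#' @param rim_core_contrast_by_label per-class core/rim uptake ratio.
#' @param fragmentation_by_label per-class count of focal high-uptake spots.
#' @param texture_amplitude relative amplitude of the correlated texture.
#' @param focus_amplitude,focus_sigma relative height and width (mm) of the
#'   focal spots.
#' @param noise_sd background noise standard deviation (relative units).
#' @param clinical_effects named log-odds-scale shifts for the clinical
#'   covariates (weak by default so the clinical baseline stays mediocre).
#' @param seed integer global seed; all stages derive their own streams.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 129L,
                             prevalence = 0.655,
                             test2_n = 18L,
                             test2_prevalence = 0.778,
                             grid = c(32L, 32L, 32L),
                             spacing = 1,
                             suv_mean = 32.2,
                             suv_range = c(14, 65),
                             tumor_radius_range = c(4, 7),
                             texture_granularity_by_label = c(5, 3),
                             rim_core_contrast_by_label = c(1.6, 2.2),
                             fragmentation_by_label = c(1L, 3L),
                             texture_amplitude = 0.25,
                             focus_amplitude = 0.8,
                             focus_sigma = 2,
                             noise_sd = 0.08,
                             clinical_effects = c(age = -0.1, ki67 = 0.3,
                                                  cT = -0.3, cN = -0.2,
                                                  grade = 0.2, regimen = 0.1,
                                                  suvmax = 0.2),
                             seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1,
            test2_prevalence > 0, test2_prevalence < 1,
            all(tumor_radius_range > 0),
            suv_range[1] > 0, suv_range[1] < suv_range[2],
            suv_mean >= suv_range[1], suv_mean <= suv_range[2])
  if (max(tumor_radius_range) / spacing > min(grid) / 2 - 2)
    stop("tumor radius too large for the configured grid")
  structure(as.list(environment()), class = "generator_config")
}

draw_clinical <- function(label, eff, suvmax) {
  # Weak label-dependent shifts: continuous covariates get a mean shift of
  # (effect x scale), ordinal/categorical draws get tilted probabilities.
  tilt <- function(p, delta) { q <- p * exp(delta * seq_along(p)); q / sum(q) }
  age <- rnorm(1, 52 - 5 * eff[["age"]] * (label - 0.5) * -2, 10)
  ki67 <- min(95, max(5, rnorm(1, 55 + 12 * eff[["ki67"]] * (label - 0.5) * 2, 18)))
  cT <- sample(1:4, 1, prob = tilt(c(0.03, 0.6, 0.1, 0.27), eff[["cT"]] * (label - 0.5) * 2))
  cN <- sample(1:3, 1, prob = tilt(c(0.58, 0.2, 0.22), eff[["cN"]] * (label - 0.5) * 2))
  grade <- sample(2:3, 1, prob = tilt(c(0.37, 0.63), eff[["grade"]] * (label - 0.5) * 2))
  regimen <- sample(c("TCbHP", "PCbHP"), 1,
                    prob = tilt(c(0.67, 0.33), eff[["regimen"]] * (label - 0.5) * 2))
  data.frame(age = round(age, 1), ki67 = round(ki67, 1), cT = cT, cN = cN,
             grade = grade, regimen = regimen, suvmax = suvmax, label = label)
}

#' Generate one labeled synthetic D-PET case
#'
#' @param config a [generator_config].
#' @param label 0 or 1.
#' @param seed integer seed for this case.
#' @return A `synthetic_case` list with `volume`, `mask`, `clinical` (one-row
#'   data frame), `label` and `truth` (planted parameters).
#' @export
generate_case <- function(config, label, seed = 1L) {
  set.seed(seed)
  g <- config$grid
  sp <- rep(config$spacing, 3)
  cls <- label + 1L
  radii <- runif(3, config$tumor_radius_range[1], config$tumor_radius_range[2]) / config$spacing
  center <- g / 2 + runif(3, -1, 1)
  ax <- lapply(1:3, function(k) (seq_len(g[k]) - center[k]))
  rx <- ax[[1]] / radii[1]; ry <- ax[[2]] / radii[2]; rz <- ax[[3]] / radii[3]
  r2 <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`)
  mask <- r2 <= 1
  if (sum(mask) < 16L) stop("tumor radius too small for the configured grid")

  contrast <- config$rim_core_contrast_by_label[cls]
  profile <- ifelse(mask, 1 + (contrast - 1) * pmax(1 - r2, 0), 0)

  gran <- config$texture_granularity_by_label[cls] / config$spacing
  tex <- gauss_smooth3(array(rnorm(prod(g)), g), rep(gran / 2, 3))
  tex <- tex / max(sd(tex), 1e-12) * config$texture_amplitude

  foci <- array(0, g)
  nf <- config$fragmentation_by_label[cls]
  in_core <- which(mask & r2 < 0.7)
  fs <- config$focus_sigma / config$spacing
  if (nf > 0 && length(in_core) > 0) {
    picks <- sample(in_core, nf, replace = length(in_core) < nf)
    pos <- arrayInd(picks, g)
    for (i in seq_len(nrow(pos))) {
      d2 <- outer(outer((seq_len(g[1]) - pos[i, 1])^2,
                        (seq_len(g[2]) - pos[i, 2])^2, `+`),
                  (seq_len(g[3]) - pos[i, 3])^2, `+`)
      foci <- foci + config$focus_amplitude * exp(-d2 / (2 * fs^2))
    }
  }

  intensity <- profile * (1 + tex) + foci * mask +
    0.05 + config$noise_sd * array(rnorm(prod(g)), g)
  target <- min(max(rnorm(1, config$suv_mean, 10), config$suv_range[1]),
                config$suv_range[2])
  s <- target / max(intensity[mask])
  intensity <- intensity * s

  suvmax <- max(intensity[mask])
  structure(list(
    volume = pet_volume(intensity, spacing = sp),
    mask = roi_mask(array(as.integer(mask), g), spacing = sp),
    clinical = draw_clinical(label, config$clinical_effects, suvmax),
    label = label,
    truth = list(granularity = config$texture_granularity_by_label[cls],
                 contrast = contrast, n_foci = nf)),
    class = "synthetic_case")
}

#' Generate a full synthetic cohort with partitions
#'
#' The primary cohort is split 70/30 stratified by label into `train` and
#' `test1` (largest-remainder allocation, so 129 cases give 90/39); a second
#' block with its own prevalence is generated independently and tagged
#' `test2`.
#'
#' @param config a [generator_config].
#' @return A `synthetic_cohort` list: `cases` (list of [generate_case]
#'   outputs), `split` (data frame `case_id`, `partition`, `label`),
#'   `clinical` (per-case covariate table) and `truth` (planted parameters).
#' @export
generate_cohort <- function(config) {
  if (config$n_cases < 10L) stop("n_cases must be >= 10")
  set.seed(derive_seed(config$seed, "labels"))
  labels <- rbinom(config$n_cases, 1L, config$prevalence)
  if (length(unique(labels)) < 2L)
    stop("degenerate prevalence: a label stratum is empty")
  labels2 <- rbinom(config$test2_n, 1L, config$test2_prevalence)
  partition <- stratified_split(labels, 0.3, derive_seed(config$seed, "split"))
  all_labels <- c(labels, labels2)
  all_part <- c(partition, rep("test2", config$test2_n))
  cases <- lapply(seq_along(all_labels), function(i)
    generate_case(config, all_labels[i], derive_seed(config$seed, paste0("case", i))))
  clinical <- do.call(rbind, lapply(cases, `[[`, "clinical"))
  clinical <- cbind(case_id = seq_along(cases), clinical,
                    partition = all_part)
  truth <- do.call(rbind, lapply(cases, function(cs) as.data.frame(cs$truth)))
  truth <- cbind(case_id = seq_along(cases), truth)
  structure(list(cases = cases,
                 split = data.frame(case_id = seq_along(cases),
                                    partition = all_part, label = all_labels),
                 clinical = clinical, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$cases), "cases:",
      paste(names(table(x$split$partition)), table(x$split$partition),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits uncompressed NIfTI volumes/masks plus `clinical.csv`, `split.csv`
#' and `truth.csv` (the planted parameters).
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$cases)) {
    write_volume(cohort$cases[[i]]$volume,
                 file.path(dir, sprintf("case%03d_vol.nii", i)))
    write_volume(cohort$cases[[i]]$mask,
                 file.path(dir, sprintf("case%03d_mask.nii", i)))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$split, file.path(dir, "split.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
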