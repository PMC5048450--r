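# Synthetic kidney phantom: a 2D coronal slice with an elliptical
# whole-kidney mask split into a one-voxel cortical rim and medullary
# interior, region-wise ground-truth IVIM and T2* parameters, Gaussian
# acquisition noise set by a target SNR, and drug-challenge transforms that
# rescale the ground truth.
#
# SNR convention: acquisitions are screened so that EVERY image in the
# series has SNR above the target, so the noise SD is anchored to the
# weakest image of a series (largest b-value or echo time), not to the
# unattenuated s0: noise_sigma = min kidney signal across the series
# divided by snr_target.

CHALLENGE_TIMEPOINTS <- c("2m15s", "6m51s", "11m24s")

#' Reference renal parameter values
#'
#' Baseline ground-truth parameter sets for healthy rat kidney at 1.5 T,
#' used to seed the phantom: whole-kidney, cortex and medulla values of the
#' perfusion fraction f, tissue diffusivity D, pseudodiffusion D*, and
#' T2*. Values are representative baseline medians from repeat renal
#' IVIM/BOLD measurements.
#'
#' @param uniform If `TRUE`, the cortex and medulla are both given the
#'   whole-kidney values (a homogeneous kidney, convenient when the target
#'   of a simulation is whole-kidney parameter recovery). If `FALSE`
#'   (default) the cortex and medulla carry distinct values.
#' @param s0 Baseline signal amplitude (arbitrary units).
#' @return Named list of per-region parameter lists with elements
#'   `f`, `d`, `d_star` (mm^2/s) and `t2_star` (ms), plus `s0`.
#' @export
default_kidney_params <- function(uniform = FALSE, s0 = 1000) {
  kidney <- list(s0 = s0, f = 0.269, d = 124.5e-5, d_star = 4.0e-2,
                 t2_star = 32.8)
  if (uniform) {
    list(cortex = kidney, medulla = kidney)
  } else {
    list(cortex = list(s0 = s0, f = 0.271, d = 105.0e-5, d_star = 3.7e-2,
                       t2_star = 32.8),
         medulla = list(s0 = s0, f = 0.234, d = 133.0e-5, d_star = 4.2e-2,
                        t2_star = 32.8))
  }
}

#' Phantom specification
#'
#' Geometry, ground truth, and noise model for the synthetic kidney slice.
#' The default ellipse (semi-axes 6.5 x 4.5 voxels on a 32 x 32 grid)
#' contains 89 whole-kidney voxels with a 28-voxel cortical rim, matching
#' typical rodent renal ROI sizes at clinical resolution (about 91 and 28
#' voxels respectively).
#'
#' @param grid Slice dimensions in voxels, length 2.
#' @param semi_axes Ellipse semi-axes (voxels), length 2.
#' @param centre Ellipse centre (voxel coordinates); defaults to the grid
#'   centre voxel.
#' @param region_params Per-region ground truth, as from
#'   [default_kidney_params()].
#' @param snr_target Target signal-to-noise ratio of the weakest image in
#'   an acquired series (the largest b-value or echo time); default 20,
#'   reflecting the screening criterion that SNR exceeds 20 on every image
#'   used for fitting. The per-stack noise SD is derived as
#'   (minimum kidney forward-model signal across the series) / snr_target.
#' @param noise_sigma Noise standard deviation; overrides `snr_target` when
#'   given.
#' @param kidney_count_band Acceptable whole-kidney voxel count range;
#'   geometry outside it is rejected. Default 91 +/- 12.
#' @param seed Integer seed making phantom construction reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L), semi_axes = c(6.5, 4.5),
                         centre = NULL,
                         region_params = default_kidney_params(),
                         snr_target = 20, noise_sigma = NULL,
                         kidney_count_band = c(79, 103), seed = 1L) {
  if (length(grid) != 2L || any(grid < 5))
    stop_invalid("grid must be two dimensions of at least 5 voxels")
  if (length(semi_axes) != 2L || any(semi_axes <= 0))
    stop_invalid("semi_axes must be two positive lengths")
  if (is.null(centre)) centre <- floor(grid / 2)
  if (!is.null(noise_sigma) && noise_sigma < 0)
    stop_invalid("noise_sigma must be >= 0")
  if (is.null(noise_sigma) && snr_target <= 0)
    stop_invalid("snr_target must be positive")
  if (!all(c("cortex", "medulla") %in% names(region_params)))
    stop_invalid("region_params must name cortex and medulla")
  structure(list(grid = as.integer(grid), semi_axes = semi_axes,
                 centre = centre, region_params = region_params,
                 snr_target = snr_target, noise_sigma = noise_sigma,
                 kidney_count_band = kidney_count_band,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Noise SD for a stack: the explicit noise_sigma when given, otherwise the
# minimum kidney signal of the series (decay is monotone, so the last
# abscissa) divided by the target SNR.
stack_sigma <- function(phantom, abscissa, forward) {
  if (!is.null(phantom$spec$noise_sigma)) return(phantom$spec$noise_sigma)
  in_kid <- phantom$regions$labels > 0L
  s_min <- min(forward(phantom, max(abscissa))[in_kid])
  s_min / phantom$spec$snr_target
}

elliptical_mask <- function(grid, semi_axes, centre) {
  xs <- matrix(rep(seq_len(grid[1]), grid[2]), grid[1], grid[2])
  ys <- matrix(rep(seq_len(grid[2]), each = grid[1]), grid[1], grid[2])
  (((xs - centre[1]) / semi_axes[1])^2 +
   ((ys - centre[2]) / semi_axes[2])^2) <= 1
}

#' Build the phantom ground truth
#'
#' Constructs the labelled slice: background / cortex (one-voxel rim) /
#' medulla (interior), with per-voxel true parameter maps constant within
#' each region. Deterministic given the spec (and its seed).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `kidney_phantom` holding the `region_set`,
#'   true parameter maps (`s0`, `f`, `d`, `d_star`, `t2_star`), and the
#'   spec.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  mask <- elliptical_mask(spec$grid, spec$semi_axes, spec$centre)
  n_kid <- sum(mask)
  if (n_kid < spec$kidney_count_band[1] || n_kid > spec$kidney_count_band[2])
    stop_invalid("kidney mask has ", n_kid, " voxels, outside the accepted ",
                 "band [", spec$kidney_count_band[1], ", ",
                 spec$kidney_count_band[2], "]; adjust semi_axes or the band")
  regions <- derive_regions(mask * 1, provenance = "phantom truth")
  truth <- list()
  for (par in c("s0", "f", "d", "d_star", "t2_star")) {
    m <- matrix(NA_real_, spec$grid[1], spec$grid[2])
    m[regions$labels == 1L] <- spec$region_params$cortex[[par]]
    m[regions$labels == 2L] <- spec$region_params$medulla[[par]]
    truth[[par]] <- m
  }
  structure(list(regions = regions, truth = truth, spec = spec),
            class = "kidney_phantom")
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat("<kidney_phantom>\n")
  cat(sprintf("  grid %dx%d, kidney %d voxels (cortex %d, medulla %d)\n",
              x$spec$grid[1], x$spec$grid[2],
              x$regions$n_voxels[["whole_kidney"]],
              x$regions$n_voxels[["cortex"]],
              x$regions$n_voxels[["medulla"]]))
  if (!is.null(x$spec$noise_sigma)) {
    cat(sprintf("  noise sigma %.3g (explicit)\n", x$spec$noise_sigma))
  } else {
    cat(sprintf("  SNR target %.3g at the weakest image of a series\n",
                x$spec$snr_target))
  }
  invisible(x)
}

add_noise <- function(clean, noise_sigma, noise_model) {
  if (noise_sigma == 0) return(clean)
  n <- length(clean)
  if (noise_model == "gaussian") {
    clean + rnorm(n, 0, noise_sigma)
  } else {
    # Rician magnitude: |signal + complex Gaussian noise|
    re <- clean + rnorm(n, 0, noise_sigma)
    im <- rnorm(n, 0, noise_sigma)
    sqrt(re^2 + im^2)
  }
}

simulate_stack <- function(phantom, abscissa, forward, noise_sigma,
                           seed, noise_model) {
  if (is.null(noise_sigma)) noise_sigma <- stack_sigma(phantom, abscissa, forward)
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  if (length(abscissa) < 1L || any(diff(abscissa) <= 0) || any(abscissa < 0))
    stop_invalid("acquisition scheme must be non-empty, strictly increasing, >= 0")
  if (!is.null(seed)) set.seed(seed)
  grid <- dim(phantom$regions$labels)
  stack <- array(0, c(grid, length(abscissa)))
  in_kid <- phantom$regions$labels > 0L
  for (k in seq_along(abscissa)) {
    slice <- matrix(0, grid[1], grid[2])
    slice[in_kid] <- forward(phantom, abscissa[k])[in_kid]
    stack[, , k] <- add_noise(slice, noise_sigma, noise_model)
  }
  attr(stack, "abscissa") <- abscissa
  attr(stack, "noise_sigma") <- noise_sigma
  stack
}

#' Simulate a multi-b-value DWI stack
#'
#' Per voxel, the biexponential IVIM forward model of the phantom's true
#' parameters is evaluated at each b-value and additive Gaussian noise is
#' applied (background voxels are noise only). The optional Rician mode
#' applies magnitude (two-channel) noise instead.
#'
#' @param phantom A `kidney_phantom` from [make_phantom()].
#' @param b_scheme b-values (s/mm^2), strictly increasing.
#' @param noise_sigma Noise SD; defaults to the phantom's SNR-target
#'   convention (minimum kidney signal of the series / snr_target).
#' @param seed Integer seed; identical seeds give identical stacks.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return 3D array `[x, y, b]` with the b-values in `attr(, "abscissa")`.
#' @export
simulate_dwi <- function(phantom, b_scheme = dwi_b_scheme(),
                         noise_sigma = NULL, seed = NULL,
                         noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  fwd <- function(ph, b) {
    ph$truth$s0 * (ph$truth$f * exp(-b * ph$truth$d_star) +
                   (1 - ph$truth$f) * exp(-b * ph$truth$d))
  }
  simulate_stack(phantom, b_scheme, fwd, noise_sigma, seed, noise_model)
}

#' Simulate a multi-echo BOLD stack
#'
#' As [simulate_dwi()] but with the monoexponential T2* forward model at
#' each echo time.
#'
#' @inheritParams simulate_dwi
#' @param te_scheme Echo times (ms), strictly increasing.
#' @return 3D array `[x, y, te]` with the echo times in `attr(, "abscissa")`.
#' @export
simulate_bold <- function(phantom, te_scheme = bold_te_scheme(),
                          noise_sigma = NULL, seed = NULL,
                          noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  fwd <- function(ph, te) ph$truth$s0 * exp(-te / ph$truth$t2_star)
  simulate_stack(phantom, te_scheme, fwd, noise_sigma, seed, noise_model)
}

default_challenge_multipliers <- function(drug) {
  # Pre -> post scale factors for whole-kidney parameters, encoding the
  # characteristic renal responses: hydralazine (vasodilator) lowers D and
  # T2* while raising f and D*; furosemide (loop diuretic) raises D and
  # T2*; angiotensin II (vasoconstrictor) transiently lowers T2*.
  # T2* multipliers are per post-administration timepoint.
  switch(drug,
    none = list(f = 1, d = 1, d_star = 1, t2_star = c(1, 1, 1)),
    hydralazine = list(f = 15.1 / 10.9, d = 100.2 / 133.9, d_star = 5.0 / 4.0,
                       t2_star = c(36.7, 34.5, 30.2) / 37.7),
    furosemide = list(f = 10.1 / 12.0, d = 138.8 / 118.8, d_star = 3.8 / 3.6,
                      t2_star = c(44.7, 48.5, 47.8) / 38.5),
    angiotensin_ii = list(f = 18.7 / 19.3, d = 115.0 / 118.8,
                          d_star = 5.1 / 4.3,
                          t2_star = c(29.8, 29.4, 30.7) / 34.5),
    stop_invalid("unknown drug: ", drug))
}

#' Drug-challenge transform
#'
#' Per-parameter multiplicative pre-to-post scale factors applied to the
#' phantom ground truth. Built-in defaults encode the characteristic renal
#' response to each agent; `t2_star` multipliers are a vector over the
#' three post-administration BOLD timepoints (2m15s, 6m51s, 11m24s).
#'
#' @param drug One of `"none"`, `"hydralazine"`, `"furosemide"`,
#'   `"angiotensin_ii"`.
#' @param multipliers Optional named list overriding any of `f`, `d`,
#'   `d_star` (scalars) and `t2_star` (length-3 vector); all must be > 0.
#' @return An object of class `challenge_transform`.
#' @export
challenge_transform <- function(drug = c("none", "hydralazine", "furosemide",
                                         "angiotensin_ii"),
                                multipliers = NULL) {
  if (is.character(drug) && length(drug) == 1L &&
      !drug %in% c("none", "hydralazine", "furosemide", "angiotensin_ii"))
    stop_invalid("unknown drug: ", drug)
  drug <- match.arg(drug)
  mult <- default_challenge_multipliers(drug)
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), names(mult))
    if (length(bad)) stop_invalid("unknown multiplier(s): ",
                                  paste(bad, collapse = ", "))
    mult <- modifyList(mult, multipliers)
  }
  if (any(unlist(mult) <= 0)) stop_invalid("multipliers must be positive")
  if (length(mult$t2_star) != 3L)
    stop_invalid("t2_star multipliers must cover the three post timepoints")
  structure(list(drug = drug, multipliers = mult,
                 timepoints = CHALLENGE_TIMEPOINTS),
            class = "challenge_transform")
}

#' Apply a challenge transform to phantom ground truth
#'
#' Returns a new phantom whose true parameter maps are multiplied by the
#' transform's factors; the input phantom is unchanged. For T2* the
#' multiplier of the requested post-administration timepoint is used.
#'
#' @param phantom A `kidney_phantom`.
#' @param transform A [challenge_transform()].
#' @param timepoint Post-administration timepoint for T2*: an index 1..3 or
#'   a label among the transform's `timepoints`. Default 1.
#' @return A transformed `kidney_phantom`.
#' @export
apply_challenge <- function(phantom, transform, timepoint = 1L) {
  if (!inherits(phantom, "kidney_phantom"))
    stop_invalid("phantom must be a kidney_phantom")
  if (!inherits(transform, "challenge_transform"))
    stop_invalid("transform must be a challenge_transform")
  if (is.character(timepoint)) {
    timepoint <- match(timepoint, transform$timepoints)
    if (is.na(timepoint)) stop_invalid("unknown timepoint label")
  }
  if (!timepoint %in% 1:3) stop_invalid("timepoint must be 1, 2 or 3")
  out <- phantom
  m <- transform$multipliers
  out$truth$f <- phantom$truth$f * m$f
  out$truth$d <- phantom$truth$d * m$d
  out$truth$d_star <- phantom$truth$d_star * m$d_star
  out$truth$t2_star <- phantom$truth$t2_star * m$t2_star[timepoint]
  if (any(out$truth$f > 1, na.rm = TRUE))
    stop_invalid("challenge multiplier drives f above 1")
  out
}

#' Write a simulated stack and its ground truth to disk
#'
#' Writes the image stack as a 4D NIfTI volume (trailing singleton slice
#' dimension inserted so viewers treat the abscissa as the fourth axis),
#' the region labels as an integer NIfTI, and a JSON sidecar with the
#' acquisition scheme, noise level, seed, and per-region true parameters.
#'
#' @param stack Array from [simulate_dwi()] / [simulate_bold()].
#' @param phantom The generating `kidney_phantom`.
#' @param prefix Output path prefix; files `<prefix>.nii.gz`,
#'   `<prefix>_labels.nii.gz`, `<prefix>.json` are written.
#' @param seed Seed recorded in the sidecar (optional).
#' @return Invisibly, the sidecar list.
#' @export
write_phantom_stack <- function(stack, phantom, prefix, seed = NULL) {
  dims <- dim(stack)
  arr4 <- array(stack, c(dims[1], dims[2], 1L, dims[3]))
  RNifti::writeNifti(arr4, paste0(prefix, ".nii.gz"))
  lab <- array(phantom$regions$labels, c(dims[1], dims[2], 1L))
  RNifti::writeNifti(lab, paste0(prefix, "_labels.nii.gz"))
  sidecar <- list(abscissa = attr(stack, "abscissa"),
                  noise_sigma = attr(stack, "noise_sigma"),
                  seed = seed,
                  grid = phantom$spec$grid,
                  region_params = phantom$spec$region_params)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
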