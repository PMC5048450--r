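# Voxelwise driver: applies a curve fitter to every masked voxel of an
# image stack and assembles parameter maps with convergence flags.

#' Fit a model voxelwise over a masked image stack
#'
#' Runs [fit_adc()], [fit_ivim_bayesian()] or [fit_t2star()] on each voxel
#' inside the mask and collects parameter maps. Convergence flags are
#' preserved per voxel and the total non-converged count is reported; for
#' the IVIM model the derived flow product fD* map is included.
#'
#' @param stack 3D array `[x, y, abscissa]` as from [simulate_dwi()] /
#'   [simulate_bold()]; b-values or echo times are taken from
#'   `attr(stack, "abscissa")` unless given.
#' @param mask Logical/0-1 matrix, or a `region_set` (whole kidney used).
#' @param model `"adc"`, `"ivim"` or `"t2star"`.
#' @param abscissa Optional override of the acquisition scheme.
#' @param verbose Log progress and the non-converged total.
#' @param ... Passed to the underlying fitter (e.g. `b_min`, `priors`,
#'   `sigma`, `grid_n`, `engine`).
#' @return An object of class `parameter_map`: `values` (named list of
#'   matrices, base units), `converged` (logical matrix), `in_mask`,
#'   `model`, `n_voxels`, `n_nonconverged`.
#' @export
fit_map <- function(stack, mask, model = c("adc", "ivim", "t2star"),
                    abscissa = NULL, verbose = FALSE, ...) {
  model <- match.arg(model)
  if (inherits(mask, "region_set")) mask <- mask$labels > 0L
  mask <- mask != 0
  dims <- dim(stack)
  if (length(dims) != 3L) stop_invalid("stack must be a 3D array [x, y, k]")
  if (!all(dim(mask) == dims[1:2]))
    stop_invalid("stack and mask are on different grids")
  if (is.null(abscissa)) abscissa <- attr(stack, "abscissa")
  if (is.null(abscissa) || length(abscissa) != dims[3])
    stop_invalid("abscissa must match the stack's third dimension")
  kind <- if (model == "t2star") "bold" else "dwi"
  par_names <- switch(model,
                      adc = c("s0", "adc"),
                      t2star = c("s0", "t2_star"),
                      ivim = c("s0", "f", "d", "d_star", "f_d_star"))
  values <- setNames(lapply(par_names, function(p)
    matrix(NA_real_, dims[1], dims[2])), par_names)
  converged <- matrix(FALSE, dims[1], dims[2])
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("mask contains no voxels; returning an empty parameter map")
  }
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]
    cur <- decay_curve(abscissa, stack[i, j, ], kind = kind)
    fit <- switch(model,
                  adc = fit_adc(cur, ...),
                  t2star = fit_t2star(cur, ...),
                  ivim = fit_ivim_bayesian(cur, ...))
    if (!is.null(fit$params)) {
      p <- fit$params
      for (nm in setdiff(par_names, "f_d_star")) values[[nm]][i, j] <- p[[nm]]
      if (model == "ivim")
        values$f_d_star[i, j] <- flow_product(p$f, p$d_star)
    }
    converged[i, j] <- isTRUE(fit$converged)
    if (verbose && v %% 50 == 0)
      message("fit_map: ", v, "/", nrow(idx), " voxels")
  }
  n_bad <- sum(mask) - sum(converged)
  if (verbose) message("fit_map: ", sum(mask), " voxels, ",
                       n_bad, " non-converged")
  structure(list(values = values, converged = converged, in_mask = mask,
                 model = model, abscissa = abscissa,
                 n_voxels = sum(mask), n_nonconverged = n_bad),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map: %s, %d voxels, %d non-converged>\n",
              x$model, x$n_voxels, x$n_nonconverged))
  cat("  parameters:", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Write a parameter map as NIfTI volumes
#'
#' One file per parameter (base units) plus a 0/1 convergence volume.
#'
#' @param map A `parameter_map`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_parameter_map <- function(map, prefix) {
  paths <- character()
  for (nm in names(map$values)) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(array(map$values[[nm]], c(dim(map$converged), 1L)), p)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_converged.nii.gz")
  RNifti::writeNifti(array(map$converged * 1, c(dim(map$converged), 1L)), p)
  invisible(c(paths, p))
}
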