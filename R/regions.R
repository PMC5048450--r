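# ROI construction and robust per-region summaries.
#
# The cortex is taken as the single-voxel outline of the kidney mask and the
# medulla as the region inside, so the two always partition the whole-kidney
# ROI. Region medians are computed over converged voxels only, which keeps
# summaries robust to fit failures.

REGION_LEVELS <- c("whole_kidney", "cortex", "medulla")

#' Derive cortex/medulla regions from a kidney mask
#'
#' Splits a binary kidney mask into its one-voxel-wide boundary layer
#' (cortex) and interior (medulla) by morphological erosion.
#'
#' @param mask Logical or 0/1 matrix; the whole-kidney ROI.
#' @param connectivity 4 (default) or 8; neighbourhood used for the one-step
#'   erosion. 4-connectivity yields a true one-voxel rim on convex shapes.
#' @param provenance Free-text origin of the mask, kept for audit.
#' @return An object of class `region_set` with integer `labels`
#'   (0 background, 1 cortex, 2 medulla) and voxel counts.
#' @examples
#' m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
#' rs <- derive_regions(m)
#' rs$n_voxels  # cortex 16, medulla 9
#' @export
derive_regions <- function(mask, connectivity = 4, provenance = "unknown") {
  if (!is.matrix(mask)) stop_invalid("mask must be a matrix")
  m <- (mask != 0) * 1
  if (sum(m) == 0) stop_invalid("kidney mask is empty")
  if (!connectivity %in% c(4, 8))
    stop_invalid("connectivity must be 4 or 8")
  shape <- if (connectivity == 4) "diamond" else "box"
  kern <- EBImage::makeBrush(3, shape = shape)
  interior <- EBImage::erode(m, kern)
  if (sum(interior) == 0)
    stop_invalid("mask too thin for a one-voxel rim plus interior: ",
                 sum(m), " voxels, bounding box ",
                 paste(dim_of_mask(m), collapse = "x"))
  labels <- matrix(0L, nrow(m), ncol(m))
  labels[m == 1 & interior == 0] <- 1L
  labels[interior == 1] <- 2L
  structure(list(
    labels = labels,
    connectivity = connectivity,
    provenance = provenance,
    n_voxels = c(whole_kidney = sum(labels > 0L),
                 cortex = sum(labels == 1L),
                 medulla = sum(labels == 2L))
  ), class = "region_set")
}

dim_of_mask <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L)
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>\n")
  cat(sprintf("  whole kidney: %d voxels (cortex %d, medulla %d)\n",
              x$n_voxels[["whole_kidney"]], x$n_voxels[["cortex"]],
              x$n_voxels[["medulla"]]))
  cat("  connectivity:", x$connectivity, " provenance:", x$provenance, "\n")
  invisible(x)
}

region_mask <- function(regions, region) {
  switch(region,
         whole_kidney = regions$labels > 0L,
         cortex = regions$labels == 1L,
         medulla = regions$labels == 2L,
         stop_invalid("unknown region: ", region))
}

#' Summarise a parameter map over regions
#'
#' Computes the ROI median of each fitted parameter over converged voxels,
#' for the whole kidney and (unless suppressed) the cortex and medulla.
#' Medians are reported in conventional reporting units (ADC/D in 1e-5
#' mm^2/s, D* in 1e-2 mm^2/s, fD* in 1e-4 mm^2/s, f in %, T2* in ms).
#'
#' @param map A `parameter_map` from [fit_map()].
#' @param regions A `region_set` from [derive_regions()].
#' @param kidney_id Identifier recorded in the output.
#' @param subregions If `FALSE`, only the whole-kidney ROI is summarised
#'   (the convention for BOLD maps, where slice partial volume precludes a
#'   reliable cortex/medulla split).
#' @return A data.frame with columns `kidney_id`, `region`, `parameter`,
#'   `median` (reporting units), `units`, `n_voxels`, `n_excluded`.
#' @export
summarise_regions <- function(map, regions, kidney_id = "k1",
                              subregions = NULL) {
  if (!inherits(map, "parameter_map")) stop_invalid("map must be a parameter_map")
  if (!inherits(regions, "region_set"))
    stop_invalid("regions must be a region_set")
  if (!all(dim(map$converged) == dim(regions$labels)))
    stop_invalid("parameter map and region set are on different grids")
  if (is.null(subregions)) subregions <- map$model != "t2star"
  regs <- if (subregions) REGION_LEVELS else "whole_kidney"
  units_of <- c(f = "%", d = "1e-5 mm^2/s", adc = "1e-5 mm^2/s",
                d_star = "1e-2 mm^2/s", f_d_star = "1e-4 mm^2/s",
                t2_star = "ms", s0 = "a.u.")
  out <- list()
  for (region in regs) {
    in_reg <- region_mask(regions, region)
    for (par in names(map$values)) {
      ok <- in_reg & map$converged
      vals <- map$values[[par]][ok]
      vals <- vals[is.finite(vals)]
      n_exc <- sum(in_reg & map$in_mask) - length(vals)
      med <- if (length(vals) >= 1L) {
        to_reporting_units(median(vals), par)
      } else {
        warning("region '", region, "' has no converged voxels for ", par)
        NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        kidney_id = kidney_id, region = region, parameter = par,
        median = med, units = unname(units_of[par]),
        n_voxels = length(vals), n_excluded = n_exc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Start an empty kidney exclusion log
#'
#' @return A zero-row data.frame with columns `kidney_id`, `reason`.
#' @export
exclusion_log <- function() {
  data.frame(kidney_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Exclude a kidney from analysis
#'
#' Marks a kidney excluded (for example because slice positioning or signal
#' precluded confident ROI drawing) with an audited reason. Downstream
#' cohort statistics drop excluded kidneys; excluding every kidney makes
#' them refuse with an error.
#'
#' @param log An exclusion log (see [exclusion_log()]).
#' @param kidney_id Kidney identifier.
#' @param reason Free-text reason, recorded verbatim.
#' @return The updated exclusion log.
#' @export
exclude_kidney <- function(log, kidney_id, reason) {
  if (!is.data.frame(log) || !all(c("kidney_id", "reason") %in% names(log)))
    stop_invalid("log must be an exclusion log data.frame")
  if (!nzchar(reason)) stop_invalid("an exclusion reason is required")
  rbind(log, data.frame(kidney_id = kidney_id, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Drop excluded kidneys from a summary table
#'
#' @param summaries A summary data.frame with a `kidney_id` column.
#' @param log An exclusion log.
#' @return `summaries` without rows from excluded kidneys; errors if no
#'   kidney survives.
#' @export
apply_exclusions <- function(summaries, log) {
  keep <- !(summaries$kidney_id %in% log$kidney_id)
  if (!any(keep))
    stop_invalid("all kidneys are excluded; no data left for cohort statistics")
  summaries[keep, , drop = FALSE]
}
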