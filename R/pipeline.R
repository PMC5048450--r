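# Experiment orchestration: simulate -> fit -> summarise -> statistics,
# reproducibly. A single master seed yields deterministic per-stage seeds,
# all of which are logged with the configuration.

DESIGNS <- c("repeatability", "hydralazine", "furosemide", "angiotensin_ii")

#' Experiment configuration
#'
#' Everything needed to reproduce a synthetic study end-to-end: phantom
#' spec, acquisition schemes, fitting settings, design, cohort size and
#' master seed. Re-running an identical configuration reproduces identical
#' outputs.
#'
#' @param design `"repeatability"` (two same-session scans, no drug) or a
#'   challenge arm: `"hydralazine"`, `"furosemide"`, `"angiotensin_ii"`.
#' @param n_kidneys Number of kidneys (subject units) simulated.
#' @param seed Master integer seed; per-stage seeds derive from it.
#' @param phantom A [phantom_spec()].
#' @param b_scheme,te_scheme Acquisition schemes.
#' @param modalities Which modalities to run: subset of `"dwi"`, `"bold"`.
#' @param fit Named list of fitting settings: `b_min` (high-b threshold,
#'   s/mm^2), `engine` and `grid_n` for the Bayesian IVIM fit.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param write_maps Also write parameter maps / stacks as NIfTI when
#'   `out_dir` is set.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = DESIGNS, n_kidneys = 6, seed = 1L,
                              phantom = phantom_spec(),
                              b_scheme = dwi_b_scheme(),
                              te_scheme = bold_te_scheme(),
                              modalities = c("dwi", "bold"),
                              fit = list(), out_dir = NULL,
                              write_maps = FALSE) {
  design <- match.arg(design)
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (n_kidneys < 1) stop_invalid("n_kidneys must be >= 1")
  fit_defaults <- list(b_min = 200, engine = "grid",
                       grid_n = c(f = 48, d = 64, d_star = 64))
  fit <- modifyList(fit_defaults, fit)
  structure(list(design = design, n_kidneys = as.integer(n_kidneys),
                 seed = as.integer(seed), phantom = phantom,
                 b_scheme = b_scheme, te_scheme = te_scheme,
                 modalities = modalities, fit = fit, out_dir = out_dir,
                 write_maps = isTRUE(write_maps)),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' The configuration is fully serialisable; the YAML round-trip reproduces
#' an equivalent `experiment_config`.
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns the configuration.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("design", "n_kidneys", "seed", "phantom", "b_scheme", "te_scheme")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_invalid("config file lacks field(s): ", paste(missing, collapse = ", "))
  ph <- x$phantom
  rp <- lapply(ph$region_params, function(p) lapply(p, as.numeric))
  phantom <- phantom_spec(grid = unlist(ph$grid),
                          semi_axes = unlist(ph$semi_axes),
                          centre = unlist(ph$centre),
                          region_params = rp,
                          snr_target = ph$snr_target,
                          noise_sigma = ph$noise_sigma,
                          kidney_count_band = unlist(ph$kidney_count_band),
                          seed = ph$seed)
  experiment_config(design = x$design, n_kidneys = x$n_kidneys,
                    seed = x$seed, phantom = phantom,
                    b_scheme = unlist(x$b_scheme),
                    te_scheme = unlist(x$te_scheme),
                    modalities = unlist(x$modalities),
                    fit = lapply(x$fit, function(v)
                      if (is.list(v)) unlist(v) else v),
                    out_dir = x$out_dir, write_maps = isTRUE(x$write_maps))
}

# Deterministic per-stage seeds below 2^31 derived from the master seed.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

fit_and_summarise <- function(stack, phantom, kidney_id, condition,
                              modality, config) {
  out <- list()
  if (modality == "dwi") {
    adc_map <- fit_map(stack, phantom$regions, model = "adc",
                       b_min = config$fit$b_min)
    ivim_map <- fit_map(stack, phantom$regions, model = "ivim",
                        engine = config$fit$engine,
                        grid_n = config$fit$grid_n)
    out <- list(adc = adc_map, ivim = ivim_map)
  } else {
    out <- list(t2star = fit_map(stack, phantom$regions, model = "t2star"))
  }
  summaries <- do.call(rbind, lapply(out, function(m)
    summarise_regions(m, phantom$regions, kidney_id = kidney_id)))
  summaries$condition <- condition
  rownames(summaries) <- NULL
  list(maps = out, summaries = summaries)
}

#' Run a synthetic experiment end-to-end
#'
#' Executes the configured design: for repeatability, two independent-noise
#' acquisitions of each kidney; for a challenge arm, a pre acquisition plus
#' post acquisitions with the drug's transform applied (DWI once, BOLD at
#' the three post-administration timepoints). Each acquisition is fitted
#' voxelwise, summarised per ROI, and the design's statistics are computed.
#' All seeds derive from the master seed and are logged in the result.
#'
#' @param config An [experiment_config()].
#' @param exclusions An exclusion log (see [exclude_kidney()]).
#' @return An object of class `experiment_result`: `config`, `summaries`
#'   (tidy data.frame), `stats`, `seeds`, `audit`.
#' @export
run_experiment <- function(config, exclusions = exclusion_log()) {
  stopifnot(inherits(config, "experiment_config"))
  phantom <- make_phantom(config$phantom)
  transform <- if (config$design == "repeatability") NULL
               else challenge_transform(config$design)
  n_acq_per_kidney <- 8L   # upper bound on seeded stages per kidney
  seeds <- derive_seeds(config$seed, config$n_kidneys * n_acq_per_kidney)
  seed_log <- list(master = config$seed)
  all_sum <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  for (k in seq_len(config$n_kidneys)) {
    kid <- sprintf("k%02d", k)
    if (kid %in% exclusions$kidney_id) next
    sk <- seeds[(k - 1L) * n_acq_per_kidney + seq_len(n_acq_per_kidney)]
    seed_log[[kid]] <- sk
    if (config$design == "repeatability") {
      conds <- c("scan1", "scan2")
      for (s in 1:2) {
        if ("dwi" %in% config$modalities) {
          dwi <- stage("simulate", simulate_dwi(phantom, config$b_scheme,
                                                seed = sk[s]))
          fs <- stage("fit", fit_and_summarise(dwi, phantom, kid, conds[s],
                                               "dwi", config))
          all_sum[[length(all_sum) + 1L]] <- fs$summaries
        }
        if ("bold" %in% config$modalities) {
          bold <- stage("simulate", simulate_bold(phantom, config$te_scheme,
                                                  seed = sk[2 + s]))
          fs <- stage("fit", fit_and_summarise(bold, phantom, kid, conds[s],
                                               "bold", config))
          all_sum[[length(all_sum) + 1L]] <- fs$summaries
        }
      }
    } else {
      if ("dwi" %in% config$modalities) {
        pre <- stage("simulate", simulate_dwi(phantom, config$b_scheme,
                                              seed = sk[1]))
        fs <- stage("fit", fit_and_summarise(pre, phantom, kid, "pre",
                                             "dwi", config))
        all_sum[[length(all_sum) + 1L]] <- fs$summaries
        post_ph <- apply_challenge(phantom, transform, timepoint = 3L)
        post <- stage("simulate", simulate_dwi(post_ph, config$b_scheme,
                                               seed = sk[2]))
        fs <- stage("fit", fit_and_summarise(post, post_ph, kid, "post",
                                             "dwi", config))
        all_sum[[length(all_sum) + 1L]] <- fs$summaries
      }
      if ("bold" %in% config$modalities) {
        base <- stage("simulate", simulate_bold(phantom, config$te_scheme,
                                                seed = sk[3]))
        fs <- stage("fit", fit_and_summarise(base, phantom, kid, "baseline",
                                             "bold", config))
        all_sum[[length(all_sum) + 1L]] <- fs$summaries
        for (tp in 1:3) {
          ph_tp <- apply_challenge(phantom, transform, timepoint = tp)
          stk <- stage("simulate", simulate_bold(ph_tp, config$te_scheme,
                                                 seed = sk[3 + tp]))
          fs <- stage("fit", fit_and_summarise(
            stk, ph_tp, kid, transform$timepoints[tp], "bold", config))
          all_sum[[length(all_sum) + 1L]] <- fs$summaries
        }
      }
    }
  }
  if (!length(all_sum))
    stop_invalid("all kidneys are excluded; nothing to run")
  summaries <- do.call(rbind, all_sum)
  rownames(summaries) <- NULL
  stats <- compute_experiment_stats(summaries, config)
  res <- structure(list(config = config, summaries = summaries,
                        stats = stats, seeds = seed_log, audit = exclusions),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(res)
  res
}

pick <- function(s, region, parameter, condition) {
  rows <- s$region == region & s$parameter == parameter &
    s$condition == condition
  setNames(s$median[rows], s$kidney_id[rows])[order(s$kidney_id[rows])]
}

compute_experiment_stats <- function(summaries, config) {
  s <- summaries
  dwi_pars <- intersect(c("f", "d", "adc", "d_star", "f_d_star"),
                        unique(s$parameter))
  stats <- list()
  if (config$design == "repeatability") {
    conds <- c("scan1", "scan2")
    rows <- list()
    for (region in unique(s$region)) {
      for (par in unique(s$parameter[s$region == region])) {
        v1 <- pick(s, region, par, conds[1])
        v2 <- pick(s, region, par, conds[2])
        if (!length(v1) || !length(v2)) next
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, parameter = par,
          mean_scan1 = mean(v1), mean_scan2 = mean(v2),
          cov_percent = cov_repeatability(v1, v2),
          p_paired = if (length(v1) >= 2) paired_test(v1, v2)$p_value
                     else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    stats$repeatability <- do.call(rbind, rows)
    if (all(c("adc", "d") %in% s$parameter)) {
      adc <- c(pick(s, "whole_kidney", "adc", conds[1]),
               pick(s, "whole_kidney", "adc", conds[2]))
      d <- c(pick(s, "whole_kidney", "d", conds[1]),
             pick(s, "whole_kidney", "d", conds[2]))
      if (length(adc) >= 3) stats$adc_d_correlation <- correlate_adc_d(adc, d)
    }
  } else {
    if ("dwi" %in% config$modalities) {
      rows <- list()
      for (region in unique(s$region)) {
        for (par in dwi_pars) {
          pre <- pick(s, region, par, "pre")
          post <- pick(s, region, par, "post")
          if (!length(pre)) next
          pt <- if (length(pre) >= 2) paired_test(pre, post)
                else list(p_value = NA_real_, significant = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            region = region, parameter = par, mean_pre = mean(pre),
            mean_post = mean(post), p_value = pt$p_value,
            significant = isTRUE(pt$significant), stringsAsFactors = FALSE)
        }
      }
      stats$challenge <- do.call(rbind, rows)
      adc <- c(pick(s, "whole_kidney", "adc", "pre"),
               pick(s, "whole_kidney", "adc", "post"))
      d <- c(pick(s, "whole_kidney", "d", "pre"),
             pick(s, "whole_kidney", "d", "post"))
      if (length(adc) >= 3) stats$adc_d_correlation <- correlate_adc_d(adc, d)
    }
    if ("bold" %in% config$modalities) {
      tps <- c("baseline", CHALLENGE_TIMEPOINTS)
      rows <- s[s$parameter == "t2_star" & s$region == "whole_kidney" &
                  s$condition %in% tps, ]
      tc <- data.frame(unit_id = rows$kidney_id,
                       timepoint = factor(rows$condition, levels = tps),
                       value = rows$median, stringsAsFactors = FALSE)
      stats$t2star_percent <- percent_change(tc)
      if (length(unique(tc$unit_id)) >= 2)
        stats$t2star_timecourse <- bold_timecourse_test(tc)
    }
  }
  stats
}

write_experiment <- function(res) {
  dir.create(res$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- res$config$out_dir
  write.csv(res$summaries, file.path(out, "summaries.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(design = res$config$design, seeds = res$seeds,
         stats = res$stats,
         package_version = as.character(utils::packageVersion("renomri"))),
    file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  if (nrow(res$audit))
    write.csv(res$audit, file.path(out, "exclusions.csv"), row.names = FALSE)
  invisible(out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s, %d kidneys>\n", x$config$design,
              x$config$n_kidneys))
  cat("  summaries:", nrow(x$summaries), "rows;  stats:",
      paste(names(x$stats), collapse = ", "), "\n")
  invisible(x)
}

#' Render a human-readable experiment report
#'
#' Prints parameter tables in reporting units: scan-1/scan-2/CoV columns
#' for a repeatability design, pre/post columns with 5% significance flags
#' for a challenge design, the BOLD timecourse with its percent-of-baseline
#' summary, and the exclusion / non-convergence audit.
#'
#' @param result An `experiment_result`, or `NULL`/empty for an explicit
#'   "no results" report.
#' @return The report lines, invisibly; printed as a side effect.
#' @export
report_experiment <- function(result) {
  out <- character()
  say <- function(...) out <<- c(out, paste0(...))
  if (is.null(result) || !length(result$summaries) ||
      !nrow(result$summaries)) {
    say("no results: the bundle is empty")
    cat(paste(out, collapse = "\n"), "\n")
    return(invisible(out))
  }
  say("Experiment: ", result$config$design, " (", result$config$n_kidneys,
      " kidneys, master seed ", result$config$seed, ")")
  fmt <- function(df) paste(capture.output(print(df, row.names = FALSE,
                                                 digits = 4)), collapse = "\n")
  st <- result$stats
  if (!is.null(st$repeatability)) {
    say("", "Repeatability (ROI medians, reporting units; CoV %):")
    say(fmt(st$repeatability))
  }
  if (!is.null(st$challenge)) {
    say("", "Challenge pre/post (ROI medians, reporting units; * p<0.05):")
    tab <- st$challenge
    tab$flag <- ifelse(tab$significant, "*", "")
    say(fmt(tab[, c("region", "parameter", "mean_pre", "mean_post",
                    "p_value", "flag")]))
  }
  if (!is.null(st$t2star_percent)) {
    say("", "BOLD T2* percent of baseline (cohort mean +/- SE):")
    say(fmt(st$t2star_percent$cohort))
  }
  if (!is.null(st$t2star_timecourse)) {
    tt <- st$t2star_timecourse
    say("", sprintf("Repeated-measures ANOVA omnibus p = %.4g (n = %d)",
                    tt$omnibus_p, tt$n_units))
    say(fmt(tt$table))
  }
  if (!is.null(st$adc_d_correlation))
    say("", sprintf("Pearson r(ADC, D) = %.3f over %d ROI medians",
                    st$adc_d_correlation$r, st$adc_d_correlation$n))
  if (nrow(result$audit)) {
    say("", "Excluded kidneys:")
    say(fmt(result$audit))
  } else {
    say("", "No kidneys excluded.")
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
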