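#' Default pipeline run configuration
#'
#' Returns the full configuration list driving [run_pipeline()]: one section
#' per scenario (tracing / imaging / calibration / assays), the list of
#' enabled stages, the significance level, and the top-level seed from which
#' every sub-generator's seed is derived.
#'
#' @param seed top-level integer seed.
#' @param stages character subset of
#'   `c("generate", "isotope", "imaging", "ptquant", "assays")`.
#' @param level nominal significance level in (0, 1).
#' @param n_fields synthetic image fields per condition.
#' @return named list, suitable for [run_pipeline()] or for serializing to
#'   YAML with [write_run_config()].
#' @export
default_run_config <- function(seed = 1L,
                               stages = c("generate", "isotope", "imaging",
                                          "ptquant", "assays"),
                               level = 0.05, n_fields = 2L) {
  stopifnot(level > 0, level < 1)
  list(seed = as.integer(seed), stages = stages, level = level,
       tracing = list(dilution_fraction = 0.2778, natural_abundance_p = 0.0107,
                      noise_cv = 0.05, n_replicates = 3),
       imaging = list(n_nuclei = 25, n_fields = as.integer(n_fields),
                      noise_sd = 5, foci_lambda_control = 1,
                      foci_lambda_treated = 4),
       calibration = list(true_slope = 0.02, true_intercept = 0,
                          relative_noise_sd = 0.03),
       assays = list(n_replicates = 3, sf_treated = 0.2,
                     lactate_effect = 0.5, redox_effect = 0.6))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return the configuration list (read) / `path` (write).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (key in names(cfg)) {
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key: '%s'", key))
    }
    if (is.list(base[[key]])) {
      extra <- setdiff(names(cfg[[key]]), names(base[[key]]))
      if (length(extra)) {
        abort(sprintf("unknown configuration key: '%s.%s'", key, extra[1]))
      }
      base[[key]][names(cfg[[key]])] <- cfg[[key]]
    } else {
      base[[key]] <- cfg[[key]]
    }
  }
  stopifnot(base$level > 0, base$level < 1)
  base$seed <- as.integer(base$seed)
  base
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_file <- function(outdir, name) file.path(outdir, name)

#' Run the synthetic study pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — generate, isotope,
#' imaging, ptquant, assays — persisting every intermediate table under
#' `outdir` (tidy TSV/CSV, multi-page TIFF fields, JSON ground-truth
#' sidecars) and returning a run report. Deterministic for a fixed seed:
#' every sub-generator's seed is derived from `config$seed`.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param outdir output directory (created if needed).
#' @return object of class `run_report`: per-stage result tables, recovery
#'   metrics against the synthetic ground truth, the configuration hash,
#'   seed and per-stage timings.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = tempfile("run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  report <- list(seed = config$seed, config_hash = rlang::hash(config),
                 outdir = outdir, stages = stages, timings = list())
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, elapsed = proc.time()[["elapsed"]] - t0)
  }
  gen <- NULL

  if ("generate" %in% stages) {
    st <- tick({
      tr_cfg <- config$tracing
      tracing <- tracing_scenario(
        dilution_fraction = tr_cfg$dilution_fraction,
        natural_abundance_p = tr_cfg$natural_abundance_p,
        noise_cv = tr_cfg$noise_cv, n_replicates = tr_cfg$n_replicates,
        seed = config$seed + 11L)
      iso <- gen_isotopologue_dataset(tracing)
      write_spectra_tsv(iso$spectra, stage_file(outdir, "spectra.tsv"))
      write_truth_json(iso$truth, stage_file(outdir, "spectra_truth.json"))

      im_cfg <- config$imaging
      fields <- list()
      for (cond in c("control", "treated")) {
        for (f in seq_len(im_cfg$n_fields)) {
          lam <- if (cond == "control") im_cfg$foci_lambda_control else
            im_cfg$foci_lambda_treated
          sc <- image_scenario(
            n_nuclei = im_cfg$n_nuclei, noise_sd = im_cfg$noise_sd,
            foci = list(type = "poisson", lambda = lam),
            seed = config$seed + 200L + 10L * f)
          fld <- gen_nuclei_image(sc, condition = cond)
          write_field_tiff(fld, stage_file(
            outdir, sprintf("field_%s_%d.tif", cond, f)))
          fields[[paste(cond, f, sep = "_")]] <- fld
        }
      }

      cal_cfg <- config$calibration
      cal <- gen_calibration_run(calibration_scenario(
        true_slope = cal_cfg$true_slope,
        true_intercept = cal_cfg$true_intercept,
        relative_noise_sd = cal_cfg$relative_noise_sd,
        seed = config$seed + 31L))
      write_calibration_csv(cal$run, stage_file(outdir, "icpms_run.csv"))
      write_truth_json(cal$truth, stage_file(outdir, "icpms_truth.json"))

      as_cfg <- config$assays
      assay <- gen_assay_tables(
        seed = config$seed + 41L, n_replicates = as_cfg$n_replicates,
        sf_treated = as_cfg$sf_treated,
        lactate_effect = as_cfg$lactate_effect,
        redox_effect = as_cfg$redox_effect)
      readr::write_tsv(assay$clonogenic, stage_file(outdir, "clonogenic.tsv"))
      readr::write_tsv(assay$lactate_plate, stage_file(outdir, "lactate_plate.tsv"))
      readr::write_tsv(assay$redox, stage_file(outdir, "redox.tsv"))
      readr::write_tsv(assay$senescence, stage_file(outdir, "senescence.tsv"))
      list(tracing = iso, fields = fields, calibration = cal, assay = assay)
    })
    gen <- st$value
    report$timings$generate <- st$elapsed
  }

  if ("isotope" %in% stages) {
    if (is.null(gen)) abort("isotope stage requires the generate stage.")
    st <- tick({
      mids <- correct_mid_table(gen$tracing$spectra,
                                p13 = config$tracing$natural_abundance_p)
      conds <- unique(gen$tracing$spectra$condition)
      contrasts <- contrast_conditions(mids, conds[1], conds[2],
                                       level = config$level)
      readr::write_tsv(mids, stage_file(outdir, "mids_corrected.tsv"))
      readr::write_tsv(contrasts, stage_file(outdir, "mid_contrasts.tsv"))
      est <- dplyr::filter(contrasts, .data$quantity == "labeled_fraction")
      truth_lf <- dplyr::distinct(gen$tracing$truth, .data$metabolite,
                                  .data$condition, .data$labeled_fraction)
      truth_a <- dplyr::filter(truth_lf, .data$condition == conds[1])
      recov <- recovery_metrics(
        estimate = est$mean_a,
        truth = truth_a$labeled_fraction[match(est$metabolite,
                                               truth_a$metabolite)])
      list(mids = mids, contrasts = contrasts, recovery = recov)
    })
    report$isotope <- st$value
    report$timings$isotope <- st$elapsed
  }

  if ("imaging" %in% stages) {
    if (is.null(gen)) abort("imaging stage requires the generate stage.")
    st <- tick({
      per_field <- list()
      for (nm in names(gen$fields)) {
        fld <- gen$fields[[nm]]
        seg <- segment_nuclei(fld$dapi)
        rec <- measure_nuclei(seg, fld$gh2ax)
        fc <- detect_foci(fld$gh2ax, seg)
        rec$foci_count <- fc$per_nucleus$foci_count
        rec$condition <- fld$condition
        rec$field <- nm
        rec$true_n <- nrow(fld$nuclei)
        per_field[[nm]] <- rec
      }
      cells <- dplyr::bind_rows(per_field)
      thr <- derive_threshold(cells[cells$condition == "control", ])
      scored <- classify_positive(cells, thr)
      summary <- dplyr::summarise(
        dplyr::group_by(scored$records, .data$condition),
        n_cells = dplyr::n(),
        percent_positive = 100 * mean(.data$positive),
        mean_foci = mean(.data$foci_count), .groups = "drop")
      readr::write_tsv(scored$records, stage_file(outdir, "cells.tsv"))
      readr::write_tsv(summary, stage_file(outdir, "imaging_summary.tsv"))
      list(cells = scored$records, threshold = thr, summary = summary)
    })
    report$imaging <- st$value
    report$timings$imaging <- st$elapsed
  }

  if ("ptquant" %in% stages) {
    if (is.null(gen)) abort("ptquant stage requires the generate stage.")
    st <- tick({
      run <- add_signal_ratios(gen$calibration$run)
      fit <- fit_calibration(run[run$role == "standard", ])
      unk <- run[run$role == "sample", ]
      bc <- back_calculate(fit, unk$ratio)
      results <- dplyr::bind_cols(unk[, c("sample", "type")], bc)
      wide <- tidyr::pivot_wider(results[, c("sample", "type", "ppb")],
                                 names_from = "type", values_from = "ppb")
      wide$dna_bound_percent <- dna_bound_fraction(wide$total, wide$dna)
      readr::write_tsv(results, stage_file(outdir, "pt_results.tsv"))
      readr::write_tsv(wide, stage_file(outdir, "pt_dna_fraction.tsv"))
      truth <- gen$calibration$truth
      recov <- recovery_metrics(
        estimate = results$ppb,
        truth = truth$true_ppb[match(paste(results$sample, results$type),
                                     paste(truth$sample, truth$type))])
      list(fit = fit, results = results, dna_fraction = wide,
           recovery = recov)
    })
    report$ptquant <- st$value
    report$timings$ptquant <- st$elapsed
  }

  if ("assays" %in% stages) {
    if (is.null(gen)) abort("assays stage requires the generate stage.")
    st <- tick({
      a <- gen$assay
      sf <- surviving_fraction(a$clonogenic, control = "control",
                               level = config$level)
      lact <- normalize_to_control(a$lactate_plate, control = "control",
                                   per_cell = TRUE, level = config$level)
      redox <- dplyr::bind_rows(lapply(
        split(a$redox, a$redox$condition), function(d) {
          s <- redox_ratio(d$reduced, d$oxidized)
          tibble::tibble(condition = d$condition[1], mean = s$mean,
                         sd = s$sd, n = s$n)
        }))
      sen <- senescence_fraction(a$senescence)
      for (tbl in c("sf", "lact", "redox", "sen")) {
        readr::write_tsv(get(tbl), stage_file(outdir, paste0("assay_", tbl, ".tsv")))
      }
      list(surviving_fraction = sf, lactate = lact, redox = redox,
           senescence = sen)
    })
    report$assays <- st$value
    report$timings$assays <- st$elapsed
  }

  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  cat("stages:", paste(x$stages, collapse = ", "), "\n")
  for (nm in names(x$timings)) {
    cat(sprintf("  %-9s %.2fs\n", nm, x$timings[[nm]]))
  }
  invisible(x)
}

#' Ground-truth recovery metrics
#'
#' Compares pipeline estimates against the synthetic generator's ground
#' truth: bias (mean signed error) and mean absolute error, plus — when
#' significance flags and true-effect indicators are supplied — the fraction
#' of true effects flagged (a power proxy) and the false-flag rate under
#' null entries.
#'
#' @param estimate,truth aligned numeric vectors.
#' @param flagged optional logical vector of significance flags.
#' @param true_effect optional logical vector marking entries with a real
#'   generated effect.
#' @return one-row tibble: `n`, `bias`, `mae`, and (when applicable)
#'   `power`, `false_flag_rate`.
#' @export
recovery_metrics <- function(estimate, truth, flagged = NULL,
                             true_effect = NULL) {
  if (length(estimate) != length(truth)) {
    abort("`estimate` and `truth` must be aligned (equal length).")
  }
  if (any(is.na(truth))) abort("missing ground truth.")
  err <- estimate - truth
  out <- tibble::tibble(n = length(err), bias = mean(err),
                        mae = mean(abs(err)))
  if (!is.null(flagged) && !is.null(true_effect)) {
    out$power <- if (any(true_effect)) mean(flagged[true_effect]) else NA_real_
    out$false_flag_rate <- if (any(!true_effect)) mean(flagged[!true_effect])
      else NA_real_
  }
  out
}
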