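#' Scenario for the U-13C6-glucose tracing generator
#'
#' Describes the ground truth of a simulated stable-isotope tracing
#' experiment: which metabolites are measured (with their carbon counts),
#' the true mass isotopomer distribution (MID) of each metabolite under each
#' condition, the share of the lactate pool fed by an unlabeled media-pyruvate
#' pool (`dilution_fraction`), the per-carbon natural heavy-isotope
#' probability contaminating the observed spectra, and the multiplicative
#' intensity noise level.
#'
#' The defaults emulate a 3-hour U-13C6-glucose labeling experiment in a
#' glycolytic tumour cell line with excess unlabeled pyruvate in the media:
#' pyruvate is ~90% labeled (m+3), while lactate — fed partly by the unlabeled
#' media pool — comes out ~65% labeled; alpha-ketoglutarate is <20% labeled
#' and pentose-phosphate intermediates 40-50%. The treated condition carries
#' suppressed labeled-lactate flux with compensatory citrate m+2/m+4 and
#' pentose-phosphate shunting.
#'
#' @param metabolites tibble with columns `metabolite`, `n_carbons`.
#' @param true_mids tibble with columns `metabolite`, `condition`,
#'   `isotopologue` (0..n), `fraction`; each metabolite/condition block must
#'   be a valid MID (non-negative, sums to 1, length `n_carbons + 1`).
#' @param dilution_fraction share in `[0, 1]` of the lactate pool coming from
#'   the unlabeled media-pyruvate pool. Lactate's generated mixture MID is
#'   `(1 - d) * MID(pyruvate) + d * delta(m+0)`.
#' @param natural_abundance_p per-carbon probability that a non-tracer carbon
#'   is a heavy isotope (13C natural abundance, default 0.0107).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 = noiseless).
#' @param n_replicates replicates per condition (>= 1).
#' @param total_pool total intensity scale (arbitrary units) of each spectrum.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return object of class `tracing_scenario`.
#' @seealso [gen_isotopologue_dataset()]
#' @export
tracing_scenario <- function(metabolites = default_tracing_metabolites(),
                             true_mids = default_tracing_mids(),
                             dilution_fraction = 0.2778,
                             natural_abundance_p = 0.0107,
                             noise_cv = 0.05,
                             n_replicates = 3,
                             total_pool = 1e6,
                             seed = 1L) {
  metabolites <- tibble::as_tibble(metabolites)
  true_mids <- tibble::as_tibble(true_mids)
  stopifnot(all(c("metabolite", "n_carbons") %in% names(metabolites)),
            all(c("metabolite", "condition", "isotopologue", "fraction") %in%
                  names(true_mids)))
  if (!is.numeric(dilution_fraction) || dilution_fraction < 0 ||
      dilution_fraction > 1) {
    abort("`dilution_fraction` must lie in [0, 1].")
  }
  if (natural_abundance_p < 0 || natural_abundance_p >= 1) {
    abort("`natural_abundance_p` must lie in [0, 1).")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")

  # every declared MID must be a proper fraction vector of the right length
  check <- dplyr::group_by(true_mids, .data$metabolite, .data$condition)
  check <- dplyr::summarise(check,
                            total = sum(.data$fraction),
                            neg = any(.data$fraction < 0),
                            len = dplyr::n(), .groups = "drop")
  check <- dplyr::left_join(check, metabolites, by = "metabolite")
  bad <- check$neg | abs(check$total - 1) > 1e-9 | check$len != check$n_carbons + 1
  if (any(bad)) {
    abort(paste0("invalid true MID for: ",
                 paste(unique(check$metabolite[bad]), collapse = ", ")))
  }

  structure(list(metabolites = metabolites, true_mids = true_mids,
                 dilution_fraction = dilution_fraction,
                 natural_abundance_p = natural_abundance_p,
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 total_pool = total_pool, seed = as.integer(seed)),
            class = "tracing_scenario")
}

#' Default metabolite panel for the tracing generator
#'
#' Glycolysis (pyruvate, lactate, hexose phosphates), pentose phosphate
#' pathway (pentose-5-phosphates, sedoheptulose-7-phosphate) and TCA
#' (citrate, alpha-ketoglutarate) intermediates with their carbon counts.
#' @return tibble with columns `metabolite`, `n_carbons`.
#' @export
default_tracing_metabolites <- function() {
  tibble::tribble(
    ~metabolite,          ~n_carbons,
    "pyruvate",            3L,
    "lactate",             3L,
    "glucose-6-phosphate", 6L,
    "fructose-1,6-bisP",   6L,
    "pentose-5-phosphate", 5L,
    "sedoheptulose-7P",    7L,
    "citrate",             6L,
    "alpha-ketoglutarate", 5L
  )
}

# build one MID row-block from a named sparse spec: list(m0 = .., m3 = ..)
mid_block <- function(metabolite, condition, n_carbons, sparse) {
  fr <- numeric(n_carbons + 1)
  idx <- as.integer(sub("^m", "", names(sparse)))
  fr[idx + 1] <- unlist(sparse)
  tibble::tibble(metabolite = metabolite, condition = condition,
                 isotopologue = 0:n_carbons, fraction = fr)
}

#' Default true MIDs for the tracing generator
#'
#' Control condition: pyruvate 90% m+3-labeled; hexose phosphates mostly m+6;
#' pentose phosphates ~45% labeled (m+5); alpha-ketoglutarate <20% labeled;
#' citrate with first-turn m+2 plus some m+4. Treated condition: labeled
#' pyruvate flux suppressed (90% -> 60%), hexose/PPP label raised slightly and
#' citrate m+2/m+4 increased, emulating shunting away from lactate. Lactate's
#' MID is not listed here: the generator derives it from pyruvate and the
#' dilution fraction.
#' @param conditions character vector of length 2: control then treated label.
#' @return tibble in the `true_mids` format of [tracing_scenario()].
#' @export
default_tracing_mids <- function(conditions = c("control", "CDDP")) {
  ctl <- conditions[1]; trt <- conditions[2]
  dplyr::bind_rows(
    mid_block("pyruvate", ctl, 3, list(m0 = 0.10, m3 = 0.90)),
    mid_block("pyruvate", trt, 3, list(m0 = 0.40, m3 = 0.60)),
    mid_block("glucose-6-phosphate", ctl, 6, list(m0 = 0.25, m6 = 0.75)),
    mid_block("glucose-6-phosphate", trt, 6, list(m0 = 0.35, m6 = 0.65)),
    mid_block("fructose-1,6-bisP", ctl, 6, list(m0 = 0.22, m6 = 0.78)),
    mid_block("fructose-1,6-bisP", trt, 6, list(m0 = 0.34, m6 = 0.66)),
    mid_block("pentose-5-phosphate", ctl, 5, list(m0 = 0.55, m5 = 0.45)),
    mid_block("pentose-5-phosphate", trt, 5, list(m0 = 0.45, m5 = 0.55)),
    mid_block("sedoheptulose-7P", ctl, 7,
              list(m0 = 0.55, m5 = 0.25, m7 = 0.20)),
    mid_block("sedoheptulose-7P", trt, 7,
              list(m0 = 0.50, m5 = 0.28, m7 = 0.22)),
    mid_block("citrate", ctl, 6, list(m0 = 0.70, m2 = 0.20, m4 = 0.07,
                                      m5 = 0.03)),
    mid_block("citrate", trt, 6, list(m0 = 0.58, m2 = 0.26, m4 = 0.12,
                                      m5 = 0.04)),
    mid_block("alpha-ketoglutarate", ctl, 5, list(m0 = 0.82, m2 = 0.14,
                                                  m4 = 0.04)),
    mid_block("alpha-ketoglutarate", trt, 5, list(m0 = 0.76, m2 = 0.18,
                                                  m4 = 0.06))
  )
}

#' Scenario for the synthetic nuclei-image generator
#'
#' One two-channel field: DAPI nuclei as non-overlapping disks, a damage
#' channel with per-nucleus base intensity plus Gaussian foci and additive
#' noise. Control and treated intensity regimes are both described so the
#' same scenario can generate either condition.
#'
#' @param n_nuclei nuclei per field.
#' @param radius_range integer range of nucleus radii (pixels).
#' @param control_intensity `c(mean, sd)` of per-nucleus base intensity in the
#'   damage channel, arbitrary units.
#' @param treated_shift additive shift of the treated base-intensity mean.
#' @param foci list: `list(type = "poisson", lambda = )` or
#'   `list(type = "fixed", count = )` foci per nucleus.
#' @param focus_amplitude,focus_sigma peak height (a.u.) and Gaussian sd (px)
#'   of each focus. Default amplitude keeps peaks > background + 5 noise sd.
#' @param focus_min_sep minimum separation between foci within one nucleus
#'   (pixels); keeps neighbouring peaks resolvable.
#' @param background,dapi_intensity background level and DAPI disk value.
#' @param noise_sd additive Gaussian noise sd (both channels); clipped at 0.
#' @param image_size `c(nx, ny)` pixels.
#' @param max_tries rejection-sampling budget for non-overlapping placement.
#' @param seed integer seed.
#' @return object of class `image_scenario`.
#' @seealso [gen_nuclei_image()]
#' @export
image_scenario <- function(n_nuclei = 30,
                           radius_range = c(8L, 14L),
                           control_intensity = c(mean = 100, sd = 15),
                           treated_shift = 40,
                           foci = list(type = "poisson", lambda = 2),
                           focus_amplitude = 60,
                           focus_sigma = 1.5,
                           focus_min_sep = 7,
                           background = 10,
                           dapi_intensity = 180,
                           noise_sd = 5,
                           image_size = c(512L, 512L),
                           max_tries = 5000L,
                           seed = 1L) {
  stopifnot(n_nuclei >= 0, length(radius_range) == 2,
            radius_range[1] <= radius_range[2], radius_range[1] >= 2,
            length(image_size) == 2, all(image_size >= 16),
            noise_sd >= 0, focus_sigma > 0)
  if (!foci$type %in% c("poisson", "fixed")) {
    abort("`foci$type` must be \"poisson\" or \"fixed\".")
  }
  structure(list(n_nuclei = as.integer(n_nuclei),
                 radius_range = as.integer(radius_range),
                 control_intensity = control_intensity,
                 treated_shift = treated_shift, foci = foci,
                 focus_amplitude = focus_amplitude, focus_sigma = focus_sigma,
                 focus_min_sep = focus_min_sep,
                 background = background, dapi_intensity = dapi_intensity,
                 noise_sd = noise_sd, image_size = as.integer(image_size),
                 max_tries = as.integer(max_tries), seed = as.integer(seed)),
            class = "image_scenario")
}

#' Scenario for the synthetic ICP-MS calibration generator
#'
#' Platinum/iridium signal ratios linear in concentration with noise whose sd
#' is proportional to concentration (constant relative error — the regime
#' that motivates 1/x^2 calibration weighting). Default standard levels are
#' the serial-dilution series 0.125, 1.25, 12.5, 25 and 50 ppb.
#'
#' @param true_slope ratio per ppb.
#' @param true_intercept ratio at zero concentration.
#' @param standard_levels strictly positive, strictly increasing ppb levels.
#' @param relative_noise_sd sd of the ratio noise as a fraction of
#'   concentration times slope (0 = noiseless).
#' @param samples tibble of unknowns: columns `sample`, `type` (free-form;
#'   the pipeline pairs `total` and `dna` rows of one specimen), `true_ppb`.
#'   Default draws paired total / DNA-bound specimens with a bound:total
#'   ratio of mean 0.06.
#' @param ir_counts iridium internal-standard counts per run row.
#' @param seed integer seed.
#' @return object of class `calibration_scenario`.
#' @seealso [gen_calibration_run()]
#' @export
calibration_scenario <- function(true_slope = 0.02,
                                 true_intercept = 0,
                                 standard_levels = c(0.125, 1.25, 12.5, 25, 50),
                                 relative_noise_sd = 0.03,
                                 samples = NULL,
                                 ir_counts = 5e5,
                                 seed = 1L) {
  if (any(standard_levels <= 0) || is.unsorted(standard_levels, strictly = TRUE)) {
    abort("`standard_levels` must be strictly positive and strictly increasing.")
  }
  stopifnot(relative_noise_sd >= 0, true_slope != 0, ir_counts > 0)
  if (is.null(samples)) {
    samples <- withr::with_seed(as.integer(seed) + 101L, {
      n <- 6L
      total <- runif(n, 20, 45)
      ratio <- rlnorm(n, meanlog = log(0.06) - 0.5 * 0.25^2, sdlog = 0.25)
      tibble::tibble(
        sample = rep(sprintf("S%02d", seq_len(n)), 2L),
        type = rep(c("total", "dna"), each = n),
        true_ppb = c(total, total * ratio))
    })
  }
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample", "type", "true_ppb") %in% names(samples)),
            all(samples$true_ppb >= 0))
  structure(list(true_slope = true_slope, true_intercept = true_intercept,
                 standard_levels = standard_levels,
                 relative_noise_sd = relative_noise_sd, samples = samples,
                 ir_counts = ir_counts, seed = as.integer(seed)),
            class = "calibration_scenario")
}
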