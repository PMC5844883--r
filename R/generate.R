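# lognormal multiplicative noise with mean 1 and the requested CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic isotopologue dataset
#'
#' Simulates the observed targeted-MS isotopologue intensity table of a
#' U-13C6-glucose tracing experiment. For every metabolite / condition /
#' replicate, the true tracer MID is convolved with the natural-abundance
#' mass-shift distribution, scaled to the total pool size and multiplied by
#' lognormal noise. Lactate is special-cased: its tracer MID is the mixture
#' `(1 - d) * MID(pyruvate) + d * delta(m+0)`, modelling the unlabeled
#' media-pyruvate pool that dilutes glycolytic label on its way into lactate
#' (so at d = 0.2778, 90% labeled pyruvate yields 65% labeled lactate).
#'
#' @param scenario a [tracing_scenario()].
#' @return list with `spectra` (wide tibble: `metabolite`, `n_carbons`,
#'   `condition`, `replicate`, `m0` ... `mN`) and `truth` (long tibble of the
#'   true tracer MIDs actually generated, including the diluted lactate MID,
#'   plus `labeled_fraction` per metabolite/condition).
#' @export
gen_isotopologue_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "tracing_scenario"))
  sc <- scenario
  mids <- sc$true_mids
  has_lactate <- "lactate" %in% sc$metabolites$metabolite
  if (has_lactate && !"lactate" %in% mids$metabolite) {
    if (!"pyruvate" %in% mids$metabolite) {
      abort("lactate dilution requires a pyruvate MID in the scenario.")
    }
    nc_lac <- sc$metabolites$n_carbons[sc$metabolites$metabolite == "lactate"]
    nc_pyr <- sc$metabolites$n_carbons[sc$metabolites$metabolite == "pyruvate"]
    if (nc_lac != nc_pyr) {
      abort("carbon-count mismatch: lactate dilution needs matching pyruvate.")
    }
    d <- sc$dilution_fraction
    lac <- dplyr::filter(mids, .data$metabolite == "pyruvate")
    lac <- dplyr::mutate(lac, metabolite = "lactate",
                         fraction = (1 - d) * .data$fraction +
                           d * as.numeric(.data$isotopologue == 0))
    mids <- dplyr::bind_rows(mids, lac)
  }
  mids <- dplyr::semi_join(mids, sc$metabolites, by = "metabolite")

  max_n <- max(sc$metabolites$n_carbons)
  withr::with_seed(sc$seed, {
    rows <- list()
    for (i in seq_len(nrow(sc$metabolites))) {
      met <- sc$metabolites$metabolite[i]
      n <- sc$metabolites$n_carbons[i]
      nam <- natural_abundance_matrix(max(n, 1L), sc$natural_abundance_p)
      for (cond in unique(mids$condition[mids$metabolite == met])) {
        fr <- dplyr::filter(mids, .data$metabolite == met,
                            .data$condition == cond)
        fr <- fr$fraction[order(fr$isotopologue)]
        expected <- as.numeric(nam$matrix %*% fr) * sc$total_pool
        for (r in seq_len(sc$n_replicates)) {
          obs <- expected * lnorm_noise(n + 1, sc$noise_cv)
          row <- c(list(metabolite = met, n_carbons = n,
                        condition = cond, replicate = r),
                   stats::setNames(as.list(c(obs, rep(NA_real_, max_n - n))),
                                   paste0("m", 0:max_n)))
          rows[[length(rows) + 1]] <- tibble::as_tibble(row)
        }
      }
    }
    spectra <- dplyr::bind_rows(rows)
  })

  truth <- dplyr::group_by(mids, .data$metabolite, .data$condition)
  truth <- dplyr::mutate(truth,
                         labeled_fraction =
                           100 * (1 - .data$fraction[.data$isotopologue == 0]))
  truth <- dplyr::ungroup(truth)
  list(spectra = spectra, truth = truth)
}

# sample n focus positions jointly within radius rmax of (cx, cy) with
# pairwise separation >= sep; the separation is relaxed by 20% steps when a
# constellation cannot be found, so generation always terminates
place_foci <- function(n, cx, cy, rmax, sep) {
  if (n == 1) {
    rr <- runif(1, 0, rmax); th <- runif(1, 0, 2 * pi)
    return(cbind(cx + rr * cos(th), cy + rr * sin(th)))
  }
  s <- sep
  repeat {
    for (try in 1:500) {
      rr <- sqrt(runif(n)) * rmax
      th <- runif(n, 0, 2 * pi)
      pts <- cbind(cx + rr * cos(th), cy + rr * sin(th))
      if (min(stats::dist(pts)) >= s) return(pts)
    }
    s <- 0.8 * s
  }
}

# one symmetric 2-D Gaussian bump added in place
add_gaussian <- function(img, cx, cy, amplitude, sigma) {
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(4 * sigma)
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
  img[xs, ys] <- img[xs, ys] + amplitude * outer(gx, gy)
  img
}

#' Generate a synthetic two-channel nuclei field
#'
#' Places non-overlapping disk nuclei by rejection sampling, draws the DAPI
#' channel (disks over background), and draws the damage channel as a
#' per-nucleus base intensity plus symmetric Gaussian foci and additive
#' Gaussian noise, clipped at zero. Full ground truth (nucleus centers,
#' radii, base intensities, focus coordinates, and the true label map) is
#' returned alongside the images.
#'
#' @param scenario an [image_scenario()].
#' @param condition `"control"` or `"treated"`; the treated condition shifts
#'   the base-intensity mean by `scenario$treated_shift`.
#' @return object of class `nuclei_field`: list with matrices `dapi`,
#'   `gh2ax`, integer matrix `labels` (true segmentation), tibbles `nuclei`
#'   (`label`, `x`, `y`, `radius`, `base_intensity`, `n_foci`) and `foci`
#'   (`label`, `x`, `y`), and the `condition`.
#' @export
gen_nuclei_image <- function(scenario, condition = c("control", "treated")) {
  stopifnot(inherits(scenario, "image_scenario"))
  condition <- match.arg(condition)
  sc <- scenario
  nx <- sc$image_size[1]; ny <- sc$image_size[2]

  withr::with_seed(sc$seed + if (condition == "treated") 1L else 0L, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < sc$n_nuclei) {
      tries <- tries + 1L
      if (tries > sc$max_tries) {
        abort(sprintf(
          "could not place %d non-overlapping nuclei in %d tries; enlarge the image.",
          sc$n_nuclei, sc$max_tries))
      }
      r <- sample(sc$radius_range[1]:sc$radius_range[2], 1)
      cx <- runif(1, r + 2, nx - r - 1)
      cy <- runif(1, r + 2, ny - r - 1)
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(dd < radii + r + 3)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }

    dapi <- matrix(sc$background, nx, ny)
    gh2ax <- matrix(sc$background, nx, ny)
    labels <- matrix(0L, nx, ny)
    base_mean <- sc$control_intensity[["mean"]] +
      if (condition == "treated") sc$treated_shift else 0
    n <- sc$n_nuclei
    base <- if (n > 0) {
      pmax(rnorm(n, base_mean, sc$control_intensity[["sd"]]), 0)
    } else numeric(0)
    n_foci <- if (n == 0) integer(0)
      else if (sc$foci$type == "fixed") rep(as.integer(sc$foci$count), n)
      else rpois(n, sc$foci$lambda)

    xs <- seq_len(nx); ys <- seq_len(ny)
    foci_rows <- list()
    for (k in seq_len(n)) {
      disk <- outer((xs - centers[k, 1])^2, (ys - centers[k, 2])^2, "+") <=
        radii[k]^2
      dapi[disk] <- sc$dapi_intensity
      gh2ax[disk] <- gh2ax[disk] + base[k]
      labels[disk] <- k
      if (n_foci[k] > 0) {
        placed <- place_foci(n_foci[k], centers[k, 1], centers[k, 2],
                             0.7 * radii[k], sc$focus_min_sep)
        for (f in seq_len(n_foci[k])) {
          gh2ax <- add_gaussian(gh2ax, placed[f, 1], placed[f, 2],
                                sc$focus_amplitude, sc$focus_sigma)
          foci_rows[[length(foci_rows) + 1]] <-
            tibble::tibble(label = k, x = placed[f, 1], y = placed[f, 2])
        }
      }
    }
    if (sc$noise_sd > 0) {
      dapi <- dapi + rnorm(nx * ny, 0, sc$noise_sd)
      gh2ax <- gh2ax + rnorm(nx * ny, 0, sc$noise_sd)
    }
    dapi <- pmax(dapi, 0)
    gh2ax <- pmax(gh2ax, 0)
  })

  nuclei <- tibble::tibble(
    label = seq_len(sc$n_nuclei),
    x = if (sc$n_nuclei) centers[, 1] else numeric(0),
    y = if (sc$n_nuclei) centers[, 2] else numeric(0),
    radius = radii, base_intensity = base, n_foci = n_foci)
  foci <- if (length(foci_rows)) dplyr::bind_rows(foci_rows) else
    tibble::tibble(label = integer(0), x = numeric(0), y = numeric(0))

  structure(list(dapi = dapi, gh2ax = gh2ax, labels = labels,
                 nuclei = nuclei, foci = foci, condition = condition),
            class = "nuclei_field")
}

#' Generate a synthetic ICP-MS calibration run
#'
#' Standards at the scenario's concentration levels and unknown samples are
#' given Pt/Ir signal ratios `slope * conc + intercept + noise` with noise sd
#' proportional to concentration (constant relative error). Ratios are
#' rendered as raw counts: total Pt counts are split over the monitored
#' masses 194/195/196 in proportion to platinum's isotopic abundances, with
#' a fixed Ir (mass 193) internal-standard count. Negative generated ratios
#' are clipped to zero and flagged.
#'
#' @param scenario a [calibration_scenario()].
#' @return object of class `calibration_run`: list with `run` (tibble:
#'   `sample`, `role`, `type`, `nominal_ppb`, `pt194`, `pt195`, `pt196`,
#'   `ir193`, `clipped`) and `truth` (sample true concentrations and the
#'   generating slope/intercept).
#' @export
gen_calibration_run <- function(scenario) {
  stopifnot(inherits(scenario, "calibration_scenario"))
  sc <- scenario
  # relative abundance of 194Pt/195Pt/196Pt among the three monitored masses
  pt_iso <- c(0.3286, 0.3378, 0.2521)
  pt_iso <- pt_iso / sum(pt_iso)

  rows <- dplyr::bind_rows(
    tibble::tibble(sample = sprintf("STD_%g", sc$standard_levels),
                   role = "standard", type = NA_character_,
                   conc = sc$standard_levels,
                   nominal_ppb = sc$standard_levels),
    tibble::tibble(sample = sc$samples$sample, role = "sample",
                   type = sc$samples$type, conc = sc$samples$true_ppb,
                   nominal_ppb = NA_real_))

  withr::with_seed(sc$seed, {
    noise_sd <- sc$relative_noise_sd * sc$true_slope * rows$conc
    ratio <- sc$true_slope * rows$conc + sc$true_intercept +
      rnorm(nrow(rows), 0, noise_sd)
  })
  clipped <- ratio < 0
  ratio[clipped] <- 0

  pt_total <- ratio * sc$ir_counts
  run <- tibble::tibble(
    sample = rows$sample, role = rows$role, type = rows$type,
    nominal_ppb = rows$nominal_ppb,
    pt194 = pt_total * pt_iso[1], pt195 = pt_total * pt_iso[2],
    pt196 = pt_total * pt_iso[3], ir193 = sc$ir_counts,
    clipped = clipped)
  truth <- tibble::tibble(sample = rows$sample, role = rows$role,
                          type = rows$type, true_ppb = rows$conc)
  structure(list(run = run, truth = truth,
                 true_slope = sc$true_slope,
                 true_intercept = sc$true_intercept),
            class = "calibration_run")
}

#' Generate synthetic endpoint-assay tables
#'
#' Small seeded generator for the plate-level inputs of the assays stage:
#' clonogenic dish counts, a lactate plate with a Hoechst cell-number
#' surrogate, paired redox (reduced/oxidized) measurements and
#' senescence field counts, for a control and a treated condition.
#'
#' @param seed integer seed.
#' @param conditions length-2 character vector, control first.
#' @param n_replicates replicates (dishes / wells / fields) per condition.
#' @param sf_treated true treated surviving fraction.
#' @param lactate_effect true treated/control intra-cellular lactate ratio.
#' @param redox_effect true treated/control NADH/NAD+ ratio ratio.
#' @param senescence_percent true percent senescent cells, `c(control,
#'   treated)`.
#' @param cv multiplicative noise CV on plate readouts.
#' @return list of tibbles `clonogenic`, `lactate_plate`, `redox`,
#'   `senescence`, plus `truth`.
#' @export
gen_assay_tables <- function(seed = 1L, conditions = c("control", "CDDP"),
                             n_replicates = 3, sf_treated = 0.2,
                             lactate_effect = 0.5, redox_effect = 0.6,
                             senescence_percent = c(5, 30), cv = 0.05) {
  ctl <- conditions[1]; trt <- conditions[2]
  withr::with_seed(as.integer(seed), {
    pe <- 0.5
    plated <- rep(400L, 2 * n_replicates)
    p_col <- pe * c(rep(1, n_replicates), rep(sf_treated, n_replicates))
    clono <- tibble::tibble(
      condition = rep(c(ctl, trt), each = n_replicates),
      plated = plated,
      colonies = rbinom(2 * n_replicates, plated, p_col))

    lac_mean <- c(rep(100, n_replicates), rep(100 * lactate_effect, n_replicates))
    surrogate <- rep(1, 2 * n_replicates) * lnorm_noise(2 * n_replicates, cv / 2)
    lactate <- tibble::tibble(
      well = sprintf("W%02d", seq_len(2 * n_replicates)),
      condition = rep(c(ctl, trt), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      readout = lac_mean * surrogate * lnorm_noise(2 * n_replicates, cv),
      surrogate = surrogate)

    nadh <- c(rep(1, n_replicates), rep(redox_effect, n_replicates)) *
      lnorm_noise(2 * n_replicates, cv)
    nad <- rep(1, 2 * n_replicates) * lnorm_noise(2 * n_replicates, cv)
    redox <- tibble::tibble(
      condition = rep(c(ctl, trt), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      reduced = nadh, oxidized = nad)

    total <- rep(100L, 2 * n_replicates)
    p_sen <- rep(senescence_percent / 100, each = n_replicates)
    senescence <- tibble::tibble(
      condition = rep(c(ctl, trt), each = n_replicates),
      field = rep(seq_len(n_replicates), 2),
      positive = rbinom(2 * n_replicates, total, p_sen),
      total = total)
  })
  list(clonogenic = clono, lactate_plate = lactate, redox = redox,
       senescence = senescence,
       truth = tibble::tibble(
         quantity = c("sf_treated", "lactate_relative", "redox_relative",
                      paste0("senescence_percent_", c(ctl, trt))),
         value = c(sf_treated, lactate_effect, redox_effect,
                   senescence_percent)))
}
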