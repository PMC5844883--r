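#' Isotopologue spectrum constructor
#'
#' One metabolite's raw intensities at mass shifts m+0 ... m+n for a single
#' replicate of a single condition, as integrated from targeted MS peaks.
#'
#' @param metabolite metabolite name.
#' @param n_carbons number of carbon atoms.
#' @param intensities numeric vector of length `n_carbons + 1`, arbitrary
#'   units, all non-negative.
#' @param condition,replicate condition label and replicate index.
#' @return object of class `isotopologue_spectrum`.
#' @export
isotopologue_spectrum <- function(metabolite, n_carbons, intensities,
                                  condition = NA_character_,
                                  replicate = NA_integer_) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1) abort("`n_carbons` must be >= 1.")
  if (length(intensities) != n_carbons + 1) {
    abort("`intensities` must have length `n_carbons + 1` (m+0 ... m+n).")
  }
  if (any(intensities < 0) || any(!is.finite(intensities))) {
    abort("intensities must be finite and non-negative.")
  }
  structure(list(metabolite = metabolite, n_carbons = n_carbons,
                 intensities = as.numeric(intensities),
                 condition = condition, replicate = replicate),
            class = "isotopologue_spectrum")
}

#' Natural-abundance correction matrix
#'
#' Transition matrix mapping a true tracer mass isotopomer distribution to
#' the observed one under per-carbon natural heavy-isotope contamination.
#' Column `k` (0-based) is the mass-shift distribution of a molecule carrying
#' `k` tracer carbons: those `k` carbons contribute shift `k` with certainty,
#' and each of the remaining `n - k` carbons is a heavy isotope independently
#' with probability `p13`, so the column is a `Binomial(n - k, p13)` pmf
#' offset by `k`. With `p13 = 0` the matrix is the identity.
#'
#' @param n_carbons number of carbons (>= 1).
#' @param p13 per-carbon heavy-isotope probability in `[0, 1)`;
#'   13C natural abundance is about 0.0107.
#' @return object of class `correction_matrix` with fields `n_carbons`,
#'   `p13` and `matrix` ((n+1) x (n+1); rows = observed shift, columns =
#'   tracer count; each column sums to 1).
#' @examples
#' m <- natural_abundance_matrix(3, 0.011)
#' m$matrix[1, 1]  # (1 - 0.011)^3
#' @export
natural_abundance_matrix <- function(n_carbons, p13 = 0.0107) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1) abort("`n_carbons` must be >= 1.")
  if (!is.numeric(p13) || p13 < 0 || p13 >= 1) {
    abort("`p13` must lie in [0, 1).")
  }
  n <- n_carbons
  m <- matrix(0, n + 1, n + 1)
  for (k in 0:n) {
    j <- k:n
    m[j + 1, k + 1] <- stats::dbinom(j - k, size = n - k, prob = p13)
  }
  dimnames(m) <- list(observed = paste0("m", 0:n), true = paste0("m", 0:n))
  structure(list(n_carbons = n, p13 = p13, matrix = m),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("natural-abundance correction matrix: %d carbons, p13 = %g\n",
              x$n_carbons, x$p13))
  print(round(x$matrix, 5))
  invisible(x)
}

new_mid <- function(metabolite, n_carbons, fractions) {
  fractions <- fractions / sum(fractions)
  structure(list(metabolite = metabolite, n_carbons = as.integer(n_carbons),
                 fractions = as.numeric(fractions),
                 labeled_fraction = 100 * (1 - fractions[1]),
                 mean_enrichment =
                   100 * sum((0:n_carbons) * fractions) / n_carbons),
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("MID %s (%d C): [%s]  labeled %.2f%%  enrichment %.2f%%\n",
              x$metabolite, x$n_carbons,
              paste(sprintf("%.4f", x$fractions), collapse = ", "),
              x$labeled_fraction, x$mean_enrichment))
  invisible(x)
}

#' Correct an isotopologue spectrum for natural abundance
#'
#' Recovers the tracer-derived mass isotopomer distribution from observed
#' intensities by solving `matrix %*% x ~ observed` as a non-negative least
#' squares problem and renormalizing the solution to sum to 1. The
#' non-negativity constraint prevents the small negative fractions that plain
#' matrix inversion produces at low signal.
#'
#' @param spectrum an [isotopologue_spectrum()], or a bare numeric intensity
#'   vector of length `n_carbons + 1`.
#' @param matrix a [natural_abundance_matrix()] of matching dimension.
#' @return object of class `mid` with fields `fractions` (sums to 1),
#'   `labeled_fraction` = 100 x (1 - m0) and `mean_enrichment` =
#'   100 x sum(k fk) / n, both percent.
#' @examples
#' m <- natural_abundance_matrix(3, 0.0107)
#' obs <- as.numeric(m$matrix %*% c(0.5, 0, 0, 0.5))
#' correct_mid(obs, m)$fractions
#' @export
correct_mid <- function(spectrum, matrix) {
  if (!inherits(matrix, "correction_matrix")) {
    abort("`matrix` must be a `correction_matrix`.")
  }
  if (inherits(spectrum, "isotopologue_spectrum")) {
    y <- spectrum$intensities
    metabolite <- spectrum$metabolite
  } else {
    y <- as.numeric(spectrum)
    metabolite <- NA_character_
  }
  if (length(y) != matrix$n_carbons + 1) {
    abort("spectrum length does not match the correction matrix dimension.")
  }
  if (any(y < 0)) abort("intensities must be non-negative.")
  tot <- sum(y)
  if (tot <= 0) abort("no signal: all intensities are zero.")
  x <- pracma::lsqnonneg(matrix$matrix, y / tot)$x
  if (sum(x) <= 0) abort("no signal after correction.")
  new_mid(metabolite, matrix$n_carbons, x)
}

as_fraction_vector <- function(mid) {
  if (inherits(mid, "mid")) mid$fractions else as.numeric(mid)
}

#' Labeled-molecule fraction of a MID
#'
#' Percent of molecules carrying any tracer carbon: `100 * (1 - f0)`. This is
#' the default reported "fractional incorporation"; [mean_enrichment()] is
#' the per-carbon atom-enrichment alternative.
#'
#' @param mid a `mid` object or a fraction vector summing to 1.
#' @return percent in `[0, 100]`.
#' @export
labeled_fraction <- function(mid) {
  f <- as_fraction_vector(mid)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-6) abort("not a valid MID.")
  100 * (1 - f[1])
}

#' Mean atom enrichment of a MID
#'
#' Percent of carbon atoms that are tracer-derived:
#' `100 * sum(k * fk) / n_carbons`.
#'
#' @inheritParams labeled_fraction
#' @return percent in `[0, 100]`.
#' @export
mean_enrichment <- function(mid) {
  f <- as_fraction_vector(mid)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-6) abort("not a valid MID.")
  n <- length(f) - 1
  100 * sum((0:n) * f) / n
}

#' Natural-abundance correction over a spectra table
#'
#' Applies [correct_mid()] to every row of a wide spectra table (the format
#' written by [gen_isotopologue_dataset()] and [write_spectra_tsv()]) and
#' returns tidy long-format corrected fractions.
#'
#' @param spectra tibble with columns `metabolite`, `n_carbons`, `condition`,
#'   `replicate`, `m0` ... `mN` (columns beyond a metabolite's carbon count
#'   may be `NA`).
#' @param p13 per-carbon heavy-isotope probability used for the correction.
#' @return tibble with columns `metabolite`, `n_carbons`, `condition`,
#'   `replicate`, `isotopologue`, `fraction`.
#' @export
correct_mid_table <- function(spectra, p13 = 0.0107) {
  spectra <- tibble::as_tibble(spectra)
  mcols <- grep("^m[0-9]+$", names(spectra), value = TRUE)
  if (length(mcols) == 0) abort("no m0...mN intensity columns found.")
  mats <- lapply(
    stats::setNames(nm = sort(unique(spectra$n_carbons))),
    function(n) natural_abundance_matrix(as.integer(n), p13))
  out <- vector("list", nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    n <- spectra$n_carbons[i]
    y <- as.numeric(spectra[i, paste0("m", 0:n)])
    mid <- correct_mid(y, mats[[as.character(n)]])
    out[[i]] <- tibble::tibble(
      metabolite = spectra$metabolite[i], n_carbons = n,
      condition = spectra$condition[i], replicate = spectra$replicate[i],
      isotopologue = 0:n, fraction = mid$fractions)
  }
  dplyr::bind_rows(out)
}

#' Per-isotopologue condition contrasts
#'
#' For every metabolite and isotopologue index, compares the corrected
#' fractions of two conditions with a two-tailed two-sample Student's t test
#' (pooled variance by default) on replicate values, and flags p below the
#' significance level. Also emits one contrast per metabolite on the
#' labeled-molecule fraction (`quantity = "labeled_fraction"`, percent
#' scale). Per-condition dispersion is reported as the standard error of the
#' mean, the convention for isotopologue bar plots.
#'
#' @param mids long-format corrected fractions as returned by
#'   [correct_mid_table()].
#' @param condition_a reference (control) condition label.
#' @param condition_b comparison condition label.
#' @param level significance level, default 0.05.
#' @param var_equal pooled-variance Student's t if `TRUE` (default); Welch
#'   otherwise.
#' @return tibble with one row per metabolite x quantity (isotopologue index
#'   or labeled fraction): means, SEMs, `difference` (b minus a), `t`, `p`,
#'   `significant`, `degenerate` (zero-variance convention applied).
#' @export
contrast_conditions <- function(mids, condition_a, condition_b,
                                level = 0.05, var_equal = TRUE) {
  mids <- tibble::as_tibble(mids)
  need <- c("metabolite", "condition", "replicate", "isotopologue", "fraction")
  stopifnot(all(need %in% names(mids)))
  mids <- dplyr::filter(mids, .data$condition %in% c(condition_a, condition_b))
  if (!all(c(condition_a, condition_b) %in% mids$condition)) {
    abort("both conditions must be present in `mids`.")
  }
  reps <- dplyr::count(mids, .data$metabolite, .data$condition,
                       .data$isotopologue)
  if (any(reps$n < 2)) abort("insufficient replicates: need >= 2 per group.")

  lab <- dplyr::filter(mids, .data$isotopologue == 0)
  lab <- dplyr::mutate(lab, isotopologue = NA_integer_,
                       fraction = 100 * (1 - .data$fraction),
                       quantity = "labeled_fraction")
  mids$quantity <- "fraction"
  all_rows <- dplyr::bind_rows(mids, lab)

  one <- function(d) {
    a <- d$fraction[d$condition == condition_a]
    b <- d$fraction[d$condition == condition_b]
    tt <- ttest_two_tailed(a, b, var_equal = var_equal)
    tibble::tibble(
      mean_a = mean(a), mean_b = mean(b),
      sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
      difference = mean(b) - mean(a),
      t = tt$t, p = tt$p, degenerate = tt$degenerate)
  }
  res <- dplyr::group_by(all_rows, .data$metabolite, .data$quantity,
                         .data$isotopologue)
  res <- dplyr::reframe(res, one(dplyr::pick(dplyr::everything())))
  res$significant <- res$p < level
  dplyr::arrange(res, .data$metabolite, .data$quantity, .data$isotopologue)
}

#' TCA isotopologue shift view
#'
#' Convenience restriction of [contrast_conditions()] to the TCA
#' isotopologues that report oxidative vs reductive turns of the cycle —
#' by default citrate m+2, m+4 and m+5 from uniformly labeled glucose.
#'
#' @inheritParams contrast_conditions
#' @param metabolite TCA metabolite name present in `mids`.
#' @param indices isotopologue indices to keep.
#' @return the matching rows of [contrast_conditions()].
#' @export
tca_mid_shift <- function(mids, metabolite = "citrate",
                          indices = c(2L, 4L, 5L),
                          condition_a, condition_b, level = 0.05) {
  mids <- tibble::as_tibble(mids)
  if (!metabolite %in% mids$metabolite) {
    abort(sprintf("unknown metabolite: %s", metabolite))
  }
  sub <- dplyr::filter(mids, .data$metabolite == !!metabolite)
  n <- max(sub$isotopologue)
  if (any(indices > n)) {
    abort(sprintf("isotopologue index exceeds carbon count (%d).", n))
  }
  res <- contrast_conditions(sub, condition_a, condition_b, level = level)
  dplyr::filter(res, .data$quantity == "fraction",
                .data$isotopologue %in% indices)
}
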