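#' Two-tailed two-sample Student's t test
#'
#' Pooled-variance Student's t by default (Welch behind `var_equal = FALSE`),
#' two-tailed. Degenerate zero-variance groups follow explicit conventions
#' rather than erroring: if both groups have zero variance, equal means give
#' `t = 0, p = 1` and unequal means give `p = 0` with the result flagged
#' `degenerate`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled variance if `TRUE` (default).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
ttest_two_tailed <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("insufficient replicates: need >= 2 values per group.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(b) - mean(a)) * Inf, p = 0,
                df = length(a) + length(b) - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

# shared per-condition summary + t test vs control on replicate values
endpoint_table <- function(values, conditions, control, level = 0.05) {
  conds <- unique(conditions)
  if (!control %in% conds) abort(sprintf("control condition '%s' missing.", control))
  ctrl <- values[conditions == control]
  rows <- lapply(conds, function(cc) {
    v <- values[conditions == cc]
    if (cc != control && length(v) >= 2 && length(ctrl) >= 2) {
      tt <- ttest_two_tailed(ctrl, v)
    } else {
      tt <- list(t = NA_real_, p = NA_real_, degenerate = NA)
    }
    tibble::tibble(condition = cc, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else NA_real_,
                   relative = mean(v) / mean(ctrl),
                   t = tt$t, p = tt$p,
                   significant = !is.na(tt$p) & tt$p < level)
  })
  out <- dplyr::bind_rows(rows)
  # control is its own reference: exactly 1 regardless of rounding
  out$relative[out$condition == control] <- 1
  out
}

#' Normalize plate readouts to the control condition
#'
#' Optionally divides each well by a cell-number surrogate (e.g. Hoechst DNA
#' signal), then expresses condition means relative to the control mean and
#' tests each condition against control with the package's default
#' two-tailed Student's t test.
#'
#' @param plate tibble with columns `condition`, `readout`, and (when
#'   `per_cell = TRUE`) `surrogate` > 0; any other columns (e.g. `well`,
#'   `replicate`) are carried along untouched.
#' @param control control condition label.
#' @param per_cell divide readouts by the surrogate first.
#' @param level significance level.
#' @return endpoint tibble: per condition `n`, `mean`, `sd`, `relative`
#'   (control = 1), `t`, `p`, `significant`.
#' @export
normalize_to_control <- function(plate, control = "control",
                                 per_cell = FALSE, level = 0.05) {
  plate <- tibble::as_tibble(plate)
  stopifnot(all(c("condition", "readout") %in% names(plate)),
            all(plate$readout >= 0))
  v <- plate$readout
  if (per_cell) {
    if (!"surrogate" %in% names(plate)) {
      abort("`per_cell = TRUE` requires a `surrogate` column.")
    }
    if (any(plate$surrogate <= 0)) abort("surrogate values must be > 0.")
    v <- v / plate$surrogate
  }
  if (mean(v[plate$condition == control]) == 0) {
    abort("control mean is zero; cannot normalize.")
  }
  endpoint_table(v, plate$condition, control, level)
}

#' Redox ratio per replicate
#'
#' Element-wise reduced/oxidized ratio (e.g. NADH/NAD+, NADPH/NADP+) over
#' paired replicates, with a summary.
#'
#' @param reduced,oxidized paired numeric vectors of equal length;
#'   `oxidized` must be > 0.
#' @return list with `per_replicate` tibble (`replicate`, `reduced`,
#'   `oxidized`, `ratio`) and summary fields `mean`, `sd`, `n`.
#' @export
redox_ratio <- function(reduced, oxidized) {
  if (length(reduced) != length(oxidized)) {
    abort("`reduced` and `oxidized` must be paired (equal length).")
  }
  bad <- which(oxidized <= 0)
  if (length(bad)) {
    abort(sprintf("oxidized value <= 0 at replicate %d.", bad[1]))
  }
  r <- reduced / oxidized
  list(per_replicate = tibble::tibble(replicate = seq_along(r),
                                      reduced = reduced, oxidized = oxidized,
                                      ratio = r),
       mean = mean(r), sd = if (length(r) > 1) sd(r) else NA_real_,
       n = length(r))
}

#' Clonogenic surviving fraction
#'
#' Plating efficiency (PE) is the control colony yield per cell plated; each
#' condition's surviving fraction (SF) is its colony yield divided by PE, so
#' SF(control) = 1 identically. With replicate dishes, the condition yield is
#' the mean of per-dish colony/plated ratios.
#'
#' @param records tibble with columns `condition`, `plated`, `colonies`
#'   (one row per dish; `colonies <= plated`).
#' @param control control condition label.
#' @param level significance level for the per-condition t test vs control
#'   (computed on per-dish SFs when both groups have >= 2 dishes).
#' @return endpoint tibble with `pe` (per-condition colony yield per cell)
#'   and `sf` alongside `n`, `sd`, `t`, `p`, `significant`.
#' @export
surviving_fraction <- function(records, control = "control", level = 0.05) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("condition", "plated", "colonies") %in% names(records)),
            all(records$plated > 0), all(records$colonies >= 0),
            all(records$colonies <= records$plated))
  if (!control %in% records$condition) abort("control condition missing.")
  pe_rows <- records$colonies / records$plated
  pe_control <- mean(pe_rows[records$condition == control])
  if (pe_control == 0) abort("control colony count is zero; PE undefined.")
  sf_rows <- pe_rows / pe_control
  out <- endpoint_table(sf_rows, records$condition, control, level)
  out <- dplyr::rename(out, sf = "relative")
  out$pe <- out$mean * pe_control
  out$mean <- NULL
  out$sf[out$condition == control] <- 1
  dplyr::relocate(out, "condition", "n", "pe", "sf")
}

#' Senescence-positive percentage per condition
#'
#' Percent of beta-galactosidase-positive cells per high-power field,
#' averaged over fields within each condition.
#'
#' @param fields tibble with columns `condition`, `positive`, `total`
#'   (one row per field). Fields with `total = 0` are dropped with a
#'   warning; an error is raised if a condition loses all its fields.
#' @return tibble per condition: `n_fields`, `percent` (mean over fields),
#'   `sd`.
#' @export
senescence_fraction <- function(fields) {
  fields <- tibble::as_tibble(fields)
  stopifnot(all(c("condition", "positive", "total") %in% names(fields)),
            all(fields$positive >= 0), all(fields$positive <= fields$total))
  empty <- fields$total == 0
  if (any(empty)) {
    warn(sprintf("dropping %d field(s) with zero cells.", sum(empty)))
    fields <- fields[!empty, ]
  }
  if (nrow(fields) == 0) abort("no usable fields: all have zero cells.")
  fields$percent <- 100 * fields$positive / fields$total
  dplyr::summarise(dplyr::group_by(fields, .data$condition),
                   n_fields = dplyr::n(),
                   percent = mean(.data$percent),
                   sd = if (dplyr::n() > 1) sd(.data$percent) else NA_real_,
                   .groups = "drop")
}
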