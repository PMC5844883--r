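test_that("noiseless undiluted generation is the identity on true MIDs", {
  sc <- tracing_scenario(dilution_fraction = 0, natural_abundance_p = 0,
                         noise_cv = 0, n_replicates = 1, seed = 1)
  ds <- gen_isotopologue_dataset(sc)
  for (i in seq_len(nrow(ds$spectra))) {
    row <- ds$spectra[i, ]
    y <- as.numeric(row[paste0("m", 0:row$n_carbons)])
    truth <- ds$truth$fraction[ds$truth$metabolite == row$metabolite &
                                 ds$truth$condition == row$condition]
    expect_equal(y / sum(y), truth, tolerance = 1e-12)
  }
})

test_that("zero noise + zero dilution: corrected MIDs equal true MIDs", {
  sc <- tracing_scenario(dilution_fraction = 0, noise_cv = 0,
                         n_replicates = 1, seed = 2)
  ds <- gen_isotopologue_dataset(sc)
  mids <- correct_mid_table(ds$spectra, p13 = sc$natural_abundance_p)
  joined <- dplyr::inner_join(
    mids, ds$truth,
    by = c("metabolite", "condition", "isotopologue"),
    suffix = c("", "_true"))
  expect_equal(nrow(joined), nrow(mids))
  expect_lt(max(abs(joined$fraction - joined$fraction_true)), 1e-9)
})

test_that("dilution mixture law holds exactly at zero noise", {
  # 90% labeled pyruvate diluted by d = 0.2778 gives 65% labeled lactate
  sc <- tracing_scenario(dilution_fraction = 0.2778, noise_cv = 0,
                         n_replicates = 1, seed = 3)
  ds <- gen_isotopologue_dataset(sc)
  tr <- unique(ds$truth[, c("metabolite", "condition", "labeled_fraction")])
  pyr <- tr$labeled_fraction[tr$metabolite == "pyruvate" &
                               tr$condition == "control"]
  lac <- tr$labeled_fraction[tr$metabolite == "lactate" &
                               tr$condition == "control"]
  expect_equal(pyr, 90)
  expect_equal(lac, (1 - 0.2778) * 90, tolerance = 1e-12)
  # and the downstream pipeline recovers it from the noiseless spectra
  mids <- correct_mid_table(ds$spectra, p13 = sc$natural_abundance_p)
  f <- mids[mids$metabolite == "lactate" & mids$condition == "control", ]
  expect_equal(100 * (1 - f$fraction[f$isotopologue == 0]), lac,
               tolerance = 1e-6)
})

test_that("tracing generator is seed-deterministic and validates inputs", {
  expect_identical(gen_isotopologue_dataset(tracing_scenario(seed = 7)),
                   gen_isotopologue_dataset(tracing_scenario(seed = 7)))
  expect_false(identical(
    gen_isotopologue_dataset(tracing_scenario(seed = 7))$spectra,
    gen_isotopologue_dataset(tracing_scenario(seed = 8))$spectra))
  expect_error(tracing_scenario(dilution_fraction = 1.2), "dilution_fraction")
  expect_error(tracing_scenario(n_replicates = 0), "n_replicates")
  # dilution against a mismatched carbon count is rejected
  mets <- tibble::tibble(metabolite = c("pyruvate", "lactate"),
                         n_carbons = c(4L, 3L))
  mids <- dplyr::bind_rows(
    tibble::tibble(metabolite = "pyruvate", condition = "control",
                   isotopologue = 0:4, fraction = c(0.1, 0, 0, 0, 0.9)))
  expect_error(
    gen_isotopologue_dataset(tracing_scenario(metabolites = mets,
                                              true_mids = mids)),
    "mismatch")
})

test_that("nuclei-image generator honours its ground-truth contract", {
  blank <- gen_nuclei_image(image_scenario(n_nuclei = 0, seed = 1))
  expect_equal(nrow(blank$nuclei), 0)
  expect_equal(nrow(blank$foci), 0)
  expect_true(all(blank$labels == 0))

  sc <- image_scenario(n_nuclei = 10, noise_sd = 0, seed = 4,
                       foci = list(type = "fixed", count = 3))
  f <- gen_nuclei_image(sc, "control")
  # exactly 10 connected DAPI components by construction
  comp <- EBImage::bwlabel(EBImage::Image(f$dapi > f$dapi[1, 1]))
  expect_equal(max(comp), 10)
  expect_true(all(f$nuclei$n_foci == 3))
  expect_equal(nrow(f$foci), 30)
  expect_true(all(f$dapi >= 0) && all(f$gh2ax >= 0))
  # no overlap: pairwise center distances exceed radius sums
  d <- as.matrix(dist(f$nuclei[, c("x", "y")]))
  rs <- outer(f$nuclei$radius, f$nuclei$radius, "+")
  expect_true(all(d[upper.tri(d)] > rs[upper.tri(rs)]))
  expect_identical(gen_nuclei_image(sc, "treated"),
                   gen_nuclei_image(sc, "treated"))
  # infeasible placement errors rather than truncating
  expect_error(
    gen_nuclei_image(image_scenario(n_nuclei = 40, image_size = c(64, 64),
                                    max_tries = 200, seed = 1)),
    "non-overlapping")
})

test_that("calibration generator is linear at zero noise and seeded", {
  sc <- calibration_scenario(relative_noise_sd = 0, seed = 5)
  run <- add_signal_ratios(gen_calibration_run(sc)$run)
  std <- run[run$role == "standard", ]
  expect_equal(std$ratio, 0.02 * std$nominal_ppb, tolerance = 1e-12)
  # inverse of the line on a sample row
  smp <- run[run$role == "sample", ][1, ]
  truth <- gen_calibration_run(sc)$truth
  expect_equal(smp$ratio / 0.02,
               truth$true_ppb[truth$sample == smp$sample &
                                truth$type == smp$type],
               tolerance = 1e-12)
  expect_identical(gen_calibration_run(sc), gen_calibration_run(sc))
  expect_error(calibration_scenario(standard_levels = c(5, 1, 10)),
               "increasing")
  expect_false(any(run$clipped))
})

test_that("assay-table generator produces coherent seeded fixtures", {
  a <- gen_assay_tables(seed = 6)
  expect_identical(a, gen_assay_tables(seed = 6))
  expect_true(all(a$clonogenic$colonies <= a$clonogenic$plated))
  expect_true(all(a$senescence$positive <= a$senescence$total))
  expect_setequal(unique(a$lactate_plate$condition), c("control", "CDDP"))
})
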