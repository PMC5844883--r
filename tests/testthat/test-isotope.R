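test_that("correction matrix columns are the enumerated heavy-placement pmfs", {
  for (n in 1:6) {
    for (p in c(0, 0.0107, 0.05)) {
      m <- natural_abundance_matrix(n, p)
      expect_equal(colSums(m$matrix), rep(1, n + 1), ignore_attr = TRUE)
      for (k in 0:n) {
        expect_equal(m$matrix[, k + 1], enumerate_mass_shift(n, k, p),
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
  # p13 = 0 is the identity; hand value at (0,0)
  expect_equal(natural_abundance_matrix(3, 0)$matrix, diag(4),
               ignore_attr = TRUE)
  expect_equal(natural_abundance_matrix(3, 0.011)$matrix[1, 1], 0.989^3)
  expect_error(natural_abundance_matrix(3, 1), "p13")
  expect_error(natural_abundance_matrix(3, -0.1), "p13")
})

test_that("correct_mid inverts the forward convolution", {
  m <- natural_abundance_matrix(3, 0.0107)
  obs <- as.numeric(m$matrix %*% c(0.5, 0, 0, 0.5))
  expect_equal(correct_mid(obs, m)$fractions, c(0.5, 0, 0, 0.5),
               tolerance = 1e-9)
  # pure unlabeled compound at natural abundance
  nat <- as.numeric(m$matrix %*% c(1, 0, 0, 0))
  expect_equal(correct_mid(nat, m)$fractions, c(1, 0, 0, 0),
               tolerance = 1e-9)
  # p13 = 0 reduces to normalization
  m0 <- natural_abundance_matrix(3, 0)
  expect_equal(correct_mid(c(2, 1, 1, 0), m0)$fractions,
               c(0.5, 0.25, 0.25, 0))
  expect_error(correct_mid(c(0, 0, 0, 0), m), "no signal")
  expect_error(correct_mid(c(1, 1, 1), m), "dimension")
})

test_that("correction round-trips random MIDs and never goes negative", {
  withr::with_seed(11, {
    for (n in 3:6) {
      m <- natural_abundance_matrix(n, 0.0107)
      for (i in 1:25) {
        truth <- random_mid(n)
        got <- correct_mid(as.numeric(m$matrix %*% truth) * 1e5, m)$fractions
        expect_equal(got, truth, tolerance = 1e-9)
        expect_true(all(got >= 0))
      }
    }
  })
})

test_that("labeled fraction and mean enrichment read a MID as specified", {
  expect_equal(labeled_fraction(c(1, 0, 0, 0)), 0)
  expect_equal(labeled_fraction(c(0, 0, 0, 1)), 100)
  expect_equal(labeled_fraction(c(0.35, 0, 0, 0.65)), 65)
  expect_equal(mean_enrichment(c(1, 0, 0, 0)), 0)
  expect_equal(mean_enrichment(c(0, 0, 0, 1)), 100)
  expect_equal(mean_enrichment(c(0.5, 0, 0, 0.5)), 50)
  mid <- correct_mid(c(0.35, 0, 0, 0.65), natural_abundance_matrix(3, 0))
  expect_equal(mid$labeled_fraction, 65)
  expect_equal(mid$mean_enrichment, 65)
})

test_that("condition contrasts match the pooled-t oracle and conventions", {
  mk <- function(cond, f0s) {
    dplyr::bind_rows(lapply(seq_along(f0s), function(r) {
      tibble::tibble(metabolite = "lactate", n_carbons = 3, condition = cond,
                     replicate = r, isotopologue = 0:3,
                     fraction = c(f0s[r], 0, 0, 1 - f0s[r]))
    }))
  }
  mids <- dplyr::bind_rows(mk("a", c(0.40, 0.38, 0.39)),
                           mk("b", c(0.60, 0.58, 0.59)))
  res <- contrast_conditions(mids, "a", "b")
  m3 <- res[res$quantity == "fraction" & res$isotopologue == 3, ]
  orc <- pooled_t_oracle(c(0.60, 0.62, 0.61), c(0.40, 0.42, 0.41))
  expect_equal(m3$t, orc$t, tolerance = 1e-12)
  expect_equal(m3$p, orc$p, tolerance = 1e-12)
  expect_equal(orc$t, -20 * sqrt(1.5), tolerance = 1e-12)  # closed form
  expect_true(m3$significant)
  expect_equal(m3$difference, -0.2, tolerance = 1e-12)

  # identical conditions: zero difference, degenerate p = 1 convention
  same <- dplyr::bind_rows(mk("a", c(0.4, 0.4)),
                           mk("b", c(0.4, 0.4)))
  r0 <- contrast_conditions(same, "a", "b")
  expect_true(all(r0$difference == 0))
  expect_true(all(r0$p == 1))
  expect_true(all(r0$degenerate))
  expect_false(any(r0$significant))

  # zero variance, unequal means: p = 0 convention
  deg <- dplyr::bind_rows(mk("a", c(0.4, 0.4)), mk("b", c(0.6, 0.6)))
  rd <- contrast_conditions(deg, "a", "b")
  expect_true(all(rd$p[rd$isotopologue %in% c(0, 3)] == 0))
  expect_true(all(rd$degenerate))

  expect_error(
    contrast_conditions(dplyr::bind_rows(mk("a", 0.4), mk("b", c(0.6, 0.6))),
                        "a", "b"),
    "insufficient replicates")
})

test_that("labeled-fraction contrasts are emitted on the percent scale", {
  mk <- function(cond, f0s) {
    dplyr::bind_rows(lapply(seq_along(f0s), function(r) {
      tibble::tibble(metabolite = "x", n_carbons = 3, condition = cond,
                     replicate = r, isotopologue = 0:3,
                     fraction = c(f0s[r], 0, 0, 1 - f0s[r]))
    }))
  }
  mids <- dplyr::bind_rows(mk("a", c(0.10, 0.12)), mk("b", c(0.35, 0.37)))
  lf <- contrast_conditions(mids, "a", "b")
  lf <- lf[lf$quantity == "labeled_fraction", ]
  expect_equal(lf$mean_a, 89)
  expect_equal(lf$mean_b, 64)
  expect_equal(lf$difference, -25)
})

test_that("tca_mid_shift restricts contrasts to the requested isotopologues", {
  sc <- tracing_scenario(noise_cv = 0.01, seed = 21)
  mids <- correct_mid_table(gen_isotopologue_dataset(sc)$spectra)
  res <- tca_mid_shift(mids, "citrate", c(2L, 4L), "control", "CDDP")
  expect_equal(sort(res$isotopologue), c(2L, 4L))
  # generator raises citrate m+2 under treatment: positive flagged difference
  expect_gt(res$difference[res$isotopologue == 2], 0)
  expect_true(res$significant[res$isotopologue == 2])
  expect_error(tca_mid_shift(mids, "citrate", 7L, "control", "CDDP"),
               "exceeds")
  expect_error(tca_mid_shift(mids, "malate", 2L, "control", "CDDP"),
               "unknown metabolite")
})
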