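test_that("internal-standard quantification follows the peak-area ratio formula", {
  pt <- peak_table("x", c("zero", "identity", "mix"), c(0, 1000, 2000),
                   is_amount = 0.8, is_peak_area = 1000, sample_weight = 1)
  p <- quantify_content(pt)
  expect_equal(unname(p$contents["zero"]), 0)
  expect_equal(unname(p$contents["identity"]), 0.8)

  pt2 <- peak_table("y", "c", 2000, is_amount = 0.5, is_peak_area = 1000,
                    sample_weight = 1.5)
  expect_equal(unname(quantify_content(pt2)$contents), (2000 * 0.5 / 1000) / 1.5)
  expect_equal(unname(quantify_content(pt2)$contents), 0.666667,
               tolerance = 1e-6)
})

test_that("invalid internal-standard fields are rejected by name", {
  expect_error(peak_table("x", "a", 1, is_amount = 0.5, is_peak_area = 0,
                          sample_weight = 1), "is_peak_area")
  expect_error(peak_table("x", "a", 1, is_amount = 0.5, is_peak_area = 10,
                          sample_weight = -1), "sample_weight")
  expect_error(peak_table("x", c("a", "a"), c(1, 2), is_amount = 0.5,
                          is_peak_area = 10, sample_weight = 1), "unique")
})

test_that("empty peak list yields an empty profile with total zero", {
  p <- quantify_content(peak_table("x", character(0), numeric(0),
                                   is_amount = 0.5, is_peak_area = 10,
                                   sample_weight = 1))
  expect_equal(p$total, 0)
  expect_length(p$contents, 0)
})

test_that("quantification is linear in peak areas and invariant to a global rescale", {
  set.seed(42)
  for (rep in 1:10) {
    areas <- runif(6, 10, 1e5)
    pt <- peak_table("x", letters[1:6], areas, is_amount = 0.7,
                     is_peak_area = 5e4, sample_weight = 1.3)
    p <- quantify_content(pt)
    expect_equal(sum(p$percents), 100, tolerance = 1e-6)

    # doubling all compound areas doubles contents, leaves percents alone
    pt2 <- peak_table("x", letters[1:6], 2 * areas, is_amount = 0.7,
                      is_peak_area = 5e4, sample_weight = 1.3)
    p2 <- quantify_content(pt2)
    expect_equal(p2$contents, 2 * p$contents)
    expect_equal(p2$percents, p$percents)

    # rescaling every area including the internal standard changes nothing
    kf <- runif(1, 0.1, 9)
    pt3 <- peak_table("x", letters[1:6], kf * areas, is_amount = 0.7,
                      is_peak_area = kf * 5e4, sample_weight = 1.3)
    expect_equal(quantify_content(pt3)$contents, p$contents)
  }
})

test_that("major-compound selection uses a strict threshold across profiles", {
  mk <- function(id, comps, areas) {
    quantify_content(peak_table(id, comps, areas, is_amount = 1,
                                is_peak_area = 1, sample_weight = 1))
  }
  p1 <- mk("a", c("A", "B"), c(50, 50))
  expect_equal(select_major_compounds(list(p1), 10), c("A", "B"))

  # X sits at exactly 10%: excluded under the strict rule
  p2 <- mk("b", c("X", "Y"), c(10, 90))
  expect_equal(select_major_compounds(list(p2), 10), "Y")
  expect_equal(select_major_compounds(list(p1, p2), 10), c("A", "B", "Y"))
  expect_error(select_major_compounds(list(), 10), "at least one")
  expect_error(select_major_compounds(list(p1), 0))
})

test_that("odor-class aggregation sums percents per class and flags unmapped compounds", {
  omap <- c(eucalyptol = "cool", "methyl benzoate" = "fruity",
            "ethyl benzoate" = "fruity", myrcene = "herbal")
  mk <- function(comps, areas) {
    quantify_content(peak_table("x", comps, areas, is_amount = 1,
                                is_peak_area = 1, sample_weight = 1))
  }
  a <- aggregate_odor_classes(mk("eucalyptol", 5), omap)
  expect_equal(unname(a$class_percents), c(0, 0, 100, 0, 0))

  a0 <- aggregate_odor_classes(mk(character(0), numeric(0)), omap)
  expect_equal(unname(a0$class_percents), rep(0, 5))
  expect_equal(a0$total_content, 0)

  # two fruity at 40% + 30%, one herbal at 30%
  a3 <- aggregate_odor_classes(
    mk(c("methyl benzoate", "ethyl benzoate", "myrcene"), c(40, 30, 30)), omap)
  expect_equal(unname(a3$class_percents), c(30, 70, 0, 0, 0))

  expect_warning(
    au <- aggregate_odor_classes(mk(c("eucalyptol", "mystery"), c(50, 50)),
                                 omap),
    "mystery")
  expect_equal(unname(au$class_percents["cool"]), 50)
  expect_equal(au$unmapped, "mystery")
  expect_equal(sum(au$class_percents) + au$unmapped_percent, 100,
               tolerance = 1e-6)
})

test_that("aggregation conserves total percentage for random profiles", {
  omap <- read_odor_map()
  set.seed(7)
  for (rep in 1:10) {
    comps <- c(sample(names(omap), 4), "unmapped_compound")
    p <- quantify_content(peak_table("x", comps, runif(5, 1, 100),
                                     is_amount = 1, is_peak_area = 1,
                                     sample_weight = 1))
    a <- suppressWarnings(aggregate_odor_classes(p, omap))
    expect_equal(sum(a$class_percents) + a$unmapped_percent, 100,
                 tolerance = 1e-6)
  }
})

test_that("aroma classification reproduces reference group assignments", {
  # eucalyptol-dominated profile -> cool group
  expect_equal(classify_aroma(aroma_profile("rs", c(9.36, 1.49, 66.30, 1.77, 0.18))),
               "cool")
  # ester-dominated profile -> fruity group
  expect_equal(classify_aroma(aroma_profile("br", c(3.21, 87.69, 2.21, 1.72, 0.33))),
               "fruity")
  # no emission -> faint
  expect_equal(classify_aroma(aroma_profile("z", rep(0, 5), total_content = 0)),
               "faint")
  # ocimene + ester blend -> lily group
  expect_equal(classify_aroma(aroma_profile("so", c(33.42, 36.78, 0, 4.43, 0))),
               "lily")
})

test_that("classification is a pure function, independent of compound order", {
  omap <- c(a = "cool", b = "fruity", c = "herbal")
  areas <- c(a = 60, b = 25, c = 15)
  labels <- vapply(1:5, function(i) {
    ord <- sample(names(areas))
    p <- quantify_content(peak_table("x", ord, areas[ord], is_amount = 1,
                                     is_peak_area = 1, sample_weight = 1))
    classify_aroma(aggregate_odor_classes(p, omap))
  }, character(1))
  expect_length(unique(labels), 1)
})

test_that("malformed classification rules raise a configuration error", {
  a <- aroma_profile("x", c(10, 20, 30, 20, 20))
  expect_error(classify_aroma(a, list(list(label = "bad", when = "sweet > 5"))),
               "unknown field")
  expect_error(classify_aroma(a, list(list(label = "bad"))), "malformed")
  expect_equal(classify_aroma(a, list(list(label = "never", when = "cool > 99"))),
               "unassigned")
})

test_that("peak-table CSV round trip preserves quantification inputs", {
  cfg <- sim_config(seed = 5, n_cultivars = 4)
  emis <- generate_emissions(cfg)
  path <- tempfile(fileext = ".csv")
  write.csv(emis$peaks, path, row.names = FALSE)
  tables <- read_peak_tables(path)
  expect_length(tables, 4)
  p <- quantify_content(tables[[1]])
  expect_equal(unname(p$contents),
               unname(emis$emissions[tables[[1]]$cultivar_id, ]))
})
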