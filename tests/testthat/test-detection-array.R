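test_that("assembly places detections and missing cells correctly", {
  lay <- study_layout("both", replicates_per_plant = 1L)  # 1 site, 2 slots
  arr <- assemble_detection_array(
    data.frame(site = 1, slot = 1, taxon = "A", detected = 1), lay, "A")
  expect_equal(unname(arr$y[1, 1, ]), c(1L, 0L))

  # empty record list, study layout, 14 taxa: all-zero, 350 cells per taxon
  lay50 <- garden_layout()
  taxa <- paste0("sp", 1:14)
  empty <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)), lay50, taxa)
  expect_equal(dim(empty$y), c(14L, 50L, 10L))
  expect_equal(sum(!is.na(empty$y[1, , ])), 350L)
  expect_true(all(empty$y == 0L, na.rm = TRUE))

  # a record at a slot the layout never surveyed errors
  lay2 <- study_layout(c("pm_only", "both"), replicates_per_plant = 2L)
  expect_error(assemble_detection_array(
    data.frame(site = 1, slot = 3, taxon = "A", detected = 1), lay2, "A"),
    "not surveyed")
  # unknown taxa and plant-label mismatches error
  expect_error(assemble_detection_array(
    data.frame(site = 2, slot = 1, taxon = "B", detected = 1), lay2, "A"),
    "unknown taxa")
  expect_error(assemble_detection_array(
    data.frame(site = 2, slot = 1, plant = "LS", taxon = "A", detected = 1),
    lay2, "A"), "disagree")
  # duplicates collapse with a warning
  expect_warning(
    arr2 <- assemble_detection_array(
      data.frame(site = c(2, 2), slot = c(1, 1), taxon = "A",
                 detected = c(1, 1)), lay2, "A"),
    "duplicate")
  expect_equal(sum(arr2$y == 1L, na.rm = TRUE), 1L)
})

test_that("augmentation appends all-zero slices and propagates missingness", {
  lay <- garden_layout()
  arr <- assemble_detection_array(
    data.frame(site = 3, slot = 2, taxon = "sp1", detected = 1),
    lay, paste0("sp", 1:14))
  aug <- augment_detection_array(arr, 35L)
  expect_equal(dim(aug$y)[1], 49L)
  expect_equal(aug$n_observed, 14L)
  expect_equal(aug$n_augmented, 35L)
  # augmented slice at a pm_only site has missing L. spicata slots
  pm_site <- which(lay$availability == "pm_only")[1]
  expect_equal(sum(is.na(aug$y[49, pm_site, ])), 5L)
  # augmentation preserves the non-missing cell count of every slice
  for (i in c(1L, 20L, 49L))
    expect_equal(sum(!is.na(aug$y[i, , ])), 350L)
  # identity augmentation
  expect_identical(augment_detection_array(arr, 0L), arr)
  # augmented slices are validated as all-zero
  expect_silent(validate_detection_array(aug))
})

test_that("records of an array with no observed taxa are empty but well-formed", {
  lay <- tiny_layout(r = 2L)
  none <- msomaug:::new_detection_array(
    array(NA_integer_, dim = c(0, 3, 4)), character(0), 0L, 0L, lay)
  rec <- detection_records(none)
  expect_equal(nrow(rec), 0L)
  expect_setequal(names(rec), c("site", "slot", "plant", "taxon", "detected"))
})

test_that("long-format round trip preserves array, mask and labels", {
  lay <- tiny_layout(r = 2L)
  m1 <- matrix(0L, 3, 4); m1[1, 2] <- 1L; m1[2, 1] <- 1L
  m2 <- matrix(0L, 3, 4); m2[3, 2] <- 1L
  arr <- array_from_matrices(list(m1, m2), lay, c("bee", "wasp"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_records(arr, path)
  back <- read_detection_records(path, lay, taxa = c("bee", "wasp"))
  expect_identical(back$y, arr$y)
  expect_identical(back$taxa, arr$taxa)
  expect_identical(is.na(back$y), is.na(arr$y))
})
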