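grid_of <- function(vals, dims = NULL, spacing = 10) {
  if (is.null(dims)) dims <- c(length(vals), 1, 1)
  dose_grid(array(vals, dims), spacing = spacing)
}
mask_of <- function(keep, dims = NULL, spacing = 10, name = "s") {
  if (is.null(dims)) dims <- c(length(keep), 1, 1)
  structure_mask(name, array(keep, dims), spacing = spacing)
}

# brute-force DVH oracle: explicit count loop per threshold
brute_dvh <- function(doses, at) {
  vapply(at, function(d) {
    n <- 0
    for (x in doses) if (x >= d) n <- n + 1
    n / length(doses)
  }, numeric(1))
}

test_that("cumulative DVH matches its definition on simple cases", {
  d <- grid_of(rep(2, 8), c(2, 2, 2))
  m <- mask_of(rep(TRUE, 8), c(2, 2, 2))
  dvh <- compute_dvh(d, m)
  expect_equal(dvh$volume[dvh$dose == 0], 1)
  expect_equal(dvh_query(dvh, "V", 2), 1)
  expect_equal(dvh_query(dvh, "V", 2 + 1e-9), 0)

  dvh2 <- compute_dvh(grid_of(c(1, 3)), mask_of(c(TRUE, TRUE)))
  expect_equal(dvh_query(dvh2, "V", 1), 1.0)
  expect_equal(dvh_query(dvh2, "V", 3), 0.5)
  expect_equal(dvh_query(dvh2, "D", 0.5), 3)
  expect_equal(dvh_query(dvh2, "D", 0.99), 1)
  expect_equal(dvh_query(dvh2, "mean"), 2)
  expect_equal(dvh_query(dvh2, "max"), 3)
})

test_that("DVH agrees with a brute-force oracle and is nonincreasing", {
  withr::with_seed(29, {
    for (k in 1:10) {
      n <- sample(50:1000, 1)
      doses <- round(runif(n, 0, 10), 1)     # force ties
      dims <- c(n, 1, 1)
      dvh <- compute_dvh(grid_of(doses, dims), mask_of(rep(TRUE, n), dims))
      expect_equal(dvh$volume, brute_dvh(doses, dvh$dose))
      expect_true(all(diff(dvh$volume) <= 0))
      expect_equal(dvh$volume[1], 1)
    }
  })
})

test_that("DVH rejects empty structures and bad queries", {
  d <- grid_of(1:4)
  expect_error(compute_dvh(d, mask_of(rep(FALSE, 4))), "empty structure")
  dvh <- compute_dvh(d, mask_of(rep(TRUE, 4)))
  expect_error(dvh_query(dvh, "D", 0), "\\(0, 1\\]")
  expect_error(dvh_query(dvh, "D", 1.5), "\\(0, 1\\]")
})

test_that("conformity index is the 95%-isodose to CTV volume ratio", {
  dims <- c(10, 10, 10)
  vals <- array(0, dims)
  ctv <- array(FALSE, dims)
  ctv[3:7, 3:7, 3:7] <- TRUE              # 125 voxels
  vals[ctv] <- 10
  body <- array(TRUE, dims)
  d <- dose_grid(vals, spacing = 2)
  expect_equal(conformity_index(d, structure_mask("body", body, spacing = 2),
                                structure_mask("ctv", ctv, spacing = 2), 10), 1)

  hot <- array(FALSE, dims); hot[1:250] <- TRUE
  vals2 <- array(0, dims); vals2[hot] <- 10
  small_ctv <- array(FALSE, dims); small_ctv[1:100] <- TRUE
  expect_equal(conformity_index(dose_grid(vals2, spacing = 2),
                                structure_mask("body", body, spacing = 2),
                                structure_mask("ctv", small_ctv, spacing = 2),
                                10), 2.5)
  # raising the prescription can only shrink the isodose volume
  withr::with_seed(31, {
    vals3 <- array(runif(1000, 0, 10), dims)
    d3 <- dose_grid(vals3, spacing = 2)
    b <- structure_mask("body", body, spacing = 2)
    c2 <- structure_mask("ctv", small_ctv, spacing = 2)
    expect_lte(conformity_index(d3, b, c2, 8), conformity_index(d3, b, c2, 4))
  })
})

test_that("integral dose is mean body dose times body volume in Gy*L", {
  # 1000 voxels of 1 cc = 1 L at 1 Gy
  dims <- c(10, 10, 10)
  d <- dose_grid(array(1, dims), spacing = 10)
  b <- structure_mask("body", array(TRUE, dims), spacing = 10)
  expect_equal(integral_dose(d, b), 1.0)

  d2 <- dose_grid(array(2, c(15, 10, 10)), spacing = 10)
  b2 <- structure_mask("body", array(TRUE, c(15, 10, 10)), spacing = 10)
  expect_equal(integral_dose(d2, b2), 3.0)

  # linearity in dose scale, and mass conservation over the whole grid
  withr::with_seed(37, {
    vals <- array(runif(1000), dims)
    da <- dose_grid(vals, spacing = 10)
    db <- dose_grid(2 * vals, spacing = 10)
    expect_equal(integral_dose(db, b), 2 * integral_dose(da, b))
    expect_equal(integral_dose(da, b), sum(vals) * 1 / 1000)
  })
})

test_that("CI and ID have set semantics under voxel permutation", {
  withr::with_seed(41, {
    dims <- c(8, 8, 8)
    vals <- runif(512, 0, 10)
    keep <- runif(512) < 0.3
    perm <- sample(512)
    d1 <- dose_grid(array(vals, dims), spacing = 5)
    d2 <- dose_grid(array(vals[perm], dims), spacing = 5)
    b1 <- structure_mask("body", array(TRUE, dims), spacing = 5)
    c1 <- structure_mask("ctv", array(keep, dims), spacing = 5)
    c2 <- structure_mask("ctv", array(keep[perm], dims), spacing = 5)
    expect_equal(integral_dose(d1, b1), integral_dose(d2, b1))
    expect_equal(conformity_index(d1, b1, c1, 8),
                 conformity_index(d2, b1, c2, 8))
  })
})

test_that("NRRD files round-trip grids and masks", {
  withr::with_seed(43, {
    d <- dose_grid(array(runif(60), c(3, 4, 5)), origin = c(-10, 0, 5),
                   spacing = c(2, 2.5, 3))
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(d, f)
    d2 <- read_nrrd(f)
    expect_equal(d2$values, d$values, tolerance = 1e-10)
    expect_equal(d2$origin, d$origin)
    expect_equal(d2$spacing, d$spacing)

    msk <- structure_mask("ctv", array(runif(60) > 0.5, c(3, 4, 5)),
                          spacing = 2)
    fm <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(msk, fm)
    m2 <- read_nrrd(fm, as_mask = TRUE, name = "ctv")
    expect_equal(m2$mask, msk$mask)
  })
})
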