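test_that("wide tables parse with correct shape and sorted grid", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,A,B,C",
               "604,1,2,3", "600,4,5,6", "610,7,8,9",
               "602,0,1,2", "608,3,4,5"), path)
  s <- read_spectra(path, "wide")
  expect_equal(n_spectra(s), 3)
  expect_equal(n_channels(s), 5)
  expect_equal(s$wavenumber, c(600, 602, 604, 608, 610))
  expect_equal(s$meta$spectrum_id, c("A", "B", "C"))
  expect_equal(unname(s$intensities[1, ]), c(4, 0, 1, 3, 7))
})

test_that("long tables are sort-invariant and reject inconsistent grids", {
  asc <- withr::local_tempfile(fileext = ".csv")
  desc <- withr::local_tempfile(fileext = ".csv")
  w <- seq(600, 640, by = 10)
  y <- c(5, 3, 8, 1, 9)
  writeLines(c("spectrum_id,wavenumber_cm-1,intensity",
               paste("S1", w, y, sep = ",")), asc)
  writeLines(c("spectrum_id,wavenumber_cm-1,intensity",
               paste("S1", rev(w), rev(y), sep = ",")), desc)
  expect_equal(read_spectra(asc, "long"), read_spectra(desc, "long"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,wavenumber_cm-1,intensity",
               paste("S1", w, y, sep = ","),
               paste("S2", w + 1, y, sep = ",")), bad)
  expect_error(read_spectra(bad, "long"), "resample_to_grid")
})

test_that("duplicate wavenumbers and non-numeric cells are parse errors", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,A", "1089.0,1", "1089.0,2", "1090,3"), dup)
  expect_error(read_spectra(dup, "wide"), "duplicate wavenumber")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,A", "600,1", "601,oops", "602,3"), bad)
  expect_error(read_spectra(bad, "wide"), "non-numeric.*'A'.*row 2")
})

test_that("write/read round-trips both dialects on randomized sets", {
  for (seed in 1:3) {
    s <- random_set(n_spec = 4, seed = seed,
                    labels = sample(c("intact", "damaged", "unknown"), 4,
                                    replace = TRUE))
    for (dialect in c("wide", "long")) {
      f <- withr::local_tempfile(fileext = ".csv")
      md <- withr::local_tempfile(fileext = ".csv")
      write_spectra(s, f, dialect, metadata_path = md)
      r <- read_spectra(f, dialect, metadata = md)
      expect_equal(r$wavenumber, s$wavenumber)
      expect_equal(r$intensities, s$intensities, tolerance = 1e-9)
      expect_equal(r$meta$label, s$meta$label)
    }
  }
})

test_that("an empty set writes a header-only file that reads back", {
  s <- spectrum_set(tiny_grid(), matrix(0, 0, 12),
                    data.frame(spectrum_id = character(0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, f, "wide")
  r <- read_spectra(f, "wide")
  expect_equal(n_spectra(r), 0)
  expect_equal(r$wavenumber, s$wavenumber)
})

test_that("extra metadata columns are carried through untouched", {
  s <- random_set(2, seed = 5)
  md <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum_id,label,operator,batch",
               "S1,intact,ana,7", "S2,unknown,ben,7"), md)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, f, "wide")
  r <- read_spectra(f, "wide", metadata = md)
  expect_equal(r$meta$operator, c("ana", "ben"))
  expect_equal(r$meta$label, c("intact", "unknown"))
})

test_that("crop keeps the closed interval, is idempotent, preserves rows", {
  s <- spectrum_set(c(400, 600, 1000, 1800, 2000), matrix(1:10, 2, 5,
                                                          byrow = TRUE))
  cr <- crop(s, 600, 1800)
  expect_equal(cr$wavenumber, c(600, 1000, 1800))
  expect_equal(n_spectra(cr), 2)
  expect_equal(crop(cr, 600, 1800), cr)
  expect_error(crop(s, 1900, 1950), "no channels")
  expect_error(crop(s, 800, 700), "lo < hi")
})

test_that("resampling is the identity on the source grid and exact on affine data", {
  g <- tiny_grid()
  s <- spectrum_set(g, matrix(2.5 * g - 40, 1))
  expect_equal(resample_to_grid(s, g)$intensities, s$intensities)
  target <- seq(min(g) + 1.3, max(g) - 2.1, length.out = 9)
  r <- resample_to_grid(s, target)
  expect_equal(unname(r$intensities[1, ]), 2.5 * target - 40, tolerance = 1e-12)
  expect_error(resample_to_grid(s, c(599, 650)), "extrapolation")
})

test_that("the container validates grids, labels and ids", {
  expect_error(spectrum_set(c(600, 600, 601), matrix(0, 1, 3)),
               "strictly increasing")
  expect_error(spectrum_set(tiny_grid(), matrix(NaN, 1, 12)), "finite")
  expect_silent(spectrum_set(tiny_grid(), matrix(NaN, 1, 12), allow_na = TRUE))
  expect_error(spectrum_set(tiny_grid(), matrix(0, 1, 12),
                            data.frame(spectrum_id = "a", label = "broken")),
               "label")
  expect_error(spectrum_set(tiny_grid(), matrix(0, 2, 12),
                            data.frame(spectrum_id = c("a", "b"),
                                       cell_id = c("c1", "c1"))),
               "cell_id")
})
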