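write_csv_fixture <- function(rows, dir = tempfile("man")) {
  dir.create(dir)
  path <- file.path(dir, "manifest.csv")
  writeLines(c("Image Index,Finding Labels", rows), path)
  path
}

test_that("NIH-dialect manifests parse pipe-delimited findings", {
  path <- write_csv_fixture(c(
    'img1.png,Effusion|Cardiomegaly',
    'img2.png,No Finding',
    'img3.png,Atelectasis'))
  man <- read_manifest(path)
  expect_s3_class(man$records, "tbl_df")
  expect_equal(man$records$labels[[1]], c("Effusion", "Cardiomegaly"))
  expect_equal(man$records$labels[[2]], character(0))   # normal record
  lm <- label_matrix(man)
  expect_equal(dim(lm), c(3L, 14L))
  expect_equal(sum(lm[2, ]), 0L)
  expect_equal(lm[1, "Effusion"], 1L)
  expect_equal(lm[1, "Cardiomegaly"], 1L)
  expect_equal(sum(lm), 3L)
})

test_that("manifest validation reports offending rows", {
  expect_error(read_manifest(write_csv_fixture('a.png,No Finding|Edema')),
               "co-occurs.*row.*1")
  expect_error(read_manifest(write_csv_fixture(c('a.png,Effusion',
                                                 'b.png,Banana'))),
               "Banana.*row.*2")
  expect_error(read_manifest(write_csv_fixture('a.png,')), "empty findings")
  expect_error(read_manifest(tempfile()), "not found")
})

test_that("missing image files are reported when a directory is given", {
  dir <- tempfile("imgs"); dir.create(dir)
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "ok.png"))
  path <- write_csv_fixture(c('ok.png,Effusion', 'gone.png,Edema'))
  expect_error(read_manifest(path, image_dir = dir), "gone.png")
  man <- read_manifest(write_csv_fixture('ok.png,Effusion'), image_dir = dir)
  expect_equal(nrow(man$records), 1L)
})

test_that("per-class dialect maps uncertain labels to negative", {
  dir <- tempfile("man2"); dir.create(dir)
  path <- file.path(dir, "m.csv")
  writeLines(c("Path,Edema,Cardiomegaly",
               "a.png,1,-1",
               "b.png,0,1",
               "c.png,-1,"), path)
  man <- read_manifest(path, dialect = "per_class")
  lm <- label_matrix(man)
  expect_equal(unname(lm[, "Edema"]), c(1L, 0L, 0L))
  expect_equal(unname(lm[, "Cardiomegaly"]), c(0L, 1L, 0L))
})

test_that("binarize_labels collapses to the normal/abnormal contract", {
  path <- write_csv_fixture(c(
    'img1.png,No Finding',
    'img2.png,Effusion|Cardiomegaly',
    'img3.png,Hernia'))
  bin <- binarize_labels(read_manifest(path))
  lm <- label_matrix(bin)
  expect_equal(colnames(lm), "Abnormal")
  expect_equal(unname(lm[, 1]), c(0L, 1L, 1L))
})

test_that("manifests round-trip through the NIH CSV dialect exactly", {
  spec <- synthetic_spec(n_images = 12L, image_side = 64L, seed = 3L)
  dir <- tempfile("synth")
  man <- generate_synthetic(spec, dir)
  man2 <- read_manifest(file.path(dir, "manifest.csv"), image_dir = dir)
  expect_identical(label_matrix(man2), label_matrix(man))
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  path <- write_csv_fixture(sprintf("img%03d.png,Effusion", 1:100))
  man <- read_manifest(path)
  sp <- split_dataset(man, 0.8, seed = 4L)
  expect_equal(nrow(sp$train$records), 80L)
  expect_equal(nrow(sp$test$records), 20L)
  expect_length(intersect(sp$train$records$image_id,
                          sp$test$records$image_id), 0L)
  expect_setequal(c(sp$train$records$image_id, sp$test$records$image_id),
                  man$records$image_id)
  sp2 <- split_dataset(man, 0.8, seed = 4L)
  expect_identical(sp2$train$records$image_id, sp$train$records$image_id)
  expect_false(identical(split_dataset(man, 0.8, seed = 5L)$train$records,
                         sp$train$records))
  expect_error(split_dataset(man, 1.2), "between 0 and 1")
  expect_error(split_dataset(squeezevit:::subset_manifest(man, 1L), 0.8),
               "fewer than 2")
})

test_that("patient-level splits keep a patient on one side", {
  path <- write_csv_fixture(sprintf("img%03d.png,Effusion", 1:20))
  man <- read_manifest(path)
  man$records$patient_id <- rep(1:5, each = 4)
  sp <- split_dataset(man, 0.6, seed = 1L, by = "patient")
  tr_p <- unique(sp$train$records$patient_id)
  te_p <- unique(sp$test$records$patient_id)
  expect_length(intersect(tr_p, te_p), 0L)
})

test_that("preprocess normalises, collapses RGB and resizes", {
  const <- matrix(0.25, 50, 50)
  out <- preprocess_image(const, side = 224L)
  expect_equal(dim(out), c(224L, 224L))
  expect_true(all(abs(out - 0.25) < 1e-12))

  big <- with_seed(5, matrix(runif(448 * 448), 448, 448))
  expect_equal(dim(preprocess_image(big, side = 224L)), c(224L, 224L))

  # 8-bit 255 decodes to exactly 1.0
  path <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 10, 10), path)
  expect_equal(max(preprocess_image(path, side = 16L)), 1.0)

  rgb <- array(0, c(20, 20, 3)); rgb[, , 1] <- 1   # pure red
  expect_true(all(abs(preprocess_image(rgb, side = 8L) - 0.299) < 1e-6))

  expect_error(preprocess_image(tempfile(fileext = ".png")), "cannot read")
  bad <- tempfile(fileext = ".png"); writeLines("junk", bad)
  expect_error(preprocess_image(bad), "undecodable")
})

test_that("load_images stacks preprocessed images in manifest order", {
  dir <- tempfile("imgs2"); dir.create(dir)
  png::writePNG(matrix(0.2, 32, 32), file.path(dir, "a.png"))
  png::writePNG(matrix(0.8, 32, 32), file.path(dir, "b.png"))
  path <- file.path(dir, "m.csv")
  writeLines(c("Image Index,Finding Labels",
               "a.png,No Finding", "b.png,Edema"), path)
  man <- read_manifest(path, image_dir = dir)
  imgs <- load_images(man, side = 32L)
  expect_equal(dim(imgs), c(32L, 32L, 2L))
  expect_equal(mean(imgs[, , 1]), 0.2, tolerance = 1e-2)
  expect_equal(mean(imgs[, , 2]), 0.8, tolerance = 1e-2)
})
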