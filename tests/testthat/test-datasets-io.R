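test_that("label mapping covers every documented vocabulary deterministically", {
  expect_identical(map_label("happiness", "samm-like"), 1L)
  expect_identical(map_label("other", "samm-like"), 0L)
  expect_identical(map_label("negative", "smic-like"), 0L)
  expect_identical(map_label("positive", "smic-like"), 1L)
  expect_identical(map_label("surprise", "samm-like"), 2L)
  expect_identical(map_label("surprise", "smic-like"), 2L)
  expect_identical(map_label("surprise", "ck-like"), 2L)
  for (neg in c("anger", "contempt", "disgust", "fear", "sadness")) {
    expect_identical(map_label(neg, "ck-like"), 0L)
  }
  expect_identical(map_label("HAPPINESS ", "samm-like"), 1L)
  expect_error(map_label("boredom", "samm-like"), "boredom")
})

test_that("scan_dataset builds one sample per clip and preserves subjects", {
  root <- file.path(tempdir(), "samm_tree")
  spec <- data.frame(
    clip_id = sprintf("clip%02d", 1:6),
    subject_id = rep(c("A", "B", "C"), each = 2),
    label = rep(c("other", "happiness"), 3),
    apex_index = c(2, 3, NA, 2, 3, 2))
  write_corpus(root, spec)
  cat <- scan_dataset(root, "samm-like", fps = 200)
  expect_s3_class(cat, "me_catalog")
  expect_equal(nrow(cat), 6)
  expect_setequal(unique(cat$subject_id), c("A", "B", "C"))
  expect_true(all(cat$domain == 0))
  expect_equal(cat$apex_index[1], 2L)
  expect_true(is.na(cat$apex_index[3]))
  expect_equal(cat$fps[1], 200)
  unlink(root, recursive = TRUE)
})

test_that("smic-like trees carry no apex and ck-like trees are macro domain", {
  spec <- data.frame(clip_id = c("c1", "c2"), subject_id = c("A", "B"),
                     label = c("negative", "positive"), apex_index = c(2, 3))
  root <- write_corpus(file.path(tempdir(), "smic_tree"), spec)
  cat <- scan_dataset(root, "smic-like")
  expect_true(all(is.na(cat$apex_index)))
  expect_true(all(cat$domain == 0))
  unlink(root, recursive = TRUE)

  spec$label <- c("anger", "happy")
  root <- write_corpus(file.path(tempdir(), "ck_tree"), spec)
  cat <- scan_dataset(root, "ck-like")
  expect_true(all(cat$domain == 1))
  expect_equal(cat$emotion, c(0L, 1L))
  unlink(root, recursive = TRUE)
})

test_that("missing label table is a configuration error; empty clips are skipped", {
  root <- file.path(tempdir(), "broken_tree")
  dir.create(root, showWarnings = FALSE)
  expect_error(scan_dataset(root, "samm-like"), "label table")

  spec <- data.frame(clip_id = c("ok", "empty"), subject_id = c("A", "B"),
                     label = c("other", "other"))
  write_corpus(root, spec)
  unlink(file.path(root, "empty", list.files(file.path(root, "empty"))))
  expect_warning(cat <- scan_dataset(root, "samm-like"), "empty")
  expect_equal(nrow(cat), 1)
  unlink(root, recursive = TRUE)
})

test_that("load_frames rescales to [0,1], converts color by luma, keeps count", {
  root <- file.path(tempdir(), "frames_tree")
  dir.create(file.path(root, "c1"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(matrix(1, 4, 4), file.path(root, "c1", "f1.png"))
  rgb <- array(128 / 255, c(4, 4, 3))
  png::writePNG(rgb, file.path(root, "c1", "f2.png"))
  png::writePNG(matrix(0, 4, 4), file.path(root, "c1", "f3.png"))
  utils::write.csv(data.frame(clip_id = "c1", subject_id = "A",
                              label = "other"),
                   file.path(root, "labels.csv"), row.names = FALSE)
  cat <- scan_dataset(root, "samm-like")
  fr <- load_frames(catalog_sample(cat, 1))
  expect_equal(dim(fr), c(4, 4, 3))
  expect_equal(max(fr[, , 1]), 1.0)
  expect_equal(fr[1, 1, 2], 128 / 255, tolerance = 1e-6)  # BT.601 on gray
  expect_equal(min(fr[, , 3]), 0.0)
  unlink(root, recursive = TRUE)
})

test_that("catalog manifests round-trip identical metadata", {
  cfg <- synth_config(n_subjects = 2, clips_per_subject = 3,
                      frames_per_clip = 4, height = 16, width = 16, seed = 9)
  cat <- synth_catalog(cfg)
  path <- file.path(tempdir(), "manifest.csv")
  write_catalog_manifest(cat, path)
  back <- read_catalog_manifest(path)
  keep <- setdiff(names(cat), "frames")
  expect_equal(as.data.frame(back[, keep]), as.data.frame(cat[, keep]))
  unlink(path)
})
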