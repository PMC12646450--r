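# Data model and file formats: EDF round trip, hypnogram TSV mapping,
# manifest plumbing, and epoch segmentation geometry.

test_that("EDF writer/reader round-trips signals within 16-bit quantization", {
  set.seed(42)
  fs <- 400
  sig <- matrix(rnorm(fs * 10 * 4, sd = 30), ncol = 4)
  colnames(sig) <- c("F3", "F4", "Fz", "Cz")
  path <- tempfile(fileext = ".edf")
  write_edf(path, sig, fs, colnames(sig))
  edf <- read_edf(path)
  expect_equal(edf$fs, fs)
  expect_equal(edf$channel_labels, colnames(sig))
  expect_equal(nrow(edf$signals), fs * 10)
  qstep <- (max(abs(sig)) * 2.0002) / 65535
  expect_lt(max(abs(edf$signals - sig)), qstep)
  unlink(path)
})

test_that("load_recording reorders channels and names missing ones", {
  set.seed(7)
  fs <- 400
  sig <- matrix(rnorm(fs * 2 * 4), ncol = 4)
  path <- tempfile(fileext = ".edf")
  write_edf(path, sig, fs, c("Cz", "F3", "F4", "Fz"))
  rec <- load_recording(path, c("F3", "F4", "Fz", "Cz"))
  expect_identical(rec$channels, c("F3", "F4", "Fz", "Cz"))
  # column content follows the label, not the file order
  expect_equal(rec$signals[, "Cz"], unname(read_edf(path)$signals[, "Cz"]))
  expect_error(load_recording(path, c("F3", "Pz")), "Pz")
  unlink(path)
  expect_error(load_recording(tempfile(), c("F3")), "not found")
})

test_that("hypnogram TSV maps labels to the fixed 0-3 coding", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("epoch_index\tstate\tartifact_flag",
               "0\tW\tFALSE", "1\tD\tFALSE", "2\tNREM\tTRUE",
               "3\tREM\tFALSE"), path)
  hyp <- load_hypnogram(path)
  expect_identical(hyp$states, 0:3)
  expect_identical(hyp$artifact_flags, c(FALSE, FALSE, TRUE, FALSE))
  unlink(path)
})

test_that("hypnogram loader handles empty files and rejects bad input", {
  path <- tempfile(fileext = ".tsv")
  writeLines("epoch_index\tstate\tartifact_flag", path)
  hyp <- load_hypnogram(path)
  expect_length(hyp$states, 0)

  writeLines(c("epoch_index\tstate\tartifact_flag",
               "0\twake\tFALSE", "1\tN3\tFALSE"), path)
  expect_error(load_hypnogram(path), "N3")
  expect_error(load_hypnogram(path), "row 2")

  writeLines(c("epoch_index\tstate\tartifact_flag",
               "0\twake\tFALSE", "2\twake\tFALSE"), path)
  expect_error(load_hypnogram(path), "contiguous")
  unlink(path)
})

test_that("hypnogram round-trips through TSV bit-exactly", {
  set.seed(3)
  hyp <- hypnogram(sample(0:3, 50, replace = TRUE),
                   sample(c(TRUE, FALSE), 50, replace = TRUE))
  path <- tempfile(fileext = ".tsv")
  write_hypnogram(hyp, path)
  back <- load_hypnogram(path)
  expect_identical(back$states, hyp$states)
  expect_identical(back$artifact_flags, hyp$artifact_flags)
  unlink(path)
})

test_that("manifest loader enforces one session per subject-condition", {
  dir <- tempfile(); dir.create(dir)
  man <- data.frame(subject_id = c("a", "a"), condition = c("control", "control"),
                    recording_path = "r.edf", hypnogram_path = "h.tsv")
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(path), "at most once")
  man$condition <- c("control", "trazodone")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- load_manifest(path)
  expect_equal(got$recording_path, file.path(dir, c("r.edf", "r.edf")))
  unlink(dir, recursive = TRUE)
})

test_that("segmentation yields 1200-sample half-open epochs at 400 Hz", {
  fs <- 400
  rec <- session_recording(matrix(seq_len(2400 * 2), ncol = 2,
                                  dimnames = list(NULL, c("F3", "F4"))), fs)
  hyp <- hypnogram(c(0, 2))
  sets <- segment_epochs(rec, hyp)
  expect_equal(nrow(sets$wake$epochs[[1]]), 1200)
  expect_equal(nrow(sets$nrem$epochs[[1]]), 1200)
  # half-open: epoch 0 is samples 1..1200, epoch 1 is 1201..2400
  expect_equal(sets$wake$epochs[[1]][, 1], 1:1200)
  expect_equal(sets$nrem$epochs[[1]][, 1], 1201:2400)
})

test_that("segmentation drops trailing samples but rejects under-covered scorings", {
  fs <- 400
  mk <- function(n) session_recording(matrix(rnorm(n), ncol = 1,
                                             dimnames = list(NULL, "Fz")), fs)
  # 150 trailing samples beyond the scored epoch are dropped
  sets <- segment_epochs(mk(1350), hypnogram(2))
  expect_length(sets$nrem$epochs, 1)
  expect_equal(nrow(sets$nrem$epochs[[1]]), 1200)
  # recording shorter than the scoring: no complete epoch -> error
  expect_error(segment_epochs(mk(1199), hypnogram(2)), "shorter")
  # more than one epoch missing -> error
  expect_error(segment_epochs(mk(1200), hypnogram(c(2, 2, 2))),
               "more than one epoch")
  # exactly one tail epoch missing is dropped, not padded
  sets <- segment_epochs(mk(1800), hypnogram(c(2, 2)))
  expect_length(sets$nrem$epochs, 1)
})

test_that("concatenated epochs reproduce the scored span of the signal", {
  set.seed(11)
  fs <- 400
  sig <- matrix(rnorm(1200 * 4 * 2), ncol = 2,
                dimnames = list(NULL, c("F3", "F4")))
  rec <- session_recording(sig, fs)
  hyp <- hypnogram(c(0, 2, 2, 1))
  sets <- segment_epochs(rec, hyp)
  all_idx <- unlist(lapply(sets, `[[`, "source_indices"))
  ord <- order(all_idx)
  all_ep <- unlist(lapply(sets, `[[`, "epochs"), recursive = FALSE)[ord]
  expect_equal(do.call(rbind, all_ep), sig, ignore_attr = TRUE)
})

test_that("recording invariants are enforced", {
  expect_error(session_recording(matrix(0, 10, 2), fs = 400,
                                 channel_labels = c("A", "A")), "unique")
  expect_error(session_recording(matrix(0, 10, 2), fs = -1,
                                 channel_labels = c("A", "B")), "positive")
  expect_error(hypnogram(c(0, 5)), "0:3")
  expect_error(hypnogram(c(0, 1), artifact_flags = TRUE), "length")
})
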