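# Dataset container, clip-level splits, and the plain-text container IO.

make_tiny_dataset <- function(n_clips = 10, n_neurons = 2, M = 3, T = 30,
                              seed = 5) {
  stims <- generate_stimuli(4, T, n_clips, seed = seed)
  strfs <- random_strfs(n_neurons, 4, 3, seed = seed + 1)
  truth <- synthetic_truth(strfs,
                           noise = list(type = "gaussian", sigma = 0.1),
                           seed = seed + 2)
  simulate_neurons(stims, truth, M = M)
}

test_that("split_dataset produces the rounded 70-10-20 partition deterministically", {
  ds <- make_tiny_dataset(10)
  sp <- split_dataset(ds, c(0.7, 0.1, 0.2), seed = 4)
  tab <- table(sp$split)
  expect_equal(as.integer(tab[c("train", "valid", "test")]), c(7L, 1L, 2L))
  # union of subsets = all clips, pairwise disjoint (split is a labelled
  # partition by construction; check every clip got exactly one label)
  expect_setequal(names(sp$split), names(ds$stimuli))
  expect_true(all(sp$split %in% c("train", "valid", "test")))
  # same seed -> identical labels; different seed -> (here) different
  expect_identical(split_dataset(ds, seed = 4)$split, sp$split)
  expect_false(identical(split_dataset(ds, seed = 5)$split, sp$split))
  # every subset non-empty even when rounding would empty one
  sp3 <- split_dataset(make_tiny_dataset(4), c(0.9, 0.05, 0.05), seed = 1)
  expect_true(all(c("train", "valid", "test") %in% sp3$split))
  expect_error(split_dataset(make_tiny_dataset(n_clips = 3)[c()],
                             seed = 1))
  expect_error(split_dataset(ds, c(0.5, 0.5, 0.2)),
               class = "audenc_argument_error")
})

test_that("the text container round-trips a dataset bit-exactly", {
  ds <- split_dataset(make_tiny_dataset(5), seed = 2)
  path <- file.path(tempdir(), "audenc-ds-roundtrip")
  on.exit(unlink(path, recursive = TRUE))
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_identical(names(back$stimuli), names(ds$stimuli))
  for (cid in names(ds$stimuli)) {
    expect_identical(audenc:::coch_values(back$stimuli[[cid]]),
                     unname(audenc:::coch_values(ds$stimuli[[cid]])))
    for (nid in ds$neurons)
      expect_identical(unname(back$responses[[cid]][[nid]]),
                       unname(ds$responses[[cid]][[nid]]))
  }
  expect_identical(back$split, ds$split)
  expect_equal(back$psth, ds$psth, ignore_attr = TRUE)
  # ground truth sidecar survives
  expect_equal(back$truth$strfs, ds$truth$strfs)
  expect_equal(back$truth$noise$sigma, ds$truth$noise$sigma)
})

test_that("the container reports missing groups as format errors", {
  ds <- split_dataset(make_tiny_dataset(5), seed = 2)
  path <- file.path(tempdir(), "audenc-ds-missing")
  on.exit(unlink(path, recursive = TRUE))
  write_dataset(ds, path)
  unlink(file.path(path, "cochleagrams"), recursive = TRUE)
  expect_error(read_dataset(path), "cochleagrams",
               class = "audenc_format_error")
  expect_error(read_dataset(tempfile()), "meta.json",
               class = "audenc_format_error")
})

test_that("a single-unit (N = 1) dataset round-trips", {
  ds <- split_dataset(make_tiny_dataset(4, n_neurons = 1), seed = 3)
  path <- file.path(tempdir(), "audenc-ds-single")
  on.exit(unlink(path, recursive = TRUE))
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_length(back$neurons, 1)
  expect_identical(unname(back$responses[[1]][[1]]),
                   unname(ds$responses[[1]][[1]]))
})

test_that("mismatched trial matrices are rejected", {
  stims <- generate_stimuli(4, 30, 2, seed = 1)
  resp <- list(list(n001 = matrix(0, 2, 30)),
               list(n001 = matrix(0, 2, 29)))
  expect_error(encoding_dataset(stims, resp, neurons = "n001"),
               class = "audenc_argument_error")
})
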