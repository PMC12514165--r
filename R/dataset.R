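#' Stimulus-response dataset for encoding-model fitting
#'
#' Pairs a set of stimulus clips (cochleagrams) with per-neuron multi-trial
#' responses. In *population* layout every neuron has responses for every
#' clip, so one model with a shared backbone and per-neuron readouts can be
#' fitted to the whole population; in single-unit layout `N = 1`.
#'
#' @param stimuli list of [cochleagram] objects.
#' @param responses list (one element per clip, same order as `stimuli`) of
#'   named lists of `M x T` trial matrices, one per neuron.
#' @param neurons character vector of neuron identifiers.
#' @param population_mode logical; `TRUE` iff all neurons were recorded for
#'   the same stimuli.
#' @param modality `"spikes"` or `"membrane_potential"`.
#' @param psth_smooth_bins odd Hanning window (bins) used when computing
#'   PSTHs from the trial matrices.
#' @return object of class `encoding_dataset` with elements `stimuli`,
#'   `responses`, `psth` (per clip, `N x T`), `neurons`,
#'   `population_mode`, `modality`, `split` (`NULL` until
#'   [split_dataset()] is applied).
#' @export
encoding_dataset <- function(stimuli, responses, neurons = NULL,
                             population_mode = TRUE,
                             modality = c("spikes", "membrane_potential"),
                             psth_smooth_bins = 1L) {
  modality <- match.arg(modality)
  if (!length(stimuli)) stop_arg("stimuli must be a non-empty list")
  if (length(responses) != length(stimuli))
    stop_arg("responses must have one element per clip")
  ids <- vapply(stimuli, function(x) attr(x, "clip_id"), "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  names(stimuli) <- ids
  names(responses) <- ids
  if (is.null(neurons)) neurons <- names(responses[[1]])
  if (is.null(neurons)) stop_arg("neuron identifiers are required")
  for (cid in ids) {
    rl <- responses[[cid]]
    if (population_mode && !all(neurons %in% names(rl)))
      stop_arg("population_mode requires responses for all neurons in clip '%s'",
               cid)
    for (nid in names(rl)) {
      m <- as.matrix(rl[[nid]])
      if (ncol(m) != ncol(stimuli[[cid]]))
        stop_arg("trial matrix for neuron '%s', clip '%s' has %d bins; stimulus has %d",
                 nid, cid, ncol(m), ncol(stimuli[[cid]]))
      responses[[cid]][[nid]] <- m
    }
  }
  psth <- lapply(ids, function(cid) {
    present <- intersect(neurons, names(responses[[cid]]))
    p <- t(vapply(present,
                  function(nid) compute_psth(responses[[cid]][[nid]],
                                             psth_smooth_bins),
                  numeric(ncol(stimuli[[cid]]))))
    rownames(p) <- present
    p
  })
  names(psth) <- ids
  structure(list(stimuli = stimuli, responses = responses, psth = psth,
                 neurons = neurons, population_mode = population_mode,
                 modality = modality,
                 psth_smooth_bins = as.integer(psth_smooth_bins),
                 split = NULL),
            class = "encoding_dataset")
}

#' @export
print.encoding_dataset <- function(x, ...) {
  Ts <- vapply(x$stimuli, ncol, 1L)
  Ms <- vapply(x$responses[[1]], nrow, 1L)
  cat(sprintf(
    "<encoding_dataset: %d clips (%d-%d bins), %d neurons, %s trials, %s layout>\n",
    length(x$stimuli), min(Ts), max(Ts), length(x$neurons),
    paste(unique(range(Ms)), collapse = "-"),
    if (x$population_mode) "population" else "single-unit"))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d valid / %d test\n",
                sum(x$split == "train"), sum(x$split == "valid"),
                sum(x$split == "test")))
  invisible(x)
}

n_clips <- function(dataset) length(dataset$stimuli)

clip_ids <- function(dataset, split = NULL) {
  ids <- names(dataset$stimuli)
  if (is.null(split)) return(ids)
  if (is.null(dataset$split)) stop_arg("dataset has no split labels")
  ids[dataset$split[ids] == split]
}

#' Assign train/validation/test splits at the clip level
#'
#' Clips (never bins within a clip) are partitioned into train, validation
#' and test subsets, which avoids temporal leakage between subsets. Counts
#' are the rounded ratios, adjusted so every subset is non-empty and the
#' counts sum to the number of clips; assignment is a seeded permutation,
#' so identical inputs give identical partitions.
#'
#' @param dataset an [encoding_dataset].
#' @param ratios length-3 positive numeric summing to 1 (train, valid,
#'   test); default `c(0.7, 0.1, 0.2)`.
#' @param seed integer seed.
#' @return the dataset with `$split` set (named character vector over
#'   clips).
#' @export
split_dataset <- function(dataset, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop_arg("ratios must be 3 positive numbers summing to 1")
  n <- n_clips(dataset)
  if (n < 3) stop_arg("need at least 3 clips to form 3 subsets")
  counts <- round(ratios * n)
  # repair rounding: make counts sum to n with every subset non-empty
  counts[counts < 1] <- 1
  while (sum(counts) > n) {
    i <- which.max(counts); counts[i] <- counts[i] - 1
  }
  while (sum(counts) < n) {
    i <- which.max(ratios * n - counts); counts[i] <- counts[i] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  lab <- rep(c("train", "valid", "test"), counts)
  split <- character(n)
  split[perm] <- lab
  names(split) <- names(dataset$stimuli)
  dataset$split <- split
  dataset
}

#' Write / read an encoding dataset as a plain-text container
#'
#' The container is a directory holding `meta.json` (identifiers, layout,
#' split labels, frequency axes, bin durations, version) and
#' tab-separated value matrices: `cochleagrams/<clip_id>.tsv` for the
#' stimuli and `responses/<neuron_id>/<clip_id>.tsv` for the `M x T` trial
#' matrices. Doubles are written at full round-trip precision, so
#' write-then-read restores values bit-exactly. If the dataset carries a
#' synthetic ground truth it is stored in `truth.json`.
#'
#' @param dataset an [encoding_dataset].
#' @param path directory to create (for writing) or read from.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the reconstructed [encoding_dataset].
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "cochleagrams"), showWarnings = FALSE)
  dir.create(file.path(path, "responses"), showWarnings = FALSE)
  meta <- list(
    version = "1",
    neurons = dataset$neurons,
    population_mode = dataset$population_mode,
    modality = dataset$modality,
    psth_smooth_bins = dataset$psth_smooth_bins,
    clips = lapply(names(dataset$stimuli), function(cid) {
      x <- dataset$stimuli[[cid]]
      list(clip_id = cid, dt = attr(x, "dt"),
           freqs = attr(x, "freqs"))
    }),
    split = as.list(dataset$split)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cid in names(dataset$stimuli))
    write_matrix_tsv(coch_values(dataset$stimuli[[cid]]),
                     file.path(path, "cochleagrams",
                               paste0(cid, ".tsv")))
  for (cid in names(dataset$responses)) {
    for (nid in names(dataset$responses[[cid]])) {
      d <- file.path(path, "responses", nid)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      write_matrix_tsv(dataset$responses[[cid]][[nid]],
                       file.path(d, paste0(cid, ".tsv")))
    }
  }
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    jsonlite::write_json(
      list(strfs = lapply(tr$strfs, function(m)
             list(nrow = nrow(m), values = as.numeric(m))),
           output_params = as.numeric(tr$output_params),
           adaptation = tr$adaptation, noise = tr$noise, seed = tr$seed),
      file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop_format("missing required file 'meta.json'")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  cdir <- file.path(path, "cochleagrams")
  if (!dir.exists(cdir))
    stop_format("missing required group 'cochleagrams'")
  rdir <- file.path(path, "responses")
  if (!dir.exists(rdir))
    stop_format("missing required group 'responses'")
  stimuli <- lapply(meta$clips, function(cl) {
    f <- file.path(cdir, paste0(cl$clip_id, ".tsv"))
    if (!file.exists(f))
      stop_format("missing cochleagram matrix for clip '%s'", cl$clip_id)
    cochleagram(read_matrix_tsv(f), freqs = cl$freqs, dt = cl$dt,
                clip_id = cl$clip_id)
  })
  ids <- vapply(meta$clips, `[[`, "", "clip_id")
  neurons <- as.character(meta$neurons)
  responses <- lapply(ids, function(cid) {
    out <- list()
    for (nid in neurons) {
      f <- file.path(rdir, nid, paste0(cid, ".tsv"))
      if (file.exists(f)) out[[nid]] <- read_matrix_tsv(f)
    }
    out
  })
  ds <- encoding_dataset(stimuli, responses, neurons = neurons,
                         population_mode = isTRUE(meta$population_mode),
                         modality = meta$modality,
                         psth_smooth_bins = meta$psth_smooth_bins)
  if (length(meta$split)) {
    split <- unlist(meta$split)
    ds$split <- split[names(ds$stimuli)]
  }
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    strfs <- lapply(tj$strfs, function(s)
      matrix(as.numeric(s$values), nrow = s$nrow))
    ds$truth <- synthetic_truth(
      strfs,
      output_params = matrix(as.numeric(tj$output_params), ncol = 4),
      adaptation = tj$adaptation, noise = tj$noise, seed = tj$seed)
  }
  ds
}

# %.17g guarantees binary64 round-trip through text; fread parses full
# precision on the way back
write_matrix_tsv <- function(m, file) {
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, file)
}

read_matrix_tsv <- function(file) {
  m <- as.matrix(data.table::fread(file, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}

# temporally concatenate the clips of a split: returns list(psth N x T,
# trials per neuron M x T, pred function input list of stimuli)
concat_split <- function(dataset, split) {
  ids <- clip_ids(dataset, split)
  if (!length(ids)) stop_arg("split '%s' is empty", split)
  neurons <- dataset$neurons
  psth <- do.call(cbind, lapply(ids, function(cid)
    dataset$psth[[cid]][neurons, , drop = FALSE]))
  trials <- lapply(neurons, function(nid) {
    mats <- lapply(ids, function(cid) dataset$responses[[cid]][[nid]])
    mmin <- min(vapply(mats, nrow, 1L))
    do.call(cbind, lapply(mats, function(m) m[seq_len(mmin), , drop = FALSE]))
  })
  names(trials) <- neurons
  list(ids = ids, psth = psth, trials = trials)
}
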