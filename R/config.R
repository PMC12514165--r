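# Experiment configuration and runnable entry points tying the modules
# into reproducible simulate / fit / dream / similarity pipelines. These
# functions are the package's command surface; inst/cli/audenc-cli.R is a
# thin Rscript wrapper around them.

#' Experiment configuration
#'
#' A serialisable recipe for a full experiment: where the data come from
#' (a dataset container path or a synthetic recipe), which model to fit,
#' how to train it, and interpretation settings. A saved configuration
#' re-runs to identical results.
#'
#' @param dataset path to a dataset container (see [write_dataset()]), or
#'   `NULL` when `synthetic` is given.
#' @param synthetic synthetic recipe: list with `n_neurons`, `n_clips`,
#'   `F`, `T`, `M`, and optional `adaptation`, `noise`, `strf_w`,
#'   `target_ceiling`.
#' @param model list of [model_spec()] arguments (without
#'   `n_freqs`/`n_neurons`, filled from the data).
#' @param train list of [train_config()] arguments.
#' @param interpret list of interpretation settings (`T`, `n_iters`,
#'   `lr`).
#' @param seeds integer vector of training seeds.
#' @param out_dir output directory.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(dataset = NULL, synthetic = NULL,
                              model = list(architecture = "ln"),
                              train = list(), interpret = list(),
                              seeds = 1L, out_dir = tempfile("audenc")) {
  if (is.null(dataset) && is.null(synthetic))
    stop_arg("either a dataset path or a synthetic recipe is required")
  structure(list(dataset = dataset, synthetic = synthetic, model = model,
                 train = train, interpret = interpret,
                 seeds = as.integer(seeds), out_dir = out_dir,
                 version = "1"),
            class = "experiment_config")
}

#' Read / write experiment configurations as JSON
#' @param config an [experiment_config].
#' @param path JSON file path.
#' @return `write_experiment_config` returns `path`;
#'   `read_experiment_config` the configuration.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  do.call(experiment_config, cfg[setdiff(names(cfg), "version")])
}

# materialise the dataset named by a config (reading or simulating)
config_dataset <- function(config, seed = 1L) {
  if (!is.null(config$dataset)) return(read_dataset(config$dataset))
  rc <- modifyList(list(n_neurons = 5L, n_clips = 20L, F = 16L, T = 400L,
                        M = 10L, strf_w = 10L,
                        adaptation = list(type = "none"),
                        noise = list(type = "gaussian", sigma = NULL),
                        target_ceiling = 0.8,
                        psth_smooth_bins = 1L,
                        ratios = c(0.7, 0.1, 0.2)),
                   config$synthetic)
  stims <- generate_stimuli(rc$F, rc$T, rc$n_clips, seed = seed)
  strfs <- random_strfs(rc$n_neurons, rc$F, rc$strf_w, seed = seed + 1L)
  truth0 <- synthetic_truth(strfs, adaptation = rc$adaptation,
                            noise = list(type = "gaussian", sigma = 0),
                            seed = seed + 2L)
  noise <- rc$noise
  if (identical(noise$type, "gaussian") && is.null(noise$sigma)) {
    rates <- do.call(cbind, lapply(stims, function(x)
      noise_free_rates(coch_values(x), truth0)))
    noise$sigma <- calibrate_noise_sigma(rates, rc$M, rc$target_ceiling)
  }
  truth <- synthetic_truth(strfs, adaptation = rc$adaptation,
                           noise = noise, seed = seed + 2L)
  ds <- simulate_neurons(stims, truth, M = rc$M,
                         psth_smooth_bins = rc$psth_smooth_bins)
  split_dataset(ds, rc$ratios, seed = seed + 3L)
}

#' Simulate a synthetic dataset and write it to disk
#'
#' Builds the dataset described by the config's synthetic recipe and
#' writes it (with its ground-truth sidecar) as a plain-text container
#' under the config's output directory.
#'
#' @param config an [experiment_config] with a synthetic recipe.
#' @param seed integer seed.
#' @return the container path, invisibly; prints a one-line summary.
#' @export
run_simulate <- function(config, seed = 1L) {
  ds <- config_dataset(config, seed = seed)
  path <- file.path(config$out_dir, "dataset")
  write_dataset(ds, path)
  Ts <- vapply(ds$stimuli, ncol, 1L)
  message(sprintf(
    "simulated dataset: N=%d neurons, %d clips, M=%d trials, F=%d, T=%d-%d -> %s",
    length(ds$neurons), length(ds$stimuli),
    nrow(ds$responses[[1]][[1]]), nrow(ds$stimuli[[1]]), min(Ts), max(Ts),
    path))
  invisible(path)
}

#' Fit the configured model over all seeds
#'
#' Trains one model per seed, writes per-seed checkpoints
#' (`checkpoint_seed<k>.rds`) and a metrics table
#' (`metrics.csv`: neuron, seed, split, cc_raw, cc_norm, plus aggregate
#' rows averaging across neurons and seeds) under the output directory.
#'
#' @param config an [experiment_config].
#' @param seed base seed offsetting the configured seed list.
#' @return list of [encoder_fit] objects, invisibly.
#' @export
run_fit <- function(config, seed = 0L) {
  ds <- config_dataset(config, seed = seed + 1L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  margs <- config$model
  margs$n_freqs <- nrow(ds$stimuli[[1]])
  margs$n_neurons <- length(ds$neurons)
  tc <- do.call(train_config, config$train)
  fits <- list()
  rows <- list()
  for (s in config$seeds) {
    sp <- do.call(model_spec, margs)
    fit <- fit_encoder(ds, sp, tc, seed = s + seed)
    fits[[as.character(s)]] <- fit
    saveRDS(fit, file.path(config$out_dir,
                           sprintf("checkpoint_seed%d.rds", s)))
    m <- fit$metrics
    m$seed <- s
    rows[[as.character(s)]] <- m
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("neuron", "seed", "split", "cc_raw", "cc_norm")]
  agg <- do.call(rbind, lapply(split(tab, tab$split), function(d)
    data.frame(neuron = "all", seed = NA, split = d$split[1],
               cc_raw = mean(d$cc_raw), cc_norm = mean(d$cc_norm))))
  tab <- rbind(tab, agg)
  write.csv(tab, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  invisible(fits)
}

#' Compute and store interpretation artifacts for saved checkpoints
#'
#' `run_dream` computes, for every checkpoint in the output directory and
#' every target neuron, the GradMap, its energy trace and a Dream, and
#' writes them as TSV/JSON under `interpret/<checkpoint>/<neuron>/`.
#' `run_similarity` computes GradMaps for all checkpoints and writes the
#' cross-model similarity matrix to `similarity.csv`.
#'
#' @param config an [experiment_config].
#' @param targets integer neuron indices (default: first neuron).
#' @return `run_dream`: invisible list of dreams; `run_similarity`: the
#'   similarity matrix.
#' @export
run_dream <- function(config, targets = 1L) {
  ckpts <- list.files(config$out_dir, "^checkpoint_.*\\.rds$",
                      full.names = TRUE)
  if (!length(ckpts)) stop("no checkpoints found in ", config$out_dir)
  ic <- modifyList(list(T = 50L, n_iters = 200L, lr = 1e-2),
                   config$interpret)
  out <- list()
  for (ck in ckpts) {
    fit <- readRDS(ck)
    tag <- sub("\\.rds$", "", basename(ck))
    for (n in targets) {
      d <- file.path(config$out_dir, "interpret", tag,
                     sprintf("neuron%03d", n))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      g <- gradmap(fit, target = n, T = ic$T)
      dr <- dream(fit, target = n, T = ic$T, n_iters = ic$n_iters,
                  lr = ic$lr)
      write_matrix_tsv(as.matrix(g), file.path(d, "gradmap.tsv"))
      write_matrix_tsv(dr$stimulus, file.path(d, "dream.tsv"))
      jsonlite::write_json(
        list(model = tag, neuron = n, horizon = ic$T,
             n_iterations = dr$n_iterations, lr = ic$lr,
             energy = as.numeric(gradmap_energy(g)),
             loss_trajectory = dr$loss_trajectory),
        file.path(d, "meta.json"), auto_unbox = TRUE, digits = NA)
      out[[paste(tag, n, sep = "/")]] <- dr
    }
  }
  invisible(out)
}

#' @rdname run_dream
#' @export
run_similarity <- function(config, targets = 1L) {
  ckpts <- list.files(config$out_dir, "^checkpoint_.*\\.rds$",
                      full.names = TRUE)
  if (length(ckpts) < 2) stop("need at least two checkpoints in ",
                              config$out_dir)
  ic <- modifyList(list(T = 50L), config$interpret)
  maps <- lapply(ckpts, function(ck) {
    fit <- readRDS(ck)
    lapply(targets, function(n) as.matrix(gradmap(fit, target = n,
                                                  T = ic$T)))
  })
  names(maps) <- sub("\\.rds$", "", basename(ckpts))
  S <- similarity_matrix(maps)
  write.csv(S, file.path(config$out_dir, "similarity.csv"))
  S
}

#' Converter stubs for the public electrophysiology archives
#'
#' The reference recordings this package's benchmarks mirror live in
#' public archives (CRCNS `aa-1` and `ac-1`, a Zenodo record and an OSF
#' repository) whose download requires registration and whose layouts are
#' MATLAB/HDF5 files. This stub documents the expected conversion --
#' cochleagrams to [cochleagram()] objects, spike or membrane-potential
#' trials to per-neuron `M x T` matrices, then [encoding_dataset()] and
#' [write_dataset()] -- but performs none of it; it always errors. It is
#' provided so pipelines can name their intended source explicitly.
#'
#' @param source one of `"crcns-aa1"`, `"crcns-ac1"`, `"zenodo"`, `"osf"`.
#' @param path local path to the downloaded archive.
#' @export
convert_public_dataset <- function(source = c("crcns-aa1", "crcns-ac1",
                                              "zenodo", "osf"), path) {
  source <- match.arg(source)
  stop("converter for '", source, "' is documented but not implemented; ",
       "see ?convert_public_dataset for the target layout")
}
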