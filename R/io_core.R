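#' Trial-aligned binned spike counts
#'
#' Container for a session's spike counts binned on a common within-trial
#' clock. Counts are stored as a 3-d integer array indexed
#' `(trial, time_bin, neuron)`; time starts at 0 at the trial alignment event
#' and bins are half-open `[t, t + bin_size)`.
#'
#' @param counts non-negative integer array, `trial x time_bin x neuron`.
#' @param bin_size bin width in seconds.
#' @param trial_duration trial length in seconds; must equal
#'   `n_bins * bin_size` to within one part in 1e6.
#' @return An object of class `binned_spikes`.
#' @export
binned_spikes <- function(counts, bin_size, trial_duration) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (trial x time_bin x neuron)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must contain non-negative integers")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("`bin_size` must be a positive scalar (seconds)")
  n_bins <- dim(counts)[2L]
  if (abs(n_bins * bin_size - trial_duration) > 1e-6 * trial_duration)
    stop("`trial_duration` must equal n_bins * bin_size")
  structure(
    list(counts = counts, bin_size = bin_size, trial_duration = trial_duration),
    class = "binned_spikes"
  )
}

#' @export
print.binned_spikes <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<binned_spikes> %d trials x %d bins (%.0f ms) x %d neurons, %d spikes\n",
    d[1L], d[2L], 1000 * x$bin_size, d[3L], sum(x$counts)))
  invisible(x)
}

#' Per-neuron brain-region labels
#'
#' Assigns each neuron to exactly one named brain region and precomputes the
#' sorted neuron index list per region (1-based indices).
#'
#' @param labels character vector, one region label per neuron.
#' @return An object of class `region_assignment` with elements `labels`
#'   (as given) and `index` (named list of sorted neuron indices per region).
#' @export
region_assignment <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyNA(labels) || any(!nzchar(labels)))
    stop("every neuron needs a non-empty region label")
  index <- lapply(split(seq_along(labels), labels), sort)
  structure(list(labels = labels, index = index), class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat("<region_assignment>",
      paste(sprintf("%s:%d", names(x$index), lengths(x$index)), collapse = " "),
      "\n")
  invisible(x)
}

#' Read a region assignment from a two-column CSV
#'
#' Expects columns `neuron_index` (1-based) and `region_label`; rows may be in
#' any order but must cover every index `1..N` exactly once.
#'
#' @param path CSV file path.
#' @return A [region_assignment()].
#' @export
read_region_csv <- function(path) {
  tab <- data.table::fread(path, colClasses = list(character = "region_label"))
  if (!all(c("neuron_index", "region_label") %in% names(tab)))
    stop("region CSV needs columns `neuron_index`, `region_label`")
  n <- nrow(tab)
  if (!setequal(tab$neuron_index, seq_len(n)))
    stop("`neuron_index` must cover 1..N exactly once")
  region_assignment(tab$region_label[order(tab$neuron_index)])
}

#' Per-trial behavior covariates
#'
#' @param choice binary (0/1) label per trial.
#' @param motion_energy numeric matrix `trial x time_bin`, e.g. whisker motion
#'   energy extracted from video, on the same time base as the spike counts.
#' @return An object of class `behavior_table`.
#' @export
behavior_table <- function(choice, motion_energy) {
  choice <- as.integer(choice)
  if (anyNA(choice) || !all(choice %in% c(0L, 1L)))
    stop("`choice` must be binary (0/1), one per trial")
  motion_energy <- as.matrix(motion_energy)
  if (nrow(motion_energy) != length(choice))
    stop("`motion_energy` must have one row per trial")
  structure(list(choice = choice, motion_energy = motion_energy),
            class = "behavior_table")
}

#' One recording session: spikes, regions, behavior
#'
#' The universal unit of input for training and evaluation. Consistency across
#' components (neuron and trial counts) is validated on construction.
#'
#' @param session_id character scalar identifying the session.
#' @param spikes a [binned_spikes()].
#' @param regions a [region_assignment()] with one label per neuron.
#' @param behavior a [behavior_table()] with one row per trial.
#' @param truth optional list of simulator ground truth (latents, rates);
#'   carried for oracle evaluation, never required and not serialized.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, spikes, regions, behavior, truth = NULL) {
  stopifnot(inherits(spikes, "binned_spikes"),
            inherits(regions, "region_assignment"),
            inherits(behavior, "behavior_table"))
  d <- dim(spikes$counts)
  if (length(regions$labels) != d[3L])
    stop("neuron count mismatch between spikes and regions")
  if (length(behavior$choice) != d[1L])
    stop("trial count mismatch between spikes and behavior")
  if (ncol(behavior$motion_energy) != d[2L])
    stop("motion_energy time axis must match spike time bins")
  structure(list(session_id = as.character(session_id), spikes = spikes,
                 regions = regions, behavior = behavior, truth = truth),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  d <- dim(x$spikes$counts)
  cat(sprintf("<session_bundle> '%s': %d trials x %d bins x %d neurons; regions: %s\n",
              x$session_id, d[1L], d[2L], d[3L],
              paste(names(x$regions$index), collapse = ", ")))
  invisible(x)
}

#' Bin spike times into trial-aligned counts
#'
#' Bins are half-open: a spike at exactly `trial_start + t * bin_size` falls in
#' bin `t + 1` (1-based). Spikes outside every trial window are silently
#' dropped.
#'
#' @param spike_times list with one numeric vector of spike times (seconds)
#'   per neuron, on the same clock as `trial_starts`.
#' @param trial_starts numeric vector of trial start times (seconds).
#' @param bin_size bin width in seconds (default 0.020).
#' @param trial_duration trial length in seconds (default 2.0); must be an
#'   integer multiple of `bin_size` to within one part in 1e6.
#' @return A [binned_spikes()] of dimension
#'   `length(trial_starts) x trial_duration/bin_size x length(spike_times)`.
#' @export
bin_spike_times <- function(spike_times, trial_starts, bin_size = 0.020,
                            trial_duration = 2.0) {
  if (bin_size <= 0) stop("`bin_size` must be positive")
  n_bins_real <- trial_duration / bin_size
  n_bins <- round(n_bins_real)
  if (abs(n_bins_real - n_bins) > 1e-6 || n_bins < 1L)
    stop("`trial_duration` must be an integer multiple of `bin_size`")
  n_trials <- length(trial_starts)
  n_neurons <- length(spike_times)
  counts <- array(0L, dim = c(n_trials, n_bins, n_neurons))
  for (n in seq_len(n_neurons)) {
    st <- spike_times[[n]]
    for (r in seq_len(n_trials)) {
      rel <- st - trial_starts[r]
      rel <- rel[rel >= 0 & rel < trial_duration]
      if (length(rel)) {
        b <- floor(rel / bin_size) + 1L
        b[b > n_bins] <- n_bins  # guard against floating-point edge at duration
        tab <- tabulate(b, nbins = n_bins)
        counts[r, , n] <- counts[r, , n] + tab
      }
    }
  }
  binned_spikes(counts, bin_size, trial_duration)
}

# container layout: one directory per session with JSON metadata and CSV
# arrays; group names mirror a hierarchical container so format errors can
# name the missing group.
.session_files <- c(meta = "session.json", counts = "spikes_counts.csv",
                    regions = "regions_labels.csv", choice = "behavior_choice.csv",
                    motion = "behavior_motion_energy.csv")

#' Write a session bundle to a directory container
#'
#' Layout: `session.json` (session_id, bin_size_s, trial_duration_s, dims),
#' `spikes_counts.csv` (flattened trial-major counts), `regions_labels.csv`
#' (`neuron_index`, `region_label`), `behavior_choice.csv`,
#' `behavior_motion_energy.csv`. All numeric metadata is stored at full
#' precision; the round trip [load_session()] is lossless.
#'
#' @param bundle a [session_bundle()]. The optional `truth` element is not
#'   serialized.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(bundle$spikes$counts)
  meta <- list(session_id = bundle$session_id,
               bin_size_s = bundle$spikes$bin_size,
               trial_duration_s = bundle$spikes$trial_duration,
               n_trials = d[1L], n_bins = d[2L], n_neurons = d[3L])
  jsonlite::write_json(meta, file.path(path, .session_files["meta"]),
                       auto_unbox = TRUE, digits = NA)
  # counts flattened to (trial*bin) x neuron, trial-major rows
  cmat <- matrix(aperm(bundle$spikes$counts, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])
  data.table::fwrite(data.table::as.data.table(cmat),
                     file.path(path, .session_files["counts"]))
  data.table::fwrite(data.table::data.table(
    neuron_index = seq_len(d[3L]), region_label = bundle$regions$labels),
    file.path(path, .session_files["regions"]))
  data.table::fwrite(data.table::data.table(choice = bundle$behavior$choice),
                     file.path(path, .session_files["choice"]))
  data.table::fwrite(data.table::as.data.table(bundle$behavior$motion_energy),
                     file.path(path, .session_files["motion"]))
  invisible(path)
}

#' Read a session bundle written by [save_session()]
#'
#' @param path container directory.
#' @return A [session_bundle()]; identical field-for-field to what was saved.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no session container at '%s'", path))
  need <- file.path(path, .session_files)
  missing <- !file.exists(need)
  if (any(missing))
    stop(sprintf("malformed session container: missing group(s) %s",
                 paste(sQuote(names(.session_files)[missing]), collapse = ", ")))
  meta <- jsonlite::read_json(file.path(path, .session_files["meta"]),
                              simplifyVector = TRUE)
  cmat <- as.matrix(data.table::fread(file.path(path, .session_files["counts"])))
  counts <- aperm(array(as.integer(cmat),
                        dim = c(meta$n_bins, meta$n_trials, meta$n_neurons)),
                  c(2L, 1L, 3L))
  reg <- read_region_csv(file.path(path, .session_files["regions"]))
  choice <- data.table::fread(file.path(path, .session_files["choice"]))$choice
  me <- as.matrix(data.table::fread(file.path(path, .session_files["motion"])))
  dimnames(me) <- NULL
  session_bundle(meta$session_id,
                 binned_spikes(counts, meta$bin_size_s, meta$trial_duration_s),
                 reg, behavior_table(choice, me))
}

#' Deterministic train/validation/test split of trials
#'
#' Sizes are `floor(fraction * n)` per part with all remainder trials assigned
#' to the training part; the permutation is drawn from `seed` alone, so the
#' split is fully reproducible.
#'
#' @param n_trials number of trials.
#' @param fractions length-3 numeric `(train, val, test)`, positive, summing
#'   to 1 within 1e-6.
#' @param seed integer seed.
#' @return An object of class `trial_split`: list with integer vectors
#'   `train`, `val`, `test` (a disjoint partition of `1:n_trials`) and `seed`.
#' @export
split_trials <- function(n_trials, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("`fractions` must be three positive numbers")
  if (abs(sum(fractions) - 1) > 1e-6) stop("`fractions` must sum to 1")
  n_val <- floor(fractions[2L] * n_trials)
  n_test <- floor(fractions[3L] * n_trials)
  n_train <- n_trials - n_val - n_test
  if (n_val < 1L || n_test < 1L || n_train < 1L)
    stop("`n_trials` too small to populate all three parts")
  perm <- withr::with_seed(seed, sample.int(n_trials))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[n_train + n_val + seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "trial_split")
}

#' Most active neurons by total spike count
#'
#' @param spikes a [binned_spikes()].
#' @param k number of neurons to return; must not exceed the neuron count.
#' @param trials optional trial indices to restrict the tally to (e.g. the
#'   training split); defaults to all trials.
#' @return Integer vector of `k` neuron indices ordered by decreasing total
#'   count, ties broken by lower index.
#' @export
most_active_neurons <- function(spikes, k, trials = NULL) {
  stopifnot(inherits(spikes, "binned_spikes"))
  n_neurons <- dim(spikes$counts)[3L]
  if (k > n_neurons) stop("`k` exceeds the number of neurons")
  cc <- spikes$counts
  if (!is.null(trials)) cc <- cc[trials, , , drop = FALSE]
  totals <- apply(cc, 3L, sum)
  order(-totals, seq_len(n_neurons))[seq_len(k)]
}
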