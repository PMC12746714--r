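#' Sensorimotor sequence container
#'
#' A single demonstration or recall trial: a `T x C` matrix of observations
#' (rows are time steps, columns are channels) together with the role of each
#' channel, the sampling interval and optional skill/trial labels.
#'
#' Channel roles follow the conventions of associative skill memories:
#' `"joint"` (joint angles, degrees), `"ee"` (end-effector coordinates,
#' metres), `"gripper"` (aperture and finger forces), `"ft"` (force/torque
#' sensor components) and `"cue"` (one-hot context channels).
#'
#' @param values numeric matrix, time steps by channels.
#' @param channels character vector of channel names (defaults to existing
#'   column names).
#' @param roles character vector of channel roles, one per channel.
#' @param dt sampling interval in seconds (default 0.5 s, i.e. 2 Hz).
#' @param skill optional skill label.
#' @param trial_id optional trial identifier.
#' @return An object of class `sm_seq`: the value matrix with channel
#'   metadata attached.
#' @export
sm_sequence <- function(values, channels = colnames(values), roles,
                        dt = 0.5, skill = NA_character_, trial_id = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(channels)) {
    abort("`channels` must be supplied when `values` has no column names.")
  }
  if (length(channels) != ncol(values)) {
    abort("`channels` must name every column of `values`.")
  }
  if (length(roles) != ncol(values)) {
    abort("`roles` must give exactly one role per channel.")
  }
  if (!all(is.finite(values))) {
    abort("sequence values must be finite.")
  }
  known <- c("joint", "ee", "gripper", "ft", "cue")
  if (!all(roles %in% known)) {
    abort(paste0("unknown channel role(s): ",
                 paste(setdiff(unique(roles), known), collapse = ", ")))
  }
  colnames(values) <- channels
  structure(values,
            roles = as.character(roles),
            dt = dt,
            skill = skill,
            trial_id = trial_id,
            class = c("sm_seq", "matrix", "array"))
}

#' @export
print.sm_seq <- function(x, ...) {
  cat(sprintf("<sm_seq> %d steps x %d channels (dt = %gs%s)\n",
              nrow(x), ncol(x), attr(x, "dt"),
              if (!is.na(attr(x, "skill"))) paste0(", skill ", attr(x, "skill")) else ""))
  tab <- table(attr(x, "roles"))
  cat("  roles:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Channel metadata of a sequence
#'
#' @param x an [sm_sequence()].
#' @return A tibble with columns `channel` and `role`.
#' @export
channel_info <- function(x) {
  stopifnot(inherits(x, "sm_seq"))
  tibble::tibble(channel = colnames(x), role = attr(x, "roles"))
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.sm_seq <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[, , drop = FALSE])
  dplyr::bind_cols(
    tibble::tibble(step = seq_len(nrow(x)) - 1L,
                   time_s = (seq_len(nrow(x)) - 1L) * attr(x, "dt")),
    out
  )
}

role_columns <- function(x, role) which(attr(x, "roles") %in% role)

# rebuild an sm_seq with new values but the same metadata
with_values <- function(x, values) {
  sm_sequence(values, channels = colnames(x), roles = attr(x, "roles"),
              dt = attr(x, "dt"), skill = attr(x, "skill"),
              trial_id = attr(x, "trial_id"))
}

#' Write / read a sequence as CSV
#'
#' One row per time step; the header encodes channel names and roles as
#' `name:role` so the file round-trips without a sidecar.
#'
#' @param x an [sm_sequence()].
#' @param path file path.
#' @return `write_sequence_csv()` returns `path` invisibly;
#'   `read_sequence_csv()` returns an [sm_sequence()].
#' @export
write_sequence_csv <- function(x, path) {
  stopifnot(inherits(x, "sm_seq"))
  df <- as.data.frame(unclass(x))
  names(df) <- paste(colnames(x), attr(x, "roles"), sep = ":")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @param dt,skill,trial_id metadata not stored in the CSV body.
#' @export
read_sequence_csv <- function(path, dt = 0.5, skill = NA_character_,
                              trial_id = NA_integer_) {
  df <- read.csv(path, check.names = FALSE)
  parts <- strsplit(names(df), ":", fixed = TRUE)
  channels <- vapply(parts, `[`, character(1), 1L)
  roles <- vapply(parts, `[`, character(1), 2L)
  sm_sequence(as.matrix(df), channels = channels, roles = roles,
              dt = dt, skill = skill, trial_id = trial_id)
}

#' Z-score channel normalisation over a set of trials
#'
#' Pools all trials and, for each channel, subtracts the pooled mean and
#' divides by the pooled standard deviation (floored at `sd_floor`, so
#' constant channels map to zero). Sequences are normalised this way before
#' being presented to any of the networks, and recalled outputs are mapped
#' back to original units with [zscore_denormalise()].
#'
#' @param trials list of [sm_sequence()] objects with identical channel layout.
#' @param sd_floor lower bound on the per-channel standard deviation.
#' @return A list with elements `trials` (normalised sequences) and `scaling`
#'   (tibble with `channel`, `mean`, `sd`).
#' @export
zscore_normalise <- function(trials, sd_floor = 1e-6) {
  if (length(trials) < 2) {
    abort("need at least 2 trials to estimate channel statistics.")
  }
  pooled <- do.call(rbind, lapply(trials, unclass))
  mu <- colMeans(pooled)
  sg <- pmax(apply(pooled, 2, sd), sd_floor)
  scaling <- tibble::tibble(channel = colnames(trials[[1]]), mean = unname(mu),
                            sd = unname(sg))
  out <- lapply(trials, function(tr) {
    with_values(tr, sweep(sweep(unclass(tr), 2, mu, "-"), 2, sg, "/"))
  })
  list(trials = out, scaling = scaling)
}

#' @rdname zscore_normalise
#' @param x an [sm_sequence()] or plain matrix in normalised units.
#' @param scaling the `scaling` tibble returned by [zscore_normalise()].
#' @export
zscore_denormalise <- function(x, scaling) {
  vals <- if (inherits(x, "sm_seq")) unclass(x) else as.matrix(x)
  vals <- sweep(sweep(vals, 2, scaling$sd, "*"), 2, scaling$mean, "+")
  if (inherits(x, "sm_seq")) with_values(x, vals) else vals
}

#' @rdname zscore_normalise
#' @export
zscore_apply <- function(x, scaling) {
  vals <- if (inherits(x, "sm_seq")) unclass(x) else as.matrix(x)
  vals <- sweep(sweep(vals, 2, scaling$mean, "-"), 2, scaling$sd, "/")
  if (inherits(x, "sm_seq")) with_values(x, vals) else vals
}
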