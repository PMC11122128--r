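#' Build feature tables from a synthetic study
#'
#' Generates `n_sequences` labelled synthetic eye sequences (streaming:
#' frames are discarded after signal extraction) and assembles the five
#' feature datasets used in the model comparison: SVD-based statistical and
#' spectral features, EAR-based statistical and spectral features, and the
#' three gaze metrics computed from the ground-truth iris track.
#'
#' @inheritParams generate_dataset
#' @param grid,band,window,max_rank SVD-signal settings, see
#'   [extract_svd_signal()].
#' @return named list of datasets (`svd_stats`, `svd_spectral`, `ear_stats`,
#'   `ear_spectral`, `gaze`), each a list with `features` (data.frame) and
#'   `label` (0/1 vector).
#' @export
simulate_feature_data <- function(n_sequences, focus_fraction = 5 / 6,
                                  params = eye_scene_params(),
                                  focus_regime = eyesvd::focus_regime(),
                                  nonfocus_regimes = list(nonfocus_fixation_regime()),
                                  seed = 1L, grid = block_grid(),
                                  band = c(0.5, 15), window = 5,
                                  max_rank = 10) {
  if (n_sequences < 2) stop("n_sequences must be at least 2")
  n_focus <- min(max(round(n_sequences * focus_fraction), 1), n_sequences - 1)
  labels <- c(rep(1L, n_focus), rep(0L, n_sequences - n_focus))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_sequences))
  svd_stats <- svd_spec <- ear_stats <- ear_spec <- gaze <- list()
  j <- 0
  for (i in seq_len(n_sequences)) {
    p <- params
    p$seed <- seeds[i]
    reg <- if (labels[i] == 1L) focus_regime else {
      j <- j + 1
      nonfocus_regimes[[(j - 1) %% length(nonfocus_regimes) + 1]]
    }
    sq <- generate_sequence(reg, p, render_frames = TRUE)
    svd_sig <- extract_svd_signal(sq$frames, fps = p$fps, grid = grid,
                                  band = band, window = window,
                                  max_rank = max_rank)
    ear_sig <- extract_ear_signal(sq$landmarks, fps = p$fps)
    svd_stats[[i]] <- statistical_features(svd_sig)
    svd_spec[[i]] <- spectral_features(svd_sig)
    ear_stats[[i]] <- statistical_features(ear_sig)
    ear_spec[[i]] <- spectral_features(ear_sig)
    gaze[[i]] <- gaze_summary(sq$log$iris_x_series)
    sq <- NULL
  }
  as_table <- function(rows) {
    list(features = as.data.frame(do.call(rbind, rows)), label = labels)
  }
  list(svd_stats = as_table(svd_stats),
       svd_spectral = as_table(svd_spec),
       ear_stats = as_table(ear_stats),
       ear_spectral = as_table(ear_spec),
       gaze = list(features = do.call(rbind, gaze), label = labels))
}

#' Write / read a temporal signal as CSV
#'
#' Two-column CSV (`frame_index`, `value`) preceded by `#`-prefixed header
#' metadata lines recording fps, source and (for SVD signals) the selected
#' rank.
#'
#' @param signal a [temporal_signal()].
#' @param path file path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a [temporal_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "temporal_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%g", signal$fps),
               sprintf("# source=%s", signal$source),
               sprintf("# selected_rank=%s", signal$selected_rank)), con)
  write.csv(data.frame(frame_index = seq_along(signal$values),
                       value = signal$values),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) sub(sprintf("^# %s=", key), "", grep(key, hdr, value = TRUE))
  df <- read.csv(path, comment.char = "#")
  rank <- suppressWarnings(as.integer(get("selected_rank")))
  temporal_signal(df$value, fps = as.numeric(get("fps")),
                  source = get("source"), selected_rank = rank)
}

#' Write a feature table as CSV
#'
#' One row per sequence: `sequence_id`, `source`, the feature columns, and
#' the binary `label`.
#'
#' @param table list with `features` and `label` (as produced by
#'   [simulate_feature_data()]).
#' @param source provenance tag for the extraction method.
#' @param path file path.
#' @export
write_feature_csv <- function(table, source, path) {
  df <- data.frame(sequence_id = seq_len(nrow(table$features)),
                   source = source, table$features, label = table$label,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an iris track from CSV
#'
#' Expects columns `frame_index` and `x` (a `y` column is permitted and
#' ignored: the gaze metrics are horizontal-only).
#'
#' @param path file path.
#' @return numeric vector of per-frame x coordinates ordered by frame.
#' @export
read_iris_track <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("frame_index", "x") %in% names(df)))
  df$x[order(df$frame_index)]
}
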