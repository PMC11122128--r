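#' Probed recording session
#'
#' A full recording session labelled by periodic attention probes: a probe
#' every `probe_period` seconds asks for a self-reported state
#' (`"Focus"`, `"nonFocus"`, or `"Skip"`), labelling the window that
#' precedes it. Only the last `keep_window` seconds of each probe period are
#' retained for analysis, to avoid the distraction transient of the probe
#' sound itself.
#'
#' @param n_frames total frames in the session.
#' @param labels character vector of per-probe labels; its length must equal
#'   the number of complete probe periods in the session.
#' @param fps frame rate (default 30).
#' @param probe_period probe interval in seconds (default 40).
#' @param keep_window retained window length in seconds (default 20;
#'   must not exceed `probe_period`).
#' @return object of class `probed_session`.
#' @export
probed_session <- function(n_frames, labels, fps = 30, probe_period = 40,
                           keep_window = 20) {
  stopifnot(n_frames >= 0, fps > 0, probe_period > 0,
            keep_window > 0, keep_window <= probe_period)
  labels <- as.character(labels)
  if (!all(labels %in% c("Focus", "nonFocus", "Skip")))
    stop("labels must be Focus, nonFocus or Skip")
  n_probes <- floor(n_frames / (fps * probe_period))
  if (length(labels) != n_probes)
    stop(sprintf("labels misaligned: session has %d complete probe period(s), got %d label(s)",
                 n_probes, length(labels)))
  structure(list(n_frames = n_frames, labels = labels, fps = fps,
                 probe_period = probe_period, keep_window = keep_window),
            class = "probed_session")
}

#' Segment a probed session into labelled analysis windows
#'
#' For probe i (ending at `i * probe_period` seconds) the retained window
#' covers the final `keep_window` seconds of the period, i.e.
#' `fps * keep_window` frames. Windows labelled `"Skip"` are dropped; the
#' rest carry the binary label Focus = 1, nonFocus = 0, and a deterministic
#' id `probe###`.
#'
#' @param session a [probed_session()].
#' @return list of windows, each a list with `probe_index`, `id`, `frames`
#'   (integer frame indices, 1-based), `label` (0/1).
#' @export
segment_session <- function(session) {
  stopifnot(inherits(session, "probed_session"))
  ppf <- session$fps * session$probe_period
  kwf <- session$fps * session$keep_window
  out <- list()
  for (i in seq_along(session$labels)) {
    if (session$labels[i] == "Skip") next
    end <- i * ppf
    out[[length(out) + 1]] <- list(
      probe_index = i,
      id = sprintf("probe%03d", i),
      frames = as.integer((end - kwf + 1):end),
      label = as.integer(session$labels[i] == "Focus"))
  }
  out
}
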