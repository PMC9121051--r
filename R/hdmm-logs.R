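#' Treatment session
#'
#' A parsed motion-monitoring session: one or more segments, each opened by
#' an image-guidance baseline (or re-baseline) event carrying the residual
#' setup error left after the CBCT correction, followed by the marker
#' records tracked against that baseline.
#'
#' @param id session identifier.
#' @param gating the session's \code{gating_config} (taken from the log
#'   header, since the clinical threshold may differ between sessions).
#' @param segments list of \code{list(residual = <3-vector mm>,
#'   trace = <marker-sample data.frame>)}; each trace has columns
#'   \code{t_s, x_mm, y_mm, z_mm, radial_mm, state}.
#' @return object of class \code{treatment_session}.
#' @export
treatment_session <- function(id, gating, segments) {
  if (length(segments) < 1L)
    stop_iconqa("a session needs at least one segment",
                "iconqa_validation_error")
  for (seg in segments) {
    if (length(seg$residual) != 3L)
      stop_iconqa("each segment needs a 3-vector baseline residual",
                  "iconqa_validation_error")
    if (is.unsorted(seg$trace$t_s, strictly = TRUE))
      stop_iconqa("segment timestamps must be strictly increasing",
                  "iconqa_validation_error")
    if (any(seg$trace$radial_mm < 0))
      stop_iconqa("radial displacement cannot be negative",
                  "iconqa_validation_error")
  }
  structure(list(id = id, gating = gating, segments = segments),
            class = "treatment_session")
}

#' Parse an HDMM-style motion log file
#'
#' Reads the CSV log dialect written by [write_hdmm_log()]: \code{#} header
#' lines carrying \code{session_id}, \code{threshold_mm},
#' \code{record_trigger_mm} and \code{window_ms}, then columns
#' \code{t_s, x_mm, y_mm, z_mm, radial_mm, state, event}.  Rows are split
#' into segments at \code{baseline}/\code{rebaseline} events; the
#' baseline row's x/y/z are kept as the segment's post-CBCT residual and
#' every record is preserved.  Note the dialect's documented asymmetry:
#' x/y/z are instantaneous while \code{radial_mm} is a trailing-window
#' mean, so the quadrature of x/y/z need not equal \code{radial_mm} — the
#' parser must not "repair" this.
#'
#' @param source log file path.
#' @return a \code{treatment_session}.
#' @export
parse_hdmm_log <- function(source) {
  lines <- readLines(source)
  hdr <- grep("^#", lines)
  header <- lines[hdr]
  meta <- list()
  for (h in sub("^#\\s*", "", header)) {
    kv <- regmatches(h, regexec("^([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  df <- tryCatch(
    utils::read.csv(text = lines[body_start:length(lines)],
                    stringsAsFactors = FALSE, colClasses = c(
                      t_s = "numeric", x_mm = "numeric", y_mm = "numeric",
                      z_mm = "numeric", radial_mm = "numeric",
                      state = "character", event = "character")),
    error = function(e) stop_iconqa(
      paste0("malformed log body in ", source, ": ", conditionMessage(e)),
      "iconqa_parse_error"))
  need <- c("t_s", "x_mm", "y_mm", "z_mm", "radial_mm", "state", "event")
  if (!all(need %in% names(df)))
    stop_iconqa(paste0("log ", source, " lacks required columns"),
                "iconqa_parse_error")
  bad <- which(!stats::complete.cases(df[, 1:5]) |
               !(df$state %in% c("treating", "paused")) |
               !(df$event %in% c("baseline", "record", "rebaseline", "end")))
  if (length(bad))
    stop_iconqa(sprintf("malformed record at line %d of %s",
                        body_start + bad[1], source),
                "iconqa_parse_error")
  if (is.unsorted(df$t_s, strictly = TRUE))
    stop_iconqa(paste0("timestamps not strictly increasing in ", source),
                "iconqa_validation_error")
  starts <- which(df$event %in% c("baseline", "rebaseline"))
  if (length(starts) == 0L || starts[1] != 1L)
    stop_iconqa(paste0("log ", source, " must open with a baseline event"),
                "iconqa_parse_error")
  ends <- c(starts[-1] - 1L, nrow(df))
  segments <- lapply(seq_along(starts), function(j) {
    rows <- df[starts[j]:ends[j], , drop = FALSE]
    rownames(rows) <- NULL
    list(residual = as.numeric(rows[1, c("x_mm", "y_mm", "z_mm")]),
         trace = rows)
  })
  gating <- gating_config(
    threshold_mm = as.numeric(meta$threshold_mm %||% 1.5),
    record_trigger_mm = as.numeric(meta$record_trigger_mm %||% 0.2),
    window_ms = as.numeric(meta$window_ms %||% 500))
  treatment_session(id = meta$session_id %||% basename(source),
                    gating = gating, segments = segments)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact time integral of min(piecewise-linear radial, threshold) over one
# inter-sample interval; segments crossing the threshold are split at the
# crossing point so the clipped integral is exact, not a trapezoid of
# clipped endpoints
clipped_segment_integral <- function(r1, r2, thr, dt) {
  both_below <- r1 <= thr & r2 <= thr
  both_above <- r1 >= thr & r2 >= thr
  out <- numeric(length(r1))
  out[both_below] <- (r1[both_below] + r2[both_below]) / 2 * dt[both_below]
  out[both_above] <- thr * dt[both_above]
  cross <- !(both_below | both_above)
  if (any(cross)) {
    a <- (thr - r1[cross]) / (r2[cross] - r1[cross])
    rising <- r1[cross] < thr
    out[cross] <- ifelse(
      rising,
      dt[cross] * (a * (r1[cross] + thr) / 2 + (1 - a) * thr),
      dt[cross] * (a * thr + (1 - a) * (thr + r2[cross]) / 2))
  }
  out
}

#' Gating-truncated time-weighted (AUC) mean displacement
#'
#' Time-weighted mean marker position over a segment, restricted to
#' treating-state intervals: the piecewise-linear radial curve is clipped
#' at the gating threshold before integration (delivery was paused beyond
#' that point, so recorded excursions above it carry no delivered dose),
#' and paused intervals contribute to neither numerator nor denominator.
#' Each inter-record interval carries the state of its left endpoint (a
#' state change takes effect at the record that reports it).  Signed
#' per-axis means use the instantaneous x/y/z exactly as recorded; the
#' radial mean uses the windowed radial — the two are never mixed.
#'
#' @param segment marker-sample data.frame (\code{t_s, x_mm, y_mm, z_mm,
#'   radial_mm, state}), non-empty, strictly time-ordered.
#' @param gating a \code{gating_config}.
#' @return object of class \code{auc_result}: \code{mean_x_mm},
#'   \code{mean_y_mm}, \code{mean_z_mm}, \code{mean_radial_mm},
#'   \code{treating_duration_s}, and \code{empty} (TRUE when the segment
#'   has no treating time, in which case the means are NA — a signal, not
#'   an error).
#' @export
auc_mean <- function(segment, gating = gating_config()) {
  if (nrow(segment) == 0L)
    stop_iconqa("segment is empty", "iconqa_validation_error")
  if (is.unsorted(segment$t_s, strictly = TRUE))
    stop_iconqa("segment timestamps must be strictly increasing",
                "iconqa_validation_error")
  n <- nrow(segment)
  empty <- structure(list(mean_x_mm = NA_real_, mean_y_mm = NA_real_,
                          mean_z_mm = NA_real_, mean_radial_mm = NA_real_,
                          treating_duration_s = 0, empty = TRUE),
                     class = "auc_result")
  if (n < 2L) return(empty)
  keep <- segment$state[-n] == "treating"
  if (!any(keep)) return(empty)
  dt <- diff(segment$t_s)[keep]
  tt <- sum(dt)
  trap <- function(v) sum((v[-n][keep] + v[-1][keep]) / 2 * dt) / tt
  r1 <- segment$radial_mm[-n][keep]
  r2 <- segment$radial_mm[-1][keep]
  structure(list(
    mean_x_mm = trap(segment$x_mm),
    mean_y_mm = trap(segment$y_mm),
    mean_z_mm = trap(segment$z_mm),
    mean_radial_mm =
      sum(clipped_segment_integral(r1, r2, gating$threshold_mm, dt)) / tt,
    treating_duration_s = tt,
    empty = FALSE), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  if (x$empty) cat("AUC result: no treating time\n")
  else cat(sprintf(
    "AUC mean (mm): x %.3f, y %.3f, z %.3f, radial %.3f over %.1f s treating\n",
    x$mean_x_mm, x$mean_y_mm, x$mean_z_mm, x$mean_radial_mm,
    x$treating_duration_s))
  invisible(x)
}

#' Session-level AUC
#'
#' Combines the per-segment AUC means of a session, weighting each segment
#' by its treating time (each segment is referenced to its own baseline).
#'
#' @param session a \code{treatment_session}.
#' @return an \code{auc_result}.
#' @export
session_auc <- function(session) {
  parts <- lapply(session$segments,
                  function(seg) auc_mean(seg$trace, session$gating))
  parts <- Filter(function(p) !p$empty, parts)
  if (length(parts) == 0L)
    return(structure(list(mean_x_mm = NA_real_, mean_y_mm = NA_real_,
                          mean_z_mm = NA_real_, mean_radial_mm = NA_real_,
                          treating_duration_s = 0, empty = TRUE),
                     class = "auc_result"))
  w <- vapply(parts, `[[`, numeric(1), "treating_duration_s")
  wavg <- function(fld)
    sum(w * vapply(parts, `[[`, numeric(1), fld)) / sum(w)
  structure(list(mean_x_mm = wavg("mean_x_mm"),
                 mean_y_mm = wavg("mean_y_mm"),
                 mean_z_mm = wavg("mean_z_mm"),
                 mean_radial_mm = wavg("mean_radial_mm"),
                 treating_duration_s = sum(w),
                 empty = FALSE), class = "auc_result")
}

#' Post-CBCT residual setup statistics
#'
#' Collects the baseline residual vectors recorded at every image-guidance
#' correction across a cohort of sessions and summarises them as per-axis
#' signed mean +/- SD and per-measurement vector mean +/- SD, packaged as a
#' random component row.
#'
#' @param sessions list of \code{treatment_session}s.
#' @param name component label.
#' @return one-row \code{component_table}.
#' @export
post_cbct_residuals <- function(sessions, name = "Post-CBCT Residual") {
  if (length(sessions) == 0L)
    stop_iconqa("no sessions supplied", "iconqa_validation_error")
  res <- do.call(rbind, lapply(sessions, function(s)
    do.call(rbind, lapply(s$segments, function(seg) seg$residual))))
  vm <- vector_mean(res)
  uncertainty_component(
    name = name,
    axis_mean = colMeans(res),
    axis_sd = apply(res, 2, function(v) if (nrow(res) > 1L) stats::sd(v) else 0),
    vec_mean = vm$mean, vec_sd = vm$sd, n = nrow(res),
    error_type = "random", class = "A")
}

#' Cohort summary of AUC results
#'
#' Per-axis and radial mean +/- SD of the session-level AUC means across a
#' cohort, packaged as a random component row (the per-session radial AUC
#' plays the role of the per-measurement vector norm).
#'
#' @param results list of non-empty \code{auc_result}s, one per session.
#' @param name component label.
#' @return one-row \code{component_table}.
#' @export
cohort_summary <- function(results, name = "Motion During Treatment") {
  results <- Filter(function(r) !r$empty, results)
  if (length(results) == 0L)
    stop_iconqa("no non-empty AUC results supplied", "iconqa_validation_error")
  g <- function(fld) vapply(results, `[[`, numeric(1), fld)
  m <- cbind(g("mean_x_mm"), g("mean_y_mm"), g("mean_z_mm"))
  radial <- g("mean_radial_mm")
  n <- length(results)
  sdv <- function(v) if (n > 1L) stats::sd(v) else 0
  uncertainty_component(
    name = name,
    axis_mean = colMeans(m),
    axis_sd = apply(m, 2, sdv),
    vec_mean = mean(radial), vec_sd = sdv(radial), n = n,
    error_type = "random", class = "A")
}
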