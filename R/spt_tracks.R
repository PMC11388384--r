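#' Acquisition settings for synthetic single-particle tracking
#'
#' @param frame_dt_s Frame interval in seconds; the imaging regimes used are
#'   0.003, 0.006 and 0.024 s (any positive value is accepted).
#' @param n_tracks Number of tracks to generate.
#' @param mean_track_len_frames Mean track length in detections; lengths are
#'   geometric, truncated to `[min_len, max_len]`.
#' @param min_len,max_len Detection-count bounds (defaults 3 and 100, the
#'   range retained for fitting).
#' @param fov_um Field-of-view edge; initial positions are uniform in it.
#' @param max_link_um Maximum linking distance of the upstream tracker,
#'   recorded as metadata only (default 1.71).
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(frame_dt_s = 0.006, n_tracks = 1000L,
                             mean_track_len_frames = 15, min_len = 3L,
                             max_len = 100L, fov_um = 100,
                             max_link_um = 1.71) {
  stopifnot(frame_dt_s > 0, n_tracks >= 0, mean_track_len_frames >= 3,
            min_len >= 3L, max_len >= min_len, fov_um > 0)
  structure(list(frame_dt_s = frame_dt_s, n_tracks = as.integer(n_tracks),
                 mean_track_len_frames = mean_track_len_frames,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 fov_um = fov_um, max_link_um = max_link_um),
            class = "acquisition_spec")
}

# geometric track length truncated to [min_len, max_len]
rtrunc_geom <- function(n, mean_len, min_len, max_len) {
  p <- 1 / max(mean_len - min_len + 1, 1.001)
  len <- min_len + stats::rgeom(n, p)
  too_long <- len > max_len
  while (any(too_long)) {
    len[too_long] <- min_len + stats::rgeom(sum(too_long), p)
    too_long <- len > max_len
  }
  len
}

#' Simulate Markov-switching Brownian tracks
#'
#' Per track: the initial hidden state is drawn from the stationary
#' occupancies; the state evolves once per frame by the per-frame transition
#' matrix (so at most one transition per frame interval); true per-axis
#' displacements are `N(0, 2 * D_state * frame_dt)`; and each observed
#' position is the true position plus independent `N(0, sigma_loc^2)`
#' localization error per axis. Track lengths are truncated-geometric.
#' Hidden states are retained in the `true_state` column so inference can be
#' tested as parameter recovery.
#'
#' @param model A `state_model`.
#' @param acq An [acquisition_spec()].
#' @param seed RNG seed.
#' @return A `track_set` data.frame with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `true_state`; attribute `frame_dt_s` carries the frame
#'   interval.
#' @export
simulate_tracks <- function(model, acq = acquisition_spec(), seed = 1L) {
  stopifnot(inherits(model, "state_model"), inherits(acq, "acquisition_spec"))
  set.seed(seed)
  K <- model$K
  n <- acq$n_tracks
  if (n == 0L) return(empty_track_set(acq$frame_dt_s))
  lens <- rtrunc_geom(n, acq$mean_track_len_frames, acq$min_len, acq$max_len)
  total <- sum(lens)
  # hidden states, frame by frame
  state <- integer(total)
  pos <- 1L
  cumA <- t(apply(model$A, 1, cumsum))
  for (tr in seq_len(n)) {
    Tl <- lens[tr]
    s <- integer(Tl)
    s[1] <- findInterval(stats::runif(1), cumsum(model$pi)) + 1L
    if (Tl > 1) {
      u <- stats::runif(Tl - 1)
      for (t in 2:Tl) s[t] <- findInterval(u[t - 1], cumA[s[t - 1], ]) + 1L
    }
    state[pos:(pos + Tl - 1L)] <- s
    pos <- pos + Tl
  }
  track_id <- rep.int(seq_len(n), lens)
  frame <- sequence(lens) - 1L
  # true displacements: the state at the *departing* frame governs the step
  state_prev <- c(state[1], state[-total])
  sd_step <- sqrt(2 * model$D_um2s[state_prev] * acq$frame_dt_s)
  dx <- stats::rnorm(total, 0, sd_step)
  dy <- stats::rnorm(total, 0, sd_step)
  first <- frame == 0L
  dx[first] <- stats::runif(sum(first), 0, acq$fov_um)
  dy[first] <- stats::runif(sum(first), 0, acq$fov_um)
  x_true <- stats::ave(dx, track_id, FUN = cumsum)
  y_true <- stats::ave(dy, track_id, FUN = cumsum)
  noise <- model$sigma_loc_um
  tracks <- data.frame(
    track_id = track_id,
    frame = frame,
    t_s = frame * acq$frame_dt_s,
    x_um = x_true + stats::rnorm(total, 0, noise),
    y_um = y_true + stats::rnorm(total, 0, noise),
    true_state = state
  )
  as_track_set(tracks, frame_dt_s = acq$frame_dt_s, validate = FALSE)
}

empty_track_set <- function(frame_dt_s) {
  as_track_set(
    data.frame(track_id = integer(), frame = integer(), t_s = numeric(),
               x_um = numeric(), y_um = numeric()),
    frame_dt_s = frame_dt_s, validate = FALSE)
}

#' Coerce and validate a track table
#'
#' Checks the track-table contract: required columns present, frames within
#' each track strictly increasing and gapless (discontinuous trajectories are
#' not allowed), finite positions.
#'
#' @param df A data.frame with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um` and optionally `true_state`.
#' @param frame_dt_s Frame interval metadata.
#' @param validate Run the contract checks (default `TRUE`).
#' @return A `track_set`.
#' @export
as_track_set <- function(df, frame_dt_s = NA_real_, validate = TRUE) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("track table is missing columns: ", paste(miss, collapse = ", "))
  if (validate && nrow(df) > 0) {
    if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
      stop("non-finite positions in track table")
    d <- unlist(tapply(df$frame, df$track_id, diff), use.names = FALSE)
    if (length(d) > 0 && any(d != 1L)) {
      bad <- names(which(vapply(split(df$frame, df$track_id),
                                function(f) any(diff(f) != 1L), logical(1))))
      stop("discontinuous or non-monotone frames in track(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  structure(df, class = c("track_set", "data.frame"),
            frame_dt_s = frame_dt_s)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d localizations in %d tracks (frame dt %s s)\n",
              nrow(x), length(unique(x$track_id)),
              format(attr(x, "frame_dt_s"))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write / read track tables
#'
#' CSV dialect: header `track_id,frame,t_s,x_um,y_um[,true_state]`, UTF-8,
#' one row per localization, frames 0-based, positions in micrometres.
#' Reading validates the frame-continuity contract and fails naming the
#' offending track.
#'
#' @param tracks A `track_set`.
#' @param path File path.
#' @return `read_tracks` returns a `track_set`; `write_tracks` returns the
#'   path invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param frame_dt_s Frame interval metadata to attach (inferred from the
#'   `t_s` column when `NA`).
#' @param col_map Optional named character vector mapping this package's
#'   column names to the file's (e.g. generic tracker exports:
#'   `c(track_id = "TRACK_ID", frame = "FRAME", x_um = "POSITION_X", ...)`).
#' @export
read_tracks <- function(path, frame_dt_s = NA_real_, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      theirs <- col_map[[ours]]
      if (!theirs %in% names(df))
        stop("mapped column not found in file: ", theirs)
      names(df)[names(df) == theirs] <- ours
    }
  }
  if (!"t_s" %in% names(df) && "frame" %in% names(df) && !is.na(frame_dt_s))
    df$t_s <- df$frame * frame_dt_s
  if (is.na(frame_dt_s) && nrow(df) > 1) {
    dt <- diff(df$t_s[df$track_id == df$track_id[1]])
    if (length(dt) > 0) frame_dt_s <- stats::median(dt)
  }
  as_track_set(df, frame_dt_s = frame_dt_s, validate = TRUE)
}

# Per-track displacement table: one row per frame interval, with sufficient
# statistics used throughout the inference layer.
track_displacements <- function(tracks) {
  df <- as.data.frame(tracks)
  if (nrow(df) == 0)
    return(data.frame(track_id = integer(), dx = numeric(), dy = numeric()))
  o <- order(df$track_id, df$frame)
  df <- df[o, ]
  same <- c(FALSE, df$track_id[-1] == df$track_id[-nrow(df)])
  data.frame(track_id = df$track_id[same],
             dx = c(NA, diff(df$x_um))[same],
             dy = c(NA, diff(df$y_um))[same])
}
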