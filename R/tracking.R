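# Microbubble tracking: constant-velocity Kalman motion model, pairing
# probability p (so that pairing cost is 1/p), globally optimal one-to-one
# assignment between consecutive frames with birth/death handling, and
# track assembly with the minimum-length filter (>= 3 frames).

#' Kalman state for a tracked microbubble
#'
#' Constant-velocity state `(x, y, vx, vy)` in um and um/s with a 4x4
#' covariance.
#'
#' @param state Length-4 numeric `(x, y, vx, vy)`.
#' @param covariance 4x4 symmetric positive semi-definite matrix.
#' @param frame Last frame index the state was updated at.
#' @return An object of class `kalman_state`.
#' @export
kalman_state <- function(state, covariance, frame = NA_integer_) {
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev)))
    stop_invalid("covariance must be positive semi-definite")
  structure(list(state = as.numeric(state), covariance = covariance,
                 frame = frame),
            class = "kalman_state")
}

kalman_F <- function(dt) {
  matrix(c(1, 0, dt, 0,
           0, 1, 0, dt,
           0, 0, 1, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

# continuous white-noise-acceleration process noise; sigma_acc in um/s^2
kalman_Q <- function(dt, sigma_acc_um_s2) {
  q <- sigma_acc_um_s2^2
  Qa <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- Qa
  Q[c(2, 4), c(2, 4)] <- Qa
  Q
}

H_MEAS <- matrix(c(1, 0, 0, 0,
                   0, 1, 0, 0), 2, 4, byrow = TRUE)

#' Kalman prediction step
#'
#' Constant-velocity transition over `dt`: position advances by velocity
#' times `dt`; the covariance is propagated with white-noise-acceleration
#' process noise.
#'
#' @param state A [kalman_state()].
#' @param dt Time step (s), > 0.
#' @param sigma_acc_um_s2 Process noise (expected acceleration scale,
#'   um/s^2); default 1 mm/s^2.
#' @return The predicted [kalman_state()].
#' @export
kalman_predict <- function(state, dt, sigma_acc_um_s2 = 1000) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  F <- kalman_F(dt)
  kalman_state(F %*% state$state,
               F %*% state$covariance %*% t(F) + kalman_Q(dt, sigma_acc_um_s2),
               state$frame)
}

#' Pairing probability under the Kalman motion model
#'
#' The Gaussian density of the innovation under `N(0, S)` (with `S` the
#' innovation covariance), normalized by its maximum, so `p = exp(-d^2/2)`
#' with `d` the Mahalanobis distance: `p = 1` at zero innovation and the
#' pairing cost is `1/p`.
#'
#' @param predicted A predicted [kalman_state()].
#' @param detection Either a `data.frame` row with `x_um`, `y_um` or a
#'   length-2 numeric position (um).
#' @param meas_sd_um Measurement noise standard deviation per axis (um);
#'   default one fine pixel (4 um).
#' @return Probability `p` in (0, 1] with attribute `"mahalanobis"`.
#' @export
pairing_probability <- function(predicted, detection, meas_sd_um = 4) {
  z <- if (is.data.frame(detection)) c(detection$x_um[1], detection$y_um[1])
       else as.numeric(detection)[1:2]
  S <- H_MEAS %*% predicted$covariance %*% t(H_MEAS) +
    diag(meas_sd_um^2, 2)
  if (abs(det(S)) < 1e-12 || !all(is.finite(S)))
    stop_degenerate("singular innovation covariance")
  nu <- z - predicted$state[1:2]
  d2 <- drop(t(nu) %*% solve(S, nu))
  p <- exp(-d2 / 2)
  attr(p, "mahalanobis") <- sqrt(d2)
  p
}

kalman_update <- function(predicted, z, meas_sd_um = 4) {
  S <- H_MEAS %*% predicted$covariance %*% t(H_MEAS) + diag(meas_sd_um^2, 2)
  K <- predicted$covariance %*% t(H_MEAS) %*% solve(S)
  nu <- z - drop(H_MEAS %*% predicted$state)
  x <- predicted$state + drop(K %*% nu)
  P <- (diag(4) - K %*% H_MEAS) %*% predicted$covariance
  kalman_state(x, P, predicted$frame)
}

# Jonker-Volgenant / shortest-augmenting-path solution of the square linear
# assignment problem; deterministic. Returns for each row its column.
lap_solve <- function(C) {
  n <- nrow(C)
  if (n == 0) return(integer())
  J0 <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(J0)
  p <- integer(J0)  # row assigned to each column (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, n)
    used <- rep(FALSE, J0)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- C[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(J0)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == J0) i else p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assign[p[j]] <- j
  assign
}

#' Build an augmented track/detection assignment problem
#'
#' The augmented square matrix has pairing costs `1/p` in the top-left
#' `n x m` block, per-track death penalties on the top-right diagonal,
#' per-detection birth penalties on the bottom-left diagonal, and zeros in
#' the completion block, so the global optimum trades pairings against
#' birth + death.
#'
#' @param pair_cost `n x m` matrix of pairing costs (`1/p`); use a large
#'   finite value for gated-out pairs.
#' @param birth,death Birth and death penalties. The defaults make
#'   birth + death equal to the pairing cost at the Mahalanobis gate radius
#'   `d = 3`, so pairings worse than the gate lose to birth + death.
#' @return An object of class `assignment_problem` (fields `cost`, `n`,
#'   `m`).
#' @export
assignment_problem <- function(pair_cost,
                               birth = exp(9 / 2) / 2,
                               death = exp(9 / 2) / 2) {
  n <- nrow(pair_cost); m <- ncol(pair_cost)
  BIG <- 1e12
  C <- matrix(BIG, n + m, n + m)
  if (n > 0 && m > 0) C[1:n, 1:m] <- pair_cost
  if (n > 0) for (i in 1:n) C[i, m + i] <- death
  if (m > 0) for (j in 1:m) C[n + j, j] <- birth
  if (n > 0 && m > 0) C[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  if (n == 0 && m == 0) C <- matrix(0, 0, 0)
  structure(list(cost = C, n = n, m = m), class = "assignment_problem")
}

#' Solve an augmented assignment problem to global optimality
#'
#' @param problem An [assignment_problem()].
#' @return List with `pairs` (2-column matrix: track row, detection column),
#'   `dead` (unmatched track rows), `born` (unmatched detection columns) and
#'   `total_cost` (over the augmented matrix).
#' @export
solve_assignment <- function(problem) {
  n <- problem$n; m <- problem$m
  if (n + m == 0)
    return(list(pairs = matrix(0L, 0, 2), dead = integer(),
                born = integer(), total_cost = 0))
  if (!all(is.finite(problem$cost))) stop_invalid("costs must be finite")
  assign <- lap_solve(problem$cost)
  pairs <- list()
  dead <- integer(); born <- integer()
  for (i in seq_len(n)) {
    j <- assign[i]
    if (j <= m) pairs[[length(pairs) + 1]] <- c(i, j) else dead <- c(dead, i)
  }
  if (m > 0) {
    matched_det <- vapply(pairs, `[`, integer(1) + 0, 2)
    born <- setdiff(seq_len(m), matched_det)
  }
  total <- sum(problem$cost[cbind(seq_len(n + m), assign)])
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else matrix(0L, 0, 2),
       dead = dead, born = born, total_cost = total)
}

#' Link per-frame localizations into microbubble tracks
#'
#' Iterates over consecutive frame pairs: active tracks are predicted with
#' the Kalman model, the pairing cost `1/p` (gated at `gate` Mahalanobis
#' radii) feeds the augmented assignment, matched tracks are Kalman-updated,
#' unmatched tracks die, and unmatched detections start new tracks with zero
#' velocity and an inflated velocity covariance. Per-step velocities are
#' displacement times frame rate. Tracks observed in fewer than
#' `min_length` frames are discarded.
#'
#' @param localizations `data.frame(frame, x_um, y_um, score)` (e.g. from
#'   [localize_sequence()]).
#' @param frame_rate_hz Frame rate (Hz).
#' @param gate Mahalanobis gate radius (default 3).
#' @param penalties List with `birth` and `death`; defaults as in
#'   [assignment_problem()].
#' @param sigma_acc_um_s2 Process noise scale (um/s^2).
#' @param meas_sd_um Measurement noise (um).
#' @param init_vel_sd_um_s New-track velocity prior standard deviation
#'   (um/s); the default spans 0-10 mm/s.
#' @param min_length Minimum number of frames per kept track (default 3).
#' @param n_frames Total frame count (defaults to the max frame index).
#' @return Object of class `ulm_tracks`: a list of data.frames
#'   `(frame, x_um, y_um, vx_um_s, vy_um_s, score)` with attribute
#'   `"n_discarded"`.
#' @export
link_tracks <- function(localizations, frame_rate_hz, gate = 3,
                        penalties = list(birth = exp(9 / 2) / 2,
                                         death = exp(9 / 2) / 2),
                        sigma_acc_um_s2 = 1000, meas_sd_um = 4,
                        init_vel_sd_um_s = 5000, min_length = 3L,
                        n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(localizations)) max(localizations$frame) else 0L
  dt <- 1 / frame_rate_hz
  BIG <- 1e9
  gate_cost <- exp(gate^2 / 2)
  by_frame <- split(localizations, factor(localizations$frame,
                                          levels = seq_len(n_frames)))
  active <- list()   # each: list(state, rows = data.frame of observations)
  finished <- list()
  new_track <- function(det, frame) {
    st <- kalman_state(c(det$x_um, det$y_um, 0, 0),
                       diag(c(meas_sd_um^2, meas_sd_um^2,
                              init_vel_sd_um_s^2, init_vel_sd_um_s^2)),
                       frame)
    list(state = st,
         rows = data.frame(frame = frame, x_um = det$x_um, y_um = det$y_um,
                           vx_um_s = 0, vy_um_s = 0, score = det$score))
  }
  if (n_frames >= 1) {
    d1 <- by_frame[[1]]
    for (k in seq_len(nrow(d1))) active[[length(active) + 1]] <-
      new_track(d1[k, ], 1L)
  }
  for (f in seq_len(n_frames)[-1]) {
    det <- by_frame[[f]]
    n <- length(active); m <- nrow(det)
    if (n == 0 && m == 0) next
    preds <- lapply(active, function(tr)
      kalman_predict(tr$state, dt, sigma_acc_um_s2))
    pair_cost <- matrix(BIG, n, m)
    if (n > 0 && m > 0) {
      for (i in seq_len(n)) {
        p <- preds[[i]]
        S <- H_MEAS %*% p$covariance %*% t(H_MEAS) + diag(meas_sd_um^2, 2)
        Sinv <- solve(S)
        nu_x <- det$x_um - p$state[1]
        nu_y <- det$y_um - p$state[2]
        d2 <- Sinv[1, 1] * nu_x^2 + 2 * Sinv[1, 2] * nu_x * nu_y +
          Sinv[2, 2] * nu_y^2
        cost <- exp(pmin(d2, 2 * log(BIG)) / 2)
        cost[sqrt(d2) > gate] <- BIG
        pair_cost[i, ] <- cost
      }
    }
    sol <- solve_assignment(assignment_problem(pair_cost,
                                               penalties$birth,
                                               penalties$death))
    next_active <- list()
    matched_tracks <- if (nrow(sol$pairs)) sol$pairs[, 1] else integer()
    for (k in seq_len(nrow(sol$pairs))) {
      i <- sol$pairs[k, 1]; j <- sol$pairs[k, 2]
      tr <- active[[i]]
      z <- c(det$x_um[j], det$y_um[j])
      st <- kalman_update(preds[[i]], z, meas_sd_um)
      st$frame <- f
      prev <- tr$rows[nrow(tr$rows), ]
      v <- (z - c(prev$x_um, prev$y_um)) * frame_rate_hz
      if (nrow(tr$rows) == 1) {  # first step defines the initial velocity
        tr$rows$vx_um_s[1] <- v[1]
        tr$rows$vy_um_s[1] <- v[2]
      }
      tr$rows <- rbind(tr$rows,
                       data.frame(frame = f, x_um = z[1], y_um = z[2],
                                  vx_um_s = v[1], vy_um_s = v[2],
                                  score = det$score[j]))
      tr$state <- st
      next_active[[length(next_active) + 1]] <- tr
    }
    for (i in setdiff(seq_len(n), matched_tracks))
      finished[[length(finished) + 1]] <- active[[i]]
    for (j in sol$born)
      next_active[[length(next_active) + 1]] <- new_track(det[j, ], f)
    active <- next_active
  }
  finished <- c(finished, active)
  keep <- vapply(finished, function(tr) nrow(tr$rows) >= min_length, logical(1))
  tracks <- lapply(finished[keep], function(tr) {
    rownames(tr$rows) <- NULL
    tr$rows
  })
  structure(tracks, class = "ulm_tracks",
            n_formed = length(finished),
            n_discarded = sum(!keep))
}

#' @export
print.ulm_tracks <- function(x, ...) {
  cat(sprintf("<ulm_tracks> %d track(s) kept (%d formed, %d below min length)\n",
              length(x), attr(x, "n_formed"), attr(x, "n_discarded")))
  invisible(x)
}

#' Flatten tracks to one data.frame
#'
#' @param tracks An `ulm_tracks` object.
#' @return `data.frame(track_id, frame, x_um, y_um, vx_um_s, vy_um_s)`.
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks))
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      vx_um_s = numeric(), vy_um_s = numeric()))
  do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track_id = i, tracks[[i]][, c("frame", "x_um", "y_um",
                                        "vx_um_s", "vy_um_s")])))
}

#' Write tracks to CSV
#'
#' @param tracks An `ulm_tracks` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- tracks_to_df(tracks)
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
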