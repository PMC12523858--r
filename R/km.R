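#' Kaplan-Meier product-limit estimate
#'
#' @param data A data frame with columns `time` (>= 0) and `event` (0/1).
#' @return A data frame of ordered `(time, n_risk, n_event, survival)` rows:
#'   one row at time 0 with survival 1, then one row per distinct event time.
#'   All-censored data yields just the time-0 row (the constant-1 function).
#' @export
km_estimate <- function(data) {
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  time <- as.numeric(data$time)
  event <- as.integer(data$event)
  if (any(time < 0)) stop("negative times", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  keep <- sf$n.event > 0
  data.frame(
    time = c(0, sf$time[keep]),
    n_risk = c(sf$n, sf$n.risk[keep]),
    n_event = c(0, sf$n.event[keep]),
    survival = c(1, sf$surv[keep]))
}

km_step <- function(km, t) {
  # step-function lookup S(t) from a km_estimate table
  idx <- findInterval(t, km$time)
  km$survival[pmax(idx, 1L)]
}

#' Digitized Kaplan-Meier curve
#'
#' Container for step coordinates read off a published Kaplan-Meier plot plus
#' the number-at-risk table printed beneath it. Survival values are snapped
#' to `[0, 1]` and monotonized (running minimum) to absorb digitization
#' noise before validation.
#'
#' @param points Data frame (or 2-column matrix) of `(time, survival)`
#'   coordinates; the first point must be at time 0 (survival 1 after
#'   snapping).
#' @param risk_table Data frame (or 2-column matrix) of `(time, n_risk)`
#'   rows; counts must be non-increasing, with at least 2 rows for
#'   reconstruction.
#' @param total_events Optional integer: the reported total number of events,
#'   used to pin down event/censoring allocation after the last at-risk time.
#' @return An object of class `"digitized_curve"`.
#' @export
digitized_curve <- function(points, risk_table, total_events = NULL) {
  points <- as.data.frame(points)[, 1:2]
  names(points) <- c("time", "survival")
  risk_table <- as.data.frame(risk_table)[, 1:2]
  names(risk_table) <- c("time", "n_risk")
  points <- points[order(points$time), , drop = FALSE]
  points$survival <- cummin(pmin(pmax(points$survival, 0), 1))
  if (points$time[1] != 0) stop("first digitized point must be at time 0", call. = FALSE)
  if (points$survival[1] != 1)
    stop("survival at time 0 must be 1", call. = FALSE)
  if (any(diff(points$time) < 0)) stop("times must be ordered", call. = FALSE)
  risk_table <- risk_table[order(risk_table$time), , drop = FALSE]
  if (any(diff(risk_table$n_risk) > 0))
    stop("at-risk counts must be non-increasing", call. = FALSE)
  if (any(risk_table$n_risk < 0) || any(risk_table$n_risk != round(risk_table$n_risk)))
    stop("at-risk counts must be non-negative integers", call. = FALSE)
  if (risk_table$time[1] > 0)
    stop("risk table must start at (or before) time 0", call. = FALSE)
  if (max(risk_table$time) > max(points$time))
    stop("risk-table times extend past the digitized curve", call. = FALSE)
  structure(list(points = points, risk_table = risk_table,
                 total_events = if (is.null(total_events)) NULL else as.integer(total_events)),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("Digitized KM curve: %d points over [0, %.2f] months, %d at risk initially\n",
              nrow(x$points), max(x$points$time), x$risk_table$n_risk[1]))
  if (!is.null(x$total_events))
    cat(sprintf("Reported total events: %d\n", x$total_events))
  invisible(x)
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Implements the Guyot-style inversion of the Kaplan-Meier construction:
#' within each interval between adjacent at-risk times, censoring times are
#' spread uniformly and event counts at the digitized time points are chosen
#' so that (a) the product-limit estimate of the output reproduces the
#' digitized survival values and (b) the implied number at risk matches the
#' printed risk table at the next at-risk time. After the final at-risk time
#' no interior censoring is assumed unless a reported `total_events` forces a
#' rescaling; subjects still at risk at the end of the observation window are
#' administratively censored there. The algorithm is deterministic.
#'
#' @param curve A [digitized_curve()].
#' @return A data frame of `n_risk[1]` records with columns `time` and
#'   `event` (1 = event, 0 = censored), sorted by time.
#' @export
reconstruct_ipd <- function(curve) {
  if (!inherits(curve, "digitized_curve"))
    stop("'curve' must be a digitized_curve", call. = FALSE)
  pts <- curve$points
  rt <- curve$risk_table
  if (nrow(rt) < 2) stop("need at least 2 risk-table entries", call. = FALSE)

  t_end <- max(pts$time)
  bounds <- c(rt$time, t_end + 1e-9)
  interval_of <- findInterval(pts$time, bounds, rightmost.closed = FALSE)

  ev_time <- numeric(0); ev_flag <- integer(0)
  n_cur <- rt$n_risk[1]
  s_km <- 1

  # allocate one interval given a censor count; returns end state. n_floor
  # trims events so the at-risk count never drops below it (used to absorb
  # digitization noise that implies a few more events than the risk table
  # can accommodate).
  alloc <- function(idx, n0, s0, cens, win, n_floor = 0L) {
    ct <- if (cens > 0) win[1] + (seq_len(cens) - 0.5) / cens * diff(win) else numeric(0)
    n <- n0; s <- s0
    times <- numeric(0); flags <- integer(0)
    for (k in idx) {
      # censor first those with times before this event time
      nc <- sum(ct < pts$time[k])
      if (nc > 0) {
        times <- c(times, ct[seq_len(nc)]); flags <- c(flags, rep(0L, nc))
        ct <- ct[-seq_len(nc)]
        n <- n - nc
      }
      if (pts$survival[k] < s && n > 0) {
        d <- round(n * (1 - pts$survival[k] / s))
        d <- max(0L, min(d, n, n - n_floor))
        if (d > 0) {
          times <- c(times, rep(pts$time[k], d)); flags <- c(flags, rep(1L, d))
          s <- s * (1 - d / n)
          n <- n - d
        }
      }
    }
    if (length(ct) > 0) {
      times <- c(times, ct); flags <- c(flags, rep(0L, length(ct)))
      n <- n - length(ct)
    }
    list(n = n, s = s, times = times, flags = flags)
  }

  for (i in seq_len(nrow(rt) - 1)) {
    idx <- which(interval_of == i & pts$time > 0)
    win <- c(rt$time[i], rt$time[i + 1])
    target <- rt$n_risk[i + 1]
    # the implied end count falls as the censor count grows: take the
    # smallest allocation still at or above the target, then pad with
    # end-of-interval censorings if rounding skipped the exact target
    best <- NULL
    for (cens in 0:max(0, n_cur - target)) {
      res <- alloc(idx, n_cur, s_km, cens, win)
      if (res$n < target) break
      best <- res
      if (res$n == target) break
    }
    if (is.null(best)) {
      # the curve drops further than the risk table allows; trim events to
      # the floor when the implied survival distortion is immaterial
      res <- alloc(idx, n_cur, s_km, 0L, win, n_floor = target)
      want <- if (length(idx) > 0) min(pts$survival[idx]) else s_km
      if (res$n == target && abs(res$s - want) <= 0.05) {
        best <- res
      } else {
        stop(sprintf(paste0("risk table inconsistent with the digitized curve in ",
                            "interval %d [%.3f, %.3f]: cannot reach %d at risk"),
                     i, win[1], win[2], target), call. = FALSE)
      }
    }
    if (best$n > target) {
      pad <- best$n - target
      best$times <- c(best$times, rep(win[2] - 1e-9, pad))
      best$flags <- c(best$flags, rep(0L, pad))
      best$n <- target
    }
    ev_time <- c(ev_time, best$times); ev_flag <- c(ev_flag, best$flags)
    n_cur <- best$n; s_km <- best$s
  }

  # last interval: events per the curve, remainder censored at the window end
  idx <- which(interval_of == nrow(rt) & pts$time > 0)
  res <- alloc(idx, n_cur, s_km, 0L, c(rt$time[nrow(rt)], t_end))
  ev_time <- c(ev_time, res$times); ev_flag <- c(ev_flag, res$flags)
  n_cur <- res$n
  if (n_cur > 0) {
    ev_time <- c(ev_time, rep(t_end, n_cur))
    ev_flag <- c(ev_flag, rep(0L, n_cur))
  }

  out <- data.frame(time = ev_time, event = ev_flag)

  if (!is.null(curve$total_events)) {
    diff_e <- curve$total_events - sum(out$event)
    if (diff_e > 0) {
      # convert latest censorings into events at their own times
      cens_idx <- rev(which(out$event == 0L & out$time >= max(rt$time)))
      take <- utils::head(cens_idx, diff_e)
      if (length(take) < diff_e)
        stop("cannot match total_events: too few late censorings", call. = FALSE)
      out$event[take] <- 1L
    } else if (diff_e < 0) {
      ev_idx <- rev(which(out$event == 1L))
      take <- utils::head(ev_idx, -diff_e)
      out$event[take] <- 0L
    }
  }

  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write pseudo-IPD and digitized curves as delimited text
#'
#' Pseudo individual patient data are exchanged as comma-separated text with
#' columns `time_months,event,arm`; digitized curves as two files (curve
#' points `time_months,survival`; risk table `time_months,n_risk`).
#'
#' @param path,points_path,risk_path File paths.
#' @param data A data frame with columns `time`, `event` and optionally `arm`.
#' @param curve A [digitized_curve()].
#' @param total_events Optional integer passed to [digitized_curve()].
#' @return `read_ipd` returns a data frame with columns `time`, `event`,
#'   `arm`; `read_digitized_curve` a [digitized_curve()]. The writers return
#'   their input invisibly.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_months", "event") %in% names(d)))
    stop("expected columns time_months,event[,arm]", call. = FALSE)
  out <- data.frame(time = as.numeric(d$time_months),
                    event = as.integer(d$event),
                    arm = if ("arm" %in% names(d)) as.character(d$arm) else NA_character_)
  out
}

#' @rdname read_ipd
#' @export
write_ipd <- function(data, path) {
  out <- data.frame(time_months = data$time, event = as.integer(data$event),
                    arm = if ("arm" %in% names(data)) data$arm else "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' @rdname read_ipd
#' @export
read_digitized_curve <- function(points_path, risk_path, total_events = NULL) {
  p <- utils::read.csv(points_path, stringsAsFactors = FALSE)
  r <- utils::read.csv(risk_path, stringsAsFactors = FALSE)
  digitized_curve(p, r, total_events = total_events)
}

#' @rdname read_ipd
#' @export
write_digitized_curve <- function(curve, points_path, risk_path) {
  utils::write.csv(data.frame(time_months = curve$points$time,
                              survival = curve$points$survival),
                   points_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(time_months = curve$risk_table$time,
                              n_risk = curve$risk_table$n_risk),
                   risk_path, row.names = FALSE, quote = FALSE)
  invisible(curve)
}
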