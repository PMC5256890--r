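# Timer + event-queue scheduler for interleaved multi-position imaging and
# uncaging, realized as a deterministic discrete-event simulation on a
# virtual clock.
#
# One timer per position step fires once every imaging period for the
# duration of the step (exactly once for an uncaging step); each firing
# appends an action to a FIFO event queue. A second, activation timer ticks
# every 0.1 s: when an action waits at the front of the queue it starts
# immediately and the activation timer pauses until the action completes, so
# no two actions ever execute concurrently. A wall-clock driver with the
# same semantics would differ only in the source of time.

#' One step of a position's timeline
#'
#' @param position_id position label.
#' @param kind `"imaging"` (periodic acquisition) or `"uncaging"`
#'   (fires exactly once).
#' @param start_s start time in seconds, relative to the position's admission
#'   into the session.
#' @param duration_s length of the step; an imaging timer fires while
#'   `t <= start_s + duration_s` (inclusive end).
#' @param period_s imaging period in seconds (required for imaging steps).
#' @return Object of class `timeline_step`.
#' @export
timeline_step <- function(position_id, kind = c("imaging", "uncaging"),
                          start_s = 0, duration_s = 0, period_s = NULL) {
  kind <- match.arg(kind)
  stopifnot(start_s >= 0, duration_s >= 0)
  if (kind == "imaging") {
    if (is.null(period_s) || period_s <= 0)
      stop("imaging steps need period_s > 0", call. = FALSE)
  } else period_s <- NA_real_
  structure(list(position_id = as.character(position_id), kind = kind,
                 start_s = start_s, duration_s = duration_s,
                 period_s = period_s),
            class = "timeline_step")
}

#' Firing times of a timeline step
#'
#' @param step a [timeline_step()].
#' @return Numeric vector of firing times (seconds, relative to admission):
#'   `start, start+period, ...` up to and including `start + duration` for
#'   imaging; a single `start` for uncaging.
#' @export
fire_times <- function(step) {
  stopifnot(inherits(step, "timeline_step"))
  if (step$kind == "uncaging") return(step$start_s)
  k <- floor(step$duration_s / step$period_s + 1e-9)
  step$start_s + step$period_s * (0:k)
}

#' Multi-position session plan
#'
#' @param steps list of [timeline_step()]s; position definition order is the
#'   order of first appearance, and breaks same-tick enqueue ties.
#' @param capacity maximum number of positions imaged concurrently; waiting
#'   positions are rotated in as earlier ones finish.
#' @param tick_s activation-timer period (seconds).
#' @return Object of class `session_plan`.
#' @export
session_plan <- function(steps, capacity = Inf, tick_s = 0.1) {
  stopifnot(is.list(steps), length(steps) >= 1, capacity >= 1, tick_s > 0)
  for (s in steps) stopifnot(inherits(s, "timeline_step"))
  ids <- unique(vapply(steps, `[[`, character(1), "position_id"))
  structure(list(steps = steps, positions = ids, capacity = capacity,
                 tick_s = tick_s),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d steps over %d positions, capacity %s, tick %.2g s\n",
              length(x$steps), length(x$positions),
              if (is.finite(x$capacity)) x$capacity else "unlimited", x$tick_s))
  invisible(x)
}

# Span of a position: time of its final firing relative to admission.
position_span <- function(plan, id) {
  mine <- Filter(function(s) s$position_id == id, plan$steps)
  max(vapply(mine, function(s) max(fire_times(s)), numeric(1)))
}

#' Rotation of positions through limited concurrent capacity
#'
#' When more positions are defined than can be imaged concurrently, only the
#' first `capacity` start at t = 0; each waiting position is admitted one
#' activation tick after an active position's final timer firing, in
#' definition order.
#'
#' @param plan a [session_plan()].
#' @param capacity override of the plan's capacity.
#' @param drop position ids deleted before the session; they are never
#'   admitted.
#' @return data.frame with `position_id` and `admit_s`.
#' @export
rotate_positions <- function(plan, capacity = plan$capacity,
                             drop = character()) {
  stopifnot(inherits(plan, "session_plan"), capacity >= 1)
  ids <- setdiff(plan$positions, drop)
  n <- length(ids)
  admit <- numeric(n)
  if (n == 0) return(data.frame(position_id = character(), admit_s = numeric()))
  spans <- vapply(ids, function(id) position_span(plan, id), numeric(1))
  release <- numeric(0)  # absolute final-firing times of active positions
  for (i in seq_len(n)) {
    if (length(release) < capacity) {
      admit[i] <- 0
    } else {
      first_done <- min(release)
      admit[i] <- first_done + plan$tick_s
      release <- release[-which.min(release)]
    }
    release <- c(release, admit[i] + spans[i])
  }
  data.frame(position_id = ids, admit_s = admit)
}

#' Execute a session plan on the virtual clock
#'
#' Fires every step's timer (offset by its position's admission time),
#' enqueues actions FIFO, and activates them on 0.1 s ticks with the
#' activation timer paused while an action executes. Fully deterministic
#' given the plan and executor.
#'
#' @param plan a [session_plan()].
#' @param executor `function(action)` performing the action and returning its
#'   duration in seconds; `action` is a list with `position_id`, `kind`, the
#'   firing (enqueue) time `fire_s` and the activation time `start_s`.
#'   Defaults to instantaneous actions.
#' @param capacity,drop see [rotate_positions()].
#' @return data.frame execution log with one row per executed action:
#'   `enqueue_t`, `start_t`, `end_t`, `position_id`, `action`.
#' @export
run_queue <- function(plan, executor = function(action) 0,
                      capacity = plan$capacity, drop = character()) {
  stopifnot(inherits(plan, "session_plan"))
  adm <- rotate_positions(plan, capacity, drop)
  if (nrow(adm) == 0)
    return(data.frame(enqueue_t = numeric(), start_t = numeric(),
                      end_t = numeric(), position_id = character(),
                      action = character()))
  pos_order <- stats::setNames(seq_along(adm$position_id), adm$position_id)
  evs <- list()
  for (si in seq_along(plan$steps)) {
    s <- plan$steps[[si]]
    if (!s$position_id %in% adm$position_id) next
    t0 <- adm$admit_s[match(s$position_id, adm$position_id)]
    for (ft in fire_times(s) + t0)
      evs[[length(evs) + 1L]] <- list(fire = ft, pos = s$position_id,
                                      kind = s$kind,
                                      ord = pos_order[[s$position_id]],
                                      step = si)
  }
  fire <- vapply(evs, `[[`, numeric(1), "fire")
  ord <- vapply(evs, `[[`, numeric(1), "ord")
  step <- vapply(evs, `[[`, numeric(1), "step")
  evs <- evs[order(fire, ord, step)]
  fire <- sort(fire)
  tick <- plan$tick_s
  eps <- 1e-9
  log <- vector("list", length(evs))
  qhead <- 1L  # front of the FIFO queue (= sorted firing order)
  tk <- tick   # next activation-timer firing
  n <- length(evs)
  while (qhead <= n) {
    # idle ticks until the next event has fired (stay on the tick grid)
    if (fire[qhead] > tk + eps)
      tk <- tk + tick * ceiling((fire[qhead] - tk - eps) / tick)
    e <- evs[[qhead]]
    dur <- executor(list(position_id = e$pos, kind = e$kind, fire_s = e$fire,
                         start_s = tk))
    stopifnot(is.finite(dur), dur >= 0)
    log[[qhead]] <- data.frame(enqueue_t = e$fire, start_t = tk,
                               end_t = tk + dur, position_id = e$pos,
                               action = e$kind)
    qhead <- qhead + 1L
    tk <- tk + dur + tick  # timer paused during execution, resumes after
  }
  do.call(rbind, log)
}
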