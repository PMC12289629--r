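# Device-workflow emulator: the measurement state machine of the
# handheld detector. Power-on initializes the modules and shows a
# welcome screen, then the device waits for the detection head to be
# pressed; a measurement either yields a result (browsable with the
# flip button, transmittable over the radio link) or a detection
# error. Timing (the ~2 s measurement, the 1 s welcome screen) is
# modeled as zero-cost `tick` events.

device_states <- function() {
  c("INIT", "WELCOME", "READY", "MEASURING", "RESULT", "ERROR",
    "TRANSMITTED")
}

device_events <- function() {
  c("power_on", "tick", "press_detect", "press_flip", "press_transmit",
    "reading")
}

#' Construct a device state
#'
#' @param state One of `INIT, WELCOME, READY, MEASURING, RESULT, ERROR,
#'   TRANSMITTED`.
#' @param estimate Current [predict_all()] estimate, or `NULL`.
#' @param page Display page, one of `"cla"`, `"clb"`, `"tcl"`.
#' @return List of class `"device_state"`.
#' @export
device_state <- function(state = "INIT", estimate = NULL, page = "cla") {
  state <- match.arg(state, device_states())
  page <- match.arg(page, c("cla", "clb", "tcl"))
  structure(list(state = state, estimate = estimate, page = page),
            class = "device_state")
}

#' @export
print.device_state <- function(x, ...) {
  cat(sprintf("<device_state> %s", x$state))
  if (!is.null(x$estimate) && x$state %in% c("RESULT", "TRANSMITTED"))
    cat(sprintf(" [%s = %.3f mg/g]", x$page, x$estimate[[x$page]]))
  cat("\n")
  invisible(x)
}

#' Advance the device state machine by one event
#'
#' Deterministic transitions: `INIT --power_on--> WELCOME --tick-->
#' READY --press_detect--> MEASURING --reading--> RESULT | ERROR`.
#' From `RESULT`: `press_flip` cycles the display page cla -> clb ->
#' tcl -> cla, `press_transmit` moves to `TRANSMITTED`, `tick` returns
#' to `READY`. `ERROR` and `TRANSMITTED` return to `READY` on `tick`.
#' An event that is illegal in the current state is a warning no-op —
#' the device never crashes on a button press.
#'
#' @param state A [device_state()].
#' @param event One of `power_on, tick, press_detect, press_flip,
#'   press_transmit, reading`.
#' @param reading A [sensor_reading()]; required with the `"reading"`
#'   event.
#' @param models,window Passed to [predict_all()].
#' @param transmit_sink Optional path; on `press_transmit` the current
#'   estimate is appended there as one JSON line (emulating the radio
#'   link to a phone).
#' @return The next [device_state()].
#' @export
#' @examples
#' s <- device_state()
#' s <- device_step(s, "power_on")
#' s <- device_step(s, "tick")
#' s <- device_step(s, "press_detect")
#' s <- device_step(s, "reading", sensor_reading(27.9, 27.0, 18.8, 80.9))
#' s
device_step <- function(state, event, reading = NULL,
                        models = default_models(),
                        window = plausibility_window(),
                        transmit_sink = NULL) {
  stopifnot(inherits(state, "device_state"))
  event <- match.arg(event, device_events())
  noop <- function() {
    warning(sprintf("event '%s' ignored in state %s", event, state$state))
    state
  }
  switch(state$state,
    INIT = if (event == "power_on") device_state("WELCOME") else noop(),
    WELCOME = if (event == "tick") device_state("READY") else noop(),
    READY = if (event == "press_detect") device_state("MEASURING")
            else noop(),
    MEASURING = if (event == "reading") {
      if (is.null(reading))
        lc_stop("the 'reading' event needs a sensor reading", "parameter")
      est <- tryCatch(
        predict_all(extract_features(reading), models, window),
        leafchroma_error = function(e) NULL)
      if (is.null(est) || est$status == "detection_error")
        device_state("ERROR")
      else device_state("RESULT", estimate = est, page = "cla")
    } else noop(),
    RESULT = switch(event,
      press_flip = device_state("RESULT", estimate = state$estimate,
                                page = c(cla = "clb", clb = "tcl",
                                         tcl = "cla")[[state$page]]),
      press_transmit = {
        if (!is.null(transmit_sink)) {
          cat(jsonlite::toJSON(state$estimate[c("cla", "clb", "tcl")],
                               auto_unbox = TRUE, digits = NA),
              "\n", file = transmit_sink, append = TRUE)
        }
        device_state("TRANSMITTED", estimate = state$estimate,
                     page = state$page)
      },
      tick = device_state("READY"),
      noop()),
    ERROR = if (event == "tick") device_state("READY") else noop(),
    TRANSMITTED = if (event == "tick") device_state("READY") else noop()
  )
}

#' Run an event script through the emulator
#'
#' @param events List whose elements are event names, or
#'   `list(event = "reading", reading = <sensor_reading>)` pairs.
#' @param state Starting state.
#' @param ... Passed to [device_step()].
#' @return List of visited [device_state()]s (including the start).
#' @export
device_run <- function(events, state = device_state(), ...) {
  visited <- list(state)
  for (ev in events) {
    if (is.list(ev)) {
      state <- device_step(state, ev$event, reading = ev$reading, ...)
    } else {
      state <- device_step(state, ev, ...)
    }
    visited[[length(visited) + 1L]] <- state
  }
  visited
}
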