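#' Device backend contract
#'
#' The interpreter drives any object implementing three generics:
#' `backend_set_valve()` applies an open/close actuation, `backend_advance_time()`
#' notifies the backend of elapsed (virtual or real) time, and
#' `backend_n_valves()` reports capacity. `backend_set_valve` must be
#' idempotent: opening an open valve, or closing a closed one, is a no-op at
#' the contract level (solenoids are level-driven, so repeated commands are
#' tolerated by the physical device too).
#'
#' Backends shipped with the package: [chip_backend()] (digital twin) and
#' [log_backend()] (records calls, touches nothing — used for dry analyses and
#' as a spy in tests).
#'
#' @param backend A backend object.
#' @param valve_id Integer valve number.
#' @param open Logical; `TRUE` to open, `FALSE` to close.
#' @param ms Elapsed milliseconds.
#' @name device_backend
NULL

#' @rdname device_backend
#' @export
backend_set_valve <- function(backend, valve_id, open) {
  UseMethod("backend_set_valve")
}

#' @rdname device_backend
#' @export
backend_advance_time <- function(backend, ms) UseMethod("backend_advance_time")

#' @rdname device_backend
#' @export
backend_n_valves <- function(backend) UseMethod("backend_n_valves")

#' A recording backend that drives no device
#'
#' Accepts any actuation within its valve range and appends it to an internal
#' log. Useful as a test spy and for trace capture without fluidic simulation.
#'
#' @param n_valves Number of valves the pretend device has.
#' @return An object of class `loc_log_backend`.
#' @export
log_backend <- function(n_valves = 15) {
  env <- new.env(parent = emptyenv())
  env$n_valves <- as.integer(n_valves)
  env$calls <- list()
  structure(env, class = "loc_log_backend")
}

#' @export
backend_set_valve.loc_log_backend <- function(backend, valve_id, open) {
  if (valve_id < 1 || valve_id > backend$n_valves)
    stop(sprintf("valve %d outside range 1..%d", valve_id, backend$n_valves))
  backend$calls <- c(backend$calls,
                     list(list(what = "set_valve", valve_id = valve_id, open = open)))
  invisible(backend)
}

#' @export
backend_advance_time.loc_log_backend <- function(backend, ms) {
  backend$calls <- c(backend$calls, list(list(what = "advance_time", ms = ms)))
  invisible(backend)
}

#' @export
backend_n_valves.loc_log_backend <- function(backend) backend$n_valves
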