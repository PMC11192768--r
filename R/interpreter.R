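#' Inline-expand all function calls in a script
#'
#' Replaces every `call` instruction by its function body, recursively for
#' nested calls, preserving order. The result contains only OPEN/CLOSE/WAIT
#' instructions. Each expanded instruction is annotated with the name of its
#' innermost enclosing function (`"main"` for top-level instructions) in an
#' `origin` attribute-field.
#'
#' @param script A validated [loc_script()].
#' @return A list of `loc_instruction` objects, each carrying an extra
#'   `origin` field.
#' @export
expand_calls <- function(script) {
  stopifnot(inherits(script, "loc_script"))
  expand_body <- function(body, origin, seen) {
    out <- list()
    for (ins in body) {
      if (ins$kind == "CALL") {
        name <- ins$function_name
        if (!(name %in% names(script$functions)))
          stop(sprintf("internal error: call to undefined function '%s'", name))
        if (name %in% seen)
          stop(sprintf("internal error: recursive call to '%s'", name))
        out <- c(out, expand_body(script$functions[[name]], name, c(seen, name)))
      } else {
        ins$origin <- origin
        out <- c(out, list(ins))
      }
    }
    out
  }
  expand_body(script$main, "main", character())
}

new_trace <- function(events, total_duration_ms, final_state_ref = NA_character_) {
  structure(
    list(events = events, total_duration_ms = total_duration_ms,
         final_state_ref = final_state_ref),
    class = "loc_trace"
  )
}

empty_events <- function() {
  data.frame(t_ms = numeric(), action = character(), valve_id = integer(),
             origin = character(), line_no = integer(), stringsAsFactors = FALSE)
}

#' @export
print.loc_trace <- function(x, ...) {
  cat(sprintf("<loc_trace: %d actuation(s), %s ms total>\n",
              nrow(x$events), format(x$total_duration_ms, big.mark = ",")))
  if (nrow(x$events) > 0) print(utils::head(x$events, 10))
  if (nrow(x$events) > 10) cat(sprintf("... %d more\n", nrow(x$events) - 10))
  invisible(x)
}

#' Execute a script against a device backend
#'
#' Walks the call-expanded instruction list: each `o`/`c` is forwarded to
#' [backend_set_valve()] and logged with the current clock value; each `w`
#' advances the clock — instantaneously in `"virtual"` mode, by sleeping
#' wall-clock time in `"realtime"` mode (for hardware/transport backends).
#' Execution is strictly sequential; there are no concurrent valve timelines.
#'
#' If the backend rejects an actuation (e.g. a fluidics violation raised by a
#' strict virtual chip), the run aborts with a condition of class
#' `loc_run_error` whose `trace` field holds the partial execution trace; no
#' rollback is attempted.
#'
#' @param script A [loc_script()] that passed [validate_script()].
#' @param backend A device backend (see [device_backend]); defaults to a
#'   [log_backend()].
#' @param mode `"virtual"` (virtual clock, default) or `"realtime"`.
#' @return An object of class `loc_trace`: `events` (data frame with `t_ms`,
#'   `action`, `valve_id`, `origin`, `line_no`), `total_duration_ms` (sum of
#'   all waits executed), `final_state_ref`.
#' @examples
#' s <- parse_script(c("main:", "o 1", "w 500", "c 1", "end"))
#' run_script(s)
#' @export
run_script <- function(script, backend = log_backend(),
                       mode = c("virtual", "realtime")) {
  mode <- match.arg(mode)
  flat <- expand_calls(script)
  t_ms <- 0
  ev_t <- numeric(); ev_a <- character(); ev_v <- integer()
  ev_o <- character(); ev_l <- integer()
  abort <- function(e) {
    events <- data.frame(t_ms = ev_t, action = ev_a, valve_id = ev_v,
                         origin = ev_o, line_no = ev_l, stringsAsFactors = FALSE)
    cond <- structure(
      class = c("loc_run_error", "error", "condition"),
      list(message = conditionMessage(e), call = conditionCall(e),
           trace = new_trace(events, t_ms, "aborted"))
    )
    stop(cond)
  }
  for (ins in flat) {
    if (ins$kind == "WAIT") {
      if (mode == "realtime" && ins$duration_ms > 0)
        Sys.sleep(ins$duration_ms / 1000)
      t_ms <- t_ms + ins$duration_ms
      tryCatch(backend_advance_time(backend, ins$duration_ms), error = abort)
    } else {
      tryCatch(
        backend_set_valve(backend, ins$valve_id, open = ins$kind == "OPEN"),
        error = abort
      )
      ev_t <- c(ev_t, t_ms); ev_a <- c(ev_a, ins$kind)
      ev_v <- c(ev_v, ins$valve_id); ev_o <- c(ev_o, ins$origin)
      ev_l <- c(ev_l, if (is.na(ins$line_no)) NA_integer_ else ins$line_no)
    }
  }
  events <- data.frame(t_ms = ev_t, action = ev_a, valve_id = ev_v,
                       origin = ev_o, line_no = ev_l, stringsAsFactors = FALSE)
  new_trace(events, t_ms, final_state_ref = class(backend)[[1]])
}

#' Pre-flight analysis of a script without touching any device
#'
#' Computes, from the call-expanded instruction list alone: the total
#' scheduled duration, per-valve open/close actuation counts, the peak number
#' of simultaneously open valves (assuming all valves start closed), and the
#' wait time attributed to each enclosing function. Supports reviewing remotely
#' submitted scripts before granting them device time.
#'
#' @param script A validated [loc_script()].
#' @param topology A [chip_topology()] (valve range only).
#' @return A list of class `loc_dry_run`: `total_duration_ms`,
#'   `n_actuations`, `valve_counts` (data frame valve/n_open/n_close),
#'   `peak_open`, `wait_by_origin` (named numeric, ms per enclosing function).
#' @export
dry_run <- function(script, topology = chip_topology()) {
  flat <- expand_calls(script)
  n <- topology$n_valves
  n_open <- integer(n); n_close <- integer(n)
  open_now <- logical(n)
  peak <- 0L
  total <- 0
  waits <- numeric()
  for (ins in flat) {
    if (ins$kind == "WAIT") {
      total <- total + ins$duration_ms
      o <- ins$origin
      waits[o] <- (if (o %in% names(waits)) waits[[o]] else 0) + ins$duration_ms
    } else {
      v <- ins$valve_id
      if (ins$kind == "OPEN") {
        n_open[v] <- n_open[v] + 1L
        open_now[v] <- TRUE
      } else {
        n_close[v] <- n_close[v] + 1L
        open_now[v] <- FALSE
      }
      peak <- max(peak, sum(open_now))
    }
  }
  structure(
    list(
      total_duration_ms = total,
      n_actuations = sum(n_open) + sum(n_close),
      valve_counts = data.frame(valve = seq_len(n), n_open = n_open,
                                n_close = n_close),
      peak_open = peak,
      wait_by_origin = waits
    ),
    class = "loc_dry_run"
  )
}

#' @export
print.loc_dry_run <- function(x, ...) {
  cat(sprintf("<dry run: %s ms scheduled, %d actuations, peak %d valves open>\n",
              format(x$total_duration_ms, big.mark = ","), x$n_actuations,
              x$peak_open))
  if (length(x$wait_by_origin) > 0) {
    cat("wait by block:\n")
    for (n in names(x$wait_by_origin))
      cat(sprintf("  %-12s %s ms\n", n,
                  format(x$wait_by_origin[[n]], big.mark = ",")))
  }
  invisible(x)
}

#' Export an execution trace
#'
#' Writes the actuation log as tab-separated text (`t_ms`, `action`,
#' `valve_id`, `origin`, `line_no`) or as structured JSON.
#'
#' @param trace A `loc_trace` from [run_script()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(trace$events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(events = trace$events, total_duration_ms = trace$total_duration_ms,
           final_state_ref = trace$final_state_ref),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
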