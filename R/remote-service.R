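#' @title Message-driven remote control
#' @description
#' On the physical platform, a remote GUI talks to the laboratory device over
#' MQTT; the local interpreter receives script text or single-valve commands
#' as messages and acknowledges with status messages. This module reproduces
#' that contract with an in-process publish/subscribe bus using MQTT-style
#' hierarchical topics (`device/<id>/command`, `device/<id>/status`) and JSON
#' payloads, and a virtual device that mirrors the GUI's three modes of
#' operation:
#'
#' 1. **manual** — remote control of an individual valve
#'    ([manual_valve_command()]);
#' 2. **saved script** — selection and execution of a locally stored script
#'    ([run_saved_script()]);
#' 3. **upload** — transferring a new script for storage and future use
#'    ([upload_script()]).
#'
#' Delivery is synchronous and per-topic FIFO; every command message is
#' answered by at least one status message carrying its `msg_id` as `ref_id`
#' (acknowledged-delivery contract). A real-broker transport can be layered on
#' the same message shape but is never required.
#' @name remote_service
NULL

#' In-process message bus
#'
#' @return An object of class `loc_bus` (an environment holding the message
#'   log and subscriptions).
#' @export
loc_bus <- function() {
  env <- new.env(parent = emptyenv())
  env$next_id <- 1L
  env$log <- list()
  env$subs <- list()   # each: list(pattern, handler)
  structure(env, class = "loc_bus")
}

#' @export
print.loc_bus <- function(x, ...) {
  cat(sprintf("<loc_bus: %d message(s), %d subscription(s)>\n",
              length(x$log), length(x$subs)))
  invisible(x)
}

#' MQTT-style topic matching
#'
#' Supports the `+` single-level and trailing `#` multi-level wildcards.
#'
#' @param pattern Subscription pattern, e.g. `"device/+/command"`.
#' @param topic Concrete topic.
#' @return Logical.
#' @export
topic_matches <- function(pattern, topic) {
  pl <- strsplit(pattern, "/", fixed = TRUE)[[1]]
  tl <- strsplit(topic, "/", fixed = TRUE)[[1]]
  for (i in seq_along(pl)) {
    if (pl[[i]] == "#") return(TRUE)
    if (i > length(tl)) return(FALSE)
    if (pl[[i]] != "+" && pl[[i]] != tl[[i]]) return(FALSE)
  }
  length(pl) == length(tl)
}

#' Subscribe a handler to a topic pattern
#'
#' @param bus A [loc_bus()].
#' @param pattern Topic pattern (see [topic_matches()]).
#' @param handler Function of one argument (the message).
#' @return The bus, invisibly.
#' @export
bus_subscribe <- function(bus, pattern, handler) {
  bus$subs <- c(bus$subs, list(list(pattern = pattern, handler = handler)))
  invisible(bus)
}

#' Publish a message
#'
#' Assigns a unique `msg_id` and timestamp, appends the message to the bus
#' log, and synchronously dispatches it to every matching subscriber in
#' subscription order (per-topic FIFO follows from synchronous in-order
#' publishing).
#'
#' @param bus A [loc_bus()].
#' @param topic Topic string.
#' @param payload Named list; serialized as JSON in transit.
#' @param ref_id Optional `msg_id` of the command this message answers.
#' @return The published message (class `loc_message`), invisibly.
#' @export
bus_publish <- function(bus, topic, payload, ref_id = NULL) {
  msg <- structure(
    list(msg_id = bus$next_id, topic = topic, payload = payload,
         ref_id = ref_id, timestamp = Sys.time()),
    class = "loc_message"
  )
  bus$next_id <- bus$next_id + 1L
  bus$log <- c(bus$log, list(msg))
  # wire format round trip: handlers see what a JSON transport would deliver
  wire <- jsonlite::parse_json(
    jsonlite::toJSON(msg$payload, auto_unbox = TRUE, digits = NA, null = "null")
  )
  delivered <- msg
  delivered$payload <- wire
  for (sub in bus$subs) {
    if (topic_matches(sub$pattern, topic)) sub$handler(delivered)
  }
  invisible(msg)
}

#' @export
print.loc_message <- function(x, ...) {
  cat(sprintf("<msg #%d %s%s>\n", x$msg_id, x$topic,
              if (is.null(x$ref_id)) "" else sprintf(" (re #%d)", x$ref_id)))
  utils::str(x$payload, max.level = 1, give.attr = FALSE)
  invisible(x)
}

statuses_for <- function(bus, device_id, ref_id) {
  topic <- sprintf("device/%s/status", device_id)
  Filter(function(m) identical(m$topic, topic) && identical(m$ref_id, ref_id),
         bus$log)
}

#' Local script store
#'
#' Named collection of script sources, as kept on the laboratory device for
#' reusable templates (washing, staining, ...). Scripts are re-parsed at store
#' time; unparsable sources are rejected.
#'
#' @param dir Optional directory for persistence; `NULL` keeps the store in
#'   memory only.
#' @return An object of class `loc_script_store`.
#' @export
script_store <- function(dir = NULL) {
  env <- new.env(parent = emptyenv())
  env$scripts <- list()
  env$dir <- dir
  if (!is.null(dir) && dir.exists(dir)) {
    for (f in list.files(dir, pattern = "\\.loc$", full.names = TRUE)) {
      name <- sub("\\.loc$", "", basename(f))
      env$scripts[[name]] <- paste(readLines(f, warn = FALSE), collapse = "\n")
    }
  }
  structure(env, class = "loc_script_store")
}

#' @rdname script_store
#' @param store A `loc_script_store`.
#' @param name Script name (unique within the store).
#' @param source Script source text.
#' @export
store_add <- function(store, name, source) {
  parse_script(source, is_path = FALSE)   # errors on unparsable source
  store$scripts[[name]] <- paste(source, collapse = "\n")
  if (!is.null(store$dir)) {
    if (!dir.exists(store$dir)) dir.create(store$dir, recursive = TRUE)
    writeLines(store$scripts[[name]], file.path(store$dir, paste0(name, ".loc")))
  }
  invisible(store)
}

#' @rdname script_store
#' @export
store_list <- function(store) sort(names(store$scripts))

#' @rdname script_store
#' @export
store_get <- function(store, name) {
  if (!(name %in% names(store$scripts))) stop("no stored script '", name, "'")
  store$scripts[[name]]
}

#' A virtual laboratory device on the bus
#'
#' Subscribes a digital-twin chip to `device/<id>/command` and answers every
#' command on `device/<id>/status`. Command payloads (JSON objects):
#'
#' * `{"type": "valve", "action": "open"|"close", "valve_id": n}`
#' * `{"type": "run", "name": "<stored script>"}`
#' * `{"type": "upload", "name": "<name>", "source": "<script text>"}`
#'
#' @param bus A [loc_bus()].
#' @param device_id Device identifier used in topics.
#' @param topology A [chip_topology()].
#' @param store A [script_store()]; the bundled staining and wash templates
#'   are preloaded by default.
#' @return An object of class `loc_device` holding the device's backend and
#'   store; its chip state is at `device$backend$state`.
#' @export
loc_device <- function(bus, device_id, topology = chip_topology(),
                       store = NULL) {
  if (is.null(store)) {
    store <- script_store()
    for (nm in c("staining", "wash")) {
      src <- paste(readLines(reference_script(nm), warn = FALSE), collapse = "\n")
      store_add(store, nm, src)
    }
  }
  dev <- new.env(parent = emptyenv())
  dev$id <- device_id
  dev$topology <- topology
  dev$backend <- chip_backend(chip_state(topology))
  dev$store <- store
  dev$bus <- bus
  class(dev) <- "loc_device"

  status_topic <- sprintf("device/%s/status", device_id)
  reply <- function(ref_id, payload) bus_publish(bus, status_topic, payload, ref_id)

  handler <- function(msg) {
    p <- msg$payload
    type <- p$type %||% "unknown"
    if (type == "valve") {
      v <- p$valve_id
      if (is.null(v) || !is.numeric(v) || v < 1 || v > topology$n_valves) {
        reply(msg$msg_id, list(status = "rejected",
                               error = sprintf("valve %s outside range 1..%d",
                                               if (is.null(v)) "?" else v,
                                               topology$n_valves)))
        return(invisible())
      }
      v <- as.integer(v)
      open <- identical(p$action, "open")
      was <- dev$backend$state$valve_open[[paste0("V", v)]]
      backend_set_valve(dev$backend, v, open)
      reply(msg$msg_id, list(
        status = "ok", valve_id = v,
        state = if (open) "open" else "closed",
        changed = !identical(was, open)
      ))
    } else if (type == "run") {
      name <- p$name
      if (is.null(name) || !(name %in% names(dev$store$scripts))) {
        reply(msg$msg_id, list(status = "error",
                               error = sprintf("no stored script '%s'", name)))
        return(invisible())
      }
      script <- parse_script(store_get(dev$store, name), is_path = FALSE)
      diags <- validate_script(script, topology)
      if (any(diags$severity == "ERROR")) {
        reply(msg$msg_id, list(status = "error",
                               diagnostics = format_diagnostics(diags, name)))
        return(invisible())
      }
      trace <- tryCatch(
        run_script(script, dev$backend, mode = "virtual"),
        loc_run_error = function(e) e
      )
      if (inherits(trace, "loc_run_error")) {
        partial <- trace$trace
        reply(msg$msg_id, list(status = "failed", error = conditionMessage(trace),
                               n_actuations = nrow(partial$events),
                               total_duration_ms = partial$total_duration_ms))
        return(invisible())
      }
      for (i in seq_len(nrow(trace$events))) {
        ev <- trace$events[i, ]
        reply(msg$msg_id, list(status = "progress", t_ms = ev$t_ms,
                               action = ev$action, valve_id = ev$valve_id))
      }
      reply(msg$msg_id, list(status = "done", name = name,
                             n_actuations = nrow(trace$events),
                             total_duration_ms = trace$total_duration_ms))
    } else if (type == "upload") {
      res <- tryCatch({
        script <- parse_script(p$source, is_path = FALSE)
        diags <- validate_script(script, topology)
        if (any(diags$severity == "ERROR")) {
          list(status = "rejected",
               diagnostics = format_diagnostics(diags, p$name %||% "<upload>"))
        } else {
          store_add(dev$store, p$name, p$source)
          list(status = "stored", name = p$name,
               warnings = format_diagnostics(
                 diags[diags$severity == "WARNING", , drop = FALSE],
                 p$name %||% "<upload>"))
        }
      }, loc_parse_error = function(e) {
        list(status = "rejected",
             diagnostics = format_diagnostics(e$diagnostics, p$name %||% "<upload>"))
      })
      reply(msg$msg_id, res)
    } else {
      reply(msg$msg_id, list(status = "rejected",
                             error = sprintf("unknown command type '%s'", type)))
    }
    invisible()
  }
  bus_subscribe(bus, sprintf("device/%s/command", device_id), handler)
  dev
}

#' @export
print.loc_device <- function(x, ...) {
  cat(sprintf("<loc_device '%s': %d stored script(s)>\n", x$id,
              length(x$store$scripts)))
  invisible(x)
}

command_topic <- function(device_id) sprintf("device/%s/command", device_id)

has_subscriber <- function(bus, topic) {
  any(vapply(bus$subs, function(s) topic_matches(s$pattern, topic), logical(1)))
}

#' Manual mode: actuate a single valve remotely
#'
#' @param bus A [loc_bus()].
#' @param device_id Target device.
#' @param action `"open"` or `"close"`.
#' @param valve_id Valve number.
#' @return The final status message (class `loc_message`); payload `status`
#'   is `"ok"`, `"rejected"`, or `"timeout"` if no device answers on the bus.
#' @export
manual_valve_command <- function(bus, device_id, action = c("open", "close"),
                                 valve_id) {
  action <- match.arg(action)
  topic <- command_topic(device_id)
  if (!has_subscriber(bus, topic)) {
    return(bus_publish(bus, sprintf("device/%s/status", device_id),
                       list(status = "timeout",
                            error = sprintf("no device '%s' on bus", device_id))))
  }
  cmd <- bus_publish(bus, topic,
                     list(type = "valve", action = action, valve_id = valve_id))
  st <- statuses_for(bus, device_id, cmd$msg_id)
  st[[length(st)]]
}

#' Saved-script mode: run a stored template remotely
#'
#' @inheritParams manual_valve_command
#' @param name Name of a script in the device's store.
#' @return All status messages answering the command, ending in a completion
#'   (`status = "done"`) or error report.
#' @export
run_saved_script <- function(bus, device_id, name) {
  topic <- command_topic(device_id)
  if (!has_subscriber(bus, topic)) {
    return(list(bus_publish(bus, sprintf("device/%s/status", device_id),
                            list(status = "timeout",
                                 error = sprintf("no device '%s' on bus",
                                                 device_id)))))
  }
  cmd <- bus_publish(bus, topic, list(type = "run", name = name))
  statuses_for(bus, device_id, cmd$msg_id)
}

#' Upload mode: store a new script on the device
#'
#' The source is parsed and validated on the device before storage; rejected
#' uploads carry the full diagnostics, which is the feedback path for remotely
#' submitted scripts.
#'
#' @inheritParams run_saved_script
#' @param source Script source text (single string or lines).
#' @return The status message (`status` `"stored"` or `"rejected"`).
#' @export
upload_script <- function(bus, device_id, name, source) {
  topic <- command_topic(device_id)
  if (!has_subscriber(bus, topic)) {
    return(bus_publish(bus, sprintf("device/%s/status", device_id),
                       list(status = "timeout",
                            error = sprintf("no device '%s' on bus", device_id))))
  }
  cmd <- bus_publish(bus, topic,
                     list(type = "upload", name = name,
                          source = paste(source, collapse = "\n")))
  st <- statuses_for(bus, device_id, cmd$msg_id)
  st[[length(st)]]
}
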