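#' Sample-preparation protocol configuration
#'
#' A protocol bundles the inlet loads (reservoir, reagent, volume in
#' microliters) and the incubation time a staining script is expected to
#' schedule. The bundled default is the reference bacterial staining protocol:
#' 2 uL *E. coli* suspension in 1X PBS on R1, 2 uL 1X SYBR Gold on R2, 5 uL
#' 1X PBS buffer on R3 — three inlets loaded — with a 20-minute incubation.
#'
#' @param config Path to a YAML protocol file; `NULL` loads the bundled
#'   default.
#' @return An object of class `protocol_config`: `inlet_loads` (data frame
#'   `reservoir`/`reagent`/`volume_ul`), `incubation_ms`, `script` (name of
#'   the companion script file, if any).
#' @examples
#' p <- protocol_config()
#' p$incubation_ms / 60000   # minutes
#' @export
protocol_config <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "default_protocol.yaml", package = "lochip")
  cfg <- yaml::read_yaml(config)
  loads <- do.call(rbind, lapply(cfg$inlet_loads, function(l) {
    data.frame(reservoir = l$reservoir, reagent = l$reagent,
               volume_ul = as.numeric(l$volume_ul), stringsAsFactors = FALSE)
  }))
  structure(
    list(inlet_loads = loads, incubation_ms = as.numeric(cfg$incubation_ms),
         script = cfg$script %||% NULL),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol: %d inlet load(s), %.0f min incubation>\n",
              nrow(x$inlet_loads), x$incubation_ms / 60000))
  print(x$inlet_loads)
  invisible(x)
}

#' Path to a bundled reference script
#'
#' @param name `"staining"` (reference staining protocol) or `"wash"`
#'   (post-experiment flush).
#' @return File path inside the installed package.
#' @export
reference_script <- function(name = c("staining", "wash")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".loc"), package = "lochip")
}

#' Run a script as a full sample-preparation protocol on the digital twin
#'
#' Applies the protocol's inlet loads to a fresh [chip_state()], then executes
#' the script through the interpreter with the virtual chip as backend, and
#' reports the parcel delivered to the detection node.
#'
#' @param script A [loc_script()] or a path to script source.
#' @param topology A [chip_topology()].
#' @param protocol A [protocol_config()].
#' @return A list of class `loc_protocol_run`: `state` (final `chip_state`),
#'   `trace` (`loc_trace`), `delivered` (cumulative parcel that reached the
#'   detection node, per-reagent nL).
#' @examples
#' run <- run_protocol(parse_script(reference_script()))
#' parcel_composition(run$delivered)
#' @export
run_protocol <- function(script, topology = chip_topology(),
                         protocol = protocol_config()) {
  if (is.character(script)) script <- parse_script(script)
  diags <- validate_script(script, topology)
  if (any(diags$severity == "ERROR"))
    stop("script fails validation:\n",
         paste(format_diagnostics(diags), collapse = "\n"))
  state <- chip_state(topology)
  for (i in seq_len(nrow(protocol$inlet_loads))) {
    ld <- protocol$inlet_loads[i, ]
    state <- load_inlet(state, ld$reservoir, ld$reagent,
                        volume_nl = ld$volume_ul * 1000)
  }
  backend <- chip_backend(state)
  trace <- run_script(script, backend, mode = "virtual")
  structure(
    list(state = backend$state, trace = trace,
         delivered = backend$state$delivered),
    class = "loc_protocol_run"
  )
}

#' @export
print.loc_protocol_run <- function(x, ...) {
  cat(sprintf("<protocol run: %d actuations over %s ms>\n",
              nrow(x$trace$events),
              format(x$trace$total_duration_ms, big.mark = ",")))
  v <- parcel_volume(x$delivered)
  if (v > 0) {
    cat(sprintf("delivered to %s: %.2f nL\n", x$state$topology$detection_node, v))
    comp <- parcel_composition(x$delivered)
    for (r in names(comp)) cat(sprintf("  %-10s %.3f\n", r, comp[[r]]))
  } else {
    cat("nothing delivered to the detection node\n")
  }
  invisible(x)
}
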