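#' @title Digital twin of the lifting-gate optofluidic chip
#' @description
#' The physical device is a PDMS chip with pneumatically actuated
#' "lifting-gate" valves: negative pressure lifts the membrane, opening a
#' fluidic exchange volume between adjacent channels; positive pressure closes
#' the valve and expels its contained liquid towards adjacent open valves.
#' The twin models this as a graph state machine over discrete fluid parcels —
#' no pressure/flow physics, channel geometry or diffusion — which conserves
#' mass exactly and captures the routing/mixing semantics a control script
#' exercises:
#'
#' * **open**: the valve becomes available; it draws fluid from adjacent inlet
#'   reservoirs up to its internal capacity, and receives expelled parcels.
#' * **close**: its parcel is expelled and split **equally by volume** among
#'   adjacent open nodes (open valves, plus reservoirs, which always accept);
#'   merging parcels combine volume-additively with volume-weighted
#'   composition averaging. Closing with no open neighbor traps the parcel in
#'   an audit field (real devices would backpressure) and records a warning.
#'
#' Volumes are tracked in nanoliters. Parcels are represented internally as
#' named per-reagent volume vectors, so per-reagent conservation is a sum
#' identity rather than a numerical approximation.
#' @name virtual_chip
NULL

# ---- fluid parcels -----------------------------------------------------------

#' Fluid parcel helpers
#'
#' A parcel is a named numeric vector of per-reagent volumes in nanoliters;
#' its total volume is `sum(parcel)` and its composition the normalized
#' fractions.
#'
#' @param ... Named per-reagent volumes in nL, e.g. `parcel(dye = 5, pbs = 5)`.
#' @param p,p1,p2 Parcels.
#' @return `parcel()` a parcel; `parcel_volume()` total nL;
#'   `parcel_composition()` named fractions summing to 1 (empty for an empty
#'   parcel); `merge_parcels()` the volume-additive union.
#' @export
parcel <- function(...) {
  x <- c(...)
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  stopifnot(!is.null(names(x)), all(x >= 0))
  x[x > 0]
}

#' @rdname parcel
#' @export
parcel_volume <- function(p) sum(p)

#' @rdname parcel
#' @export
parcel_composition <- function(p) {
  v <- sum(p)
  if (v <= 0) return(stats::setNames(numeric(0), character(0)))
  p / v
}

#' @rdname parcel
#' @export
merge_parcels <- function(p1, p2) {
  keys <- union(names(p1), names(p2))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(p1)] <- out[names(p1)] + p1
  out[names(p2)] <- out[names(p2)] + p2
  out[out > 0]
}

# ---- topology ----------------------------------------------------------------

#' Chip topology: valve/reservoir graph
#'
#' Builds the node graph of the device: pneumatic valves `V1..Vn`, fluidic
#' reservoirs with `INLET`/`OUTLET` roles, undirected adjacency edges, and the
#' designated detection node (the valve feeding the optical detection channel,
#' where the excitation waveguide crosses the analyte channel).
#'
#' With no arguments the bundled default topology is loaded: 15 valves and 6
#' reservoirs arranged as a serial mixing chain — three inlet reservoirs
#' (R1–R3) feed inlet valves V1–V3, which converge on central mixing valves
#' V4–V6; a transport chain V7–V13 leads to the detection valve V14 and an
#' output valve V15 adjacent to three outlet reservoirs R4–R6. The exact
#' adjacency of the physical chip is not published; this is a schematic
#' stand-in with the same node counts and roles, and alternate architectures
#' are drop-in via the YAML config.
#'
#' @param config Path to a YAML topology file; `NULL` loads the bundled
#'   default (`system.file("extdata", "default_topology.yaml")`).
#' @return An object of class `chip_topology`: `n_valves`, `valves` (node
#'   ids `"V1"...`), `reservoirs` (named character of roles), `edges` (2-column
#'   character matrix), `neighbors` (named list), `detection_node`,
#'   `valve_capacity_nl`.
#' @examples
#' topo <- chip_topology()
#' topo$n_valves
#' @export
chip_topology <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "default_topology.yaml", package = "lochip")
  cfg <- yaml::read_yaml(config)
  n_valves <- as.integer(cfg$n_valves)
  valves <- paste0("V", seq_len(n_valves))
  reservoirs <- vapply(cfg$reservoirs, identity, character(1))
  stopifnot(all(reservoirs %in% c("INLET", "OUTLET")))
  edges <- do.call(rbind, lapply(cfg$edges, function(e) c(e[[1]], e[[2]])))
  nodes <- c(valves, names(reservoirs))
  if (!all(edges %in% nodes))
    stop("topology edge references unknown node: ",
         paste(setdiff(unique(c(edges)), nodes), collapse = ", "))
  detection_node <- cfg$detection_node
  stopifnot(detection_node %in% valves)

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  missing_nodes <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing_nodes) > 0) g <- g + igraph::vertices(missing_nodes)
  if (!igraph::is_connected(g)) stop("topology graph is not connected")
  inlets <- names(reservoirs)[reservoirs == "INLET"]
  d <- igraph::distances(g, v = inlets, to = detection_node)
  if (any(!is.finite(d)))
    stop("detection node unreachable from inlet(s): ",
         paste(inlets[!is.finite(d[, 1])], collapse = ", "))

  nb <- lapply(stats::setNames(nodes, nodes), function(nd) {
    sort(unique(c(edges[edges[, 1] == nd, 2], edges[edges[, 2] == nd, 1])))
  })
  structure(
    list(n_valves = n_valves, valves = valves, reservoirs = reservoirs,
         edges = edges, neighbors = nb, detection_node = detection_node,
         valve_capacity_nl = as.numeric(cfg$valve_capacity_nl %||% 10)),
    class = "chip_topology"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chip_topology <- function(x, ...) {
  cat(sprintf(
    "<chip_topology: %d valves, %d reservoirs (%d inlet / %d outlet), detection at %s>\n",
    x$n_valves, length(x$reservoirs), sum(x$reservoirs == "INLET"),
    sum(x$reservoirs == "OUTLET"), x$detection_node))
  invisible(x)
}

valve_node <- function(topology, valve) {
  if (is.character(valve)) {
    if (!(valve %in% topology$valves)) stop("unknown valve '", valve, "'")
    return(valve)
  }
  v <- as.integer(valve)
  if (is.na(v) || v < 1 || v > topology$n_valves)
    stop(sprintf("valve %s outside range 1..%d", valve, topology$n_valves))
  paste0("V", v)
}

# ---- chip state --------------------------------------------------------------

#' Initial state of a chip
#'
#' All valves closed, all nodes empty, empty ledgers.
#'
#' @param topology A [chip_topology()].
#' @return An object of class `chip_state`: `valve_open` (named logical),
#'   `contents` (named list of parcels per node, reservoirs included),
#'   `ledger` (per-reservoir `loaded`/`inflow`/`outflow` per-reagent nL),
#'   `delivered` (cumulative parcel that entered the detection node),
#'   `trapped` (list of parcels expelled with no open neighbor), `audit`
#'   (data frame of recorded warnings), `t_ms` (virtual clock).
#' @export
chip_state <- function(topology = chip_topology()) {
  nodes <- c(topology$valves, names(topology$reservoirs))
  empty <- parcel()
  structure(
    list(
      topology = topology,
      valve_open = stats::setNames(rep(FALSE, topology$n_valves), topology$valves),
      contents = lapply(stats::setNames(nodes, nodes), function(n) empty),
      ledger = lapply(stats::setNames(names(topology$reservoirs),
                                      names(topology$reservoirs)),
                      function(r) list(loaded = empty, inflow = empty,
                                       outflow = empty)),
      delivered = empty,
      trapped = list(),
      audit = data.frame(code = character(), node = character(),
                         message = character(), stringsAsFactors = FALSE),
      t_ms = 0
    ),
    class = "chip_state"
  )
}

#' @export
print.chip_state <- function(x, ...) {
  n_open <- sum(x$valve_open)
  vol_on_chip <- sum(vapply(x$contents[x$topology$valves], sum, numeric(1)))
  cat(sprintf("<chip_state @ %s ms: %d/%d valves open, %.2f nL on valves, %.2f nL delivered>\n",
              format(x$t_ms, big.mark = ","), n_open, x$topology$n_valves,
              vol_on_chip, sum(x$delivered)))
  invisible(x)
}

audit_add <- function(state, code, node, message) {
  state$audit <- rbind(state$audit,
                       data.frame(code = code, node = node, message = message,
                                  stringsAsFactors = FALSE))
  state
}

#' Load a reagent onto an inlet reservoir
#'
#' Credits the reservoir's ledger and makes the fluid available for draw into
#' adjacent valves on subsequent open actuations. Sequential loads accumulate.
#'
#' @param state A [chip_state()].
#' @param reservoir Reservoir id, e.g. `"R1"`; must have the `INLET` role.
#' @param reagent Reagent name.
#' @param volume_nl Volume in nanoliters; must be positive.
#' @return The updated `chip_state`.
#' @export
load_inlet <- function(state, reservoir, reagent, volume_nl) {
  topo <- state$topology
  if (!(reservoir %in% names(topo$reservoirs)))
    stop("unknown reservoir '", reservoir, "'")
  if (topo$reservoirs[[reservoir]] != "INLET")
    stop("reservoir '", reservoir, "' is not an INLET")
  if (!is.numeric(volume_nl) || volume_nl <= 0)
    stop("load volume must be positive")
  add <- parcel(stats::setNames(volume_nl, reagent))
  state$contents[[reservoir]] <- merge_parcels(state$contents[[reservoir]], add)
  state$ledger[[reservoir]]$loaded <-
    merge_parcels(state$ledger[[reservoir]]$loaded, add)
  state
}

# deposit a parcel into a node, updating delivery/ledger bookkeeping
deposit <- function(state, node, p) {
  if (sum(p) <= 0) return(state)
  topo <- state$topology
  state$contents[[node]] <- merge_parcels(state$contents[[node]], p)
  if (node %in% names(topo$reservoirs)) {
    state$ledger[[node]]$inflow <- merge_parcels(state$ledger[[node]]$inflow, p)
  } else {
    if (node == topo$detection_node)
      state$delivered <- merge_parcels(state$delivered, p)
    if (sum(state$contents[[node]]) > topo$valve_capacity_nl + 1e-12) {
      state <- audit_add(state, "W_CAPACITY", node,
        sprintf("%s holds %.3f nL, above capacity %.3f nL", node,
                sum(state$contents[[node]]), topo$valve_capacity_nl))
    }
  }
  state
}

#' Open a valve (lift the gate)
#'
#' Marks the valve open and draws fluid from adjacent inlet reservoirs, up to
#' the valve's remaining internal capacity (default 10 nL), in lexicographic
#' reservoir order. Opening an already-open valve is a no-op.
#'
#' @param state A [chip_state()].
#' @param valve Valve number (1-based integer) or node id (`"V3"`).
#' @return The updated `chip_state`.
#' @export
open_valve <- function(state, valve) {
  topo <- state$topology
  node <- valve_node(topo, valve)
  if (state$valve_open[[node]]) return(state)   # idempotent
  state$valve_open[[node]] <- TRUE
  capacity_left <- topo$valve_capacity_nl - sum(state$contents[[node]])
  for (nb in topo$neighbors[[node]]) {
    if (capacity_left <= 0) break
    if (!(nb %in% names(topo$reservoirs))) next
    if (topo$reservoirs[[nb]] != "INLET") next
    avail <- sum(state$contents[[nb]])
    if (avail <= 0) next
    take_frac <- min(1, capacity_left / avail)
    draw <- state$contents[[nb]] * take_frac
    state$contents[[nb]] <- (state$contents[[nb]] - draw)
    state$contents[[nb]] <- state$contents[[nb]][state$contents[[nb]] > 0]
    state$ledger[[nb]]$outflow <- merge_parcels(state$ledger[[nb]]$outflow, draw)
    state <- deposit(state, node, draw)
    capacity_left <- topo$valve_capacity_nl - sum(state$contents[[node]])
  }
  state
}

#' Close a valve (press the gate)
#'
#' Marks the valve closed and expels its parcel, partitioned equally by volume
#' among adjacent open nodes: open valves and reservoirs (reservoirs always
#' accept — expelling towards an inlet pushes fluid back up it). Composition
#' travels with each partition. Closing an empty valve is a no-op; closing a
#' loaded valve with no open neighbor traps the parcel in `state$trapped`
#' (conservation-preserving) and records a `W_TRAPPED` audit warning.
#'
#' @inheritParams open_valve
#' @return The updated `chip_state`.
#' @export
close_valve <- function(state, valve) {
  topo <- state$topology
  node <- valve_node(topo, valve)
  state$valve_open[[node]] <- FALSE
  p <- state$contents[[node]]
  if (sum(p) <= 0) return(state)
  recipients <- Filter(function(nb) {
    nb %in% names(topo$reservoirs) || state$valve_open[[nb]]
  }, topo$neighbors[[node]])
  state$contents[[node]] <- parcel()
  if (length(recipients) == 0) {
    state$trapped <- c(state$trapped, list(list(node = node, parcel = p)))
    return(audit_add(state, "W_TRAPPED", node,
                     sprintf("%.3f nL expelled from %s with no open neighbor",
                             sum(p), node)))
  }
  share <- p / length(recipients)
  for (nb in recipients) state <- deposit(state, nb, share)
  state
}

#' Per-reagent mass balance of a chip state
#'
#' For every reagent ever loaded, compares the loaded total against what the
#' state can account for: fluid sitting on valve nodes, fluid in reservoirs
#' (both unloaded remainder and returned outflow), and trapped parcels.
#'
#' @param state A [chip_state()].
#' @return A data frame with columns `reagent`, `loaded_nl`, `accounted_nl`,
#'   `rel_error` (|loaded - accounted| / loaded).
#' @export
mass_balance <- function(state) {
  loaded <- parcel()
  for (r in names(state$ledger))
    loaded <- merge_parcels(loaded, state$ledger[[r]]$loaded)
  accounted <- parcel()
  for (node in names(state$contents))
    accounted <- merge_parcels(accounted, state$contents[[node]])
  for (tr in state$trapped)
    accounted <- merge_parcels(accounted, tr$parcel)
  reagents <- sort(names(loaded))
  acc <- vapply(reagents, function(r) {
    if (r %in% names(accounted)) accounted[[r]] else 0
  }, numeric(1))
  data.frame(
    reagent = reagents,
    loaded_nl = as.numeric(loaded[reagents]),
    accounted_nl = as.numeric(acc),
    rel_error = abs(as.numeric(loaded[reagents]) - as.numeric(acc)) /
      as.numeric(loaded[reagents]),
    stringsAsFactors = FALSE
  )
}

# ---- backend adapter ---------------------------------------------------------

#' Use a virtual chip as an interpreter backend
#'
#' Wraps a [chip_state()] in a mutable handle implementing the
#' [device_backend] contract, so [run_script()] can drive the digital twin.
#'
#' @param state A [chip_state()]; defaults to a fresh state on the default
#'   topology.
#' @return An object of class `loc_chip_backend`; the evolving state is
#'   available as `backend$state`.
#' @export
chip_backend <- function(state = chip_state()) {
  env <- new.env(parent = emptyenv())
  env$state <- state
  structure(env, class = "loc_chip_backend")
}

#' @export
backend_set_valve.loc_chip_backend <- function(backend, valve_id, open) {
  backend$state <- if (open) open_valve(backend$state, valve_id)
                   else close_valve(backend$state, valve_id)
  invisible(backend)
}

#' @export
backend_advance_time.loc_chip_backend <- function(backend, ms) {
  backend$state$t_ms <- backend$state$t_ms + ms
  invisible(backend)
}

#' @export
backend_n_valves.loc_chip_backend <- function(backend) {
  backend$state$topology$n_valves
}

# ---- state snapshots ---------------------------------------------------------

#' Snapshot a chip state to JSON and back
#'
#' Serializes everything except the topology (which is reloaded from its
#' config); used by the command-line interface to persist manual-mode state
#' between invocations.
#'
#' @param state A [chip_state()].
#' @param path JSON file path.
#' @param topology Topology to attach on restore.
#' @return `write_chip_state()` returns `path` invisibly;
#'   `read_chip_state()` a `chip_state`.
#' @export
write_chip_state <- function(state, path) {
  snap <- list(
    valve_open = as.list(state$valve_open),
    contents = lapply(state$contents, as.list),
    ledger = lapply(state$ledger, function(l) lapply(l, as.list)),
    delivered = as.list(state$delivered),
    trapped = lapply(state$trapped,
                     function(tr) list(node = tr$node, parcel = as.list(tr$parcel))),
    audit = state$audit,
    t_ms = state$t_ms
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chip_state
#' @export
read_chip_state <- function(path, topology = chip_topology()) {
  snap <- jsonlite::read_json(path, simplifyVector = FALSE)
  state <- chip_state(topology)
  as_parcel <- function(l) parcel(unlist(l) %||% numeric(0))
  state$valve_open[names(snap$valve_open)] <- unlist(snap$valve_open)
  for (node in names(snap$contents))
    state$contents[[node]] <- as_parcel(snap$contents[[node]])
  for (r in names(snap$ledger))
    state$ledger[[r]] <- lapply(snap$ledger[[r]], as_parcel)
  state$delivered <- as_parcel(snap$delivered)
  state$trapped <- lapply(snap$trapped, function(tr)
    list(node = tr$node, parcel = as_parcel(tr$parcel)))
  state$audit <- if (length(snap$audit) == 0) state$audit else
    do.call(rbind, lapply(snap$audit, as.data.frame))
  state$t_ms <- snap$t_ms
  state
}
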