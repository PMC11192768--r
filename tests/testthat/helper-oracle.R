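# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the executor interprets calls lazily with
# no pre-expansion, and the tallies are brute-force loops.

# Naive line-by-line executor: returns the ordered (action, valve) sequence
# and the summed wait time for a script, by direct recursive interpretation.
naive_execute <- function(script) {
  actions <- character(0)
  valves <- integer(0)
  wait_total <- 0
  walk <- function(body) {
    for (ins in body) {
      if (ins$kind == "OPEN") {
        actions <<- c(actions, "OPEN"); valves <<- c(valves, ins$valve_id)
      } else if (ins$kind == "CLOSE") {
        actions <<- c(actions, "CLOSE"); valves <<- c(valves, ins$valve_id)
      } else if (ins$kind == "WAIT") {
        wait_total <<- wait_total + ins$duration_ms
      } else if (ins$kind == "CALL") {
        walk(script$functions[[ins$function_name]])
      }
    }
  }
  walk(script$main)
  list(actions = actions, valves = valves, wait_total = wait_total)
}

# Brute-force recursive call expander (kinds only), for expand_calls checks.
naive_expand_kinds <- function(script) {
  out <- list()
  walk <- function(body) {
    for (ins in body) {
      if (ins$kind == "CALL") walk(script$functions[[ins$function_name]])
      else out[[length(out) + 1]] <<- ins
    }
  }
  walk(script$main)
  out
}

# Random open/close/wait actuation sequence applied functionally to a chip
# state; returns the final state. Used for conservation fuzzing.
random_actuations <- function(state, n_ops = 40) {
  n_valves <- state$topology$n_valves
  for (i in seq_len(n_ops)) {
    v <- sample.int(n_valves, 1)
    if (stats::runif(1) < 0.5) state <- open_valve(state, v)
    else state <- close_valve(state, v)
  }
  state
}

# Fresh default-topology state with the reference loads applied.
loaded_state <- function() {
  st <- chip_state(chip_topology())
  st <- load_inlet(st, "R1", "ecoli_pbs", 2000)
  st <- load_inlet(st, "R2", "sybr_gold", 2000)
  st <- load_inlet(st, "R3", "pbs", 5000)
  st
}
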