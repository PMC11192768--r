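#' @title Valve-control scripting language
#' @description
#' The chip is driven by a deliberately minimal scripting language: three
#' single-character commands — `o <valve>` opens a valve, `c <valve>` closes a
#' valve, `w <milliseconds>` waits — plus `call <name>` to invoke a user-defined
#' function. A script has a `main:` block followed (after `end`) by any number
#' of `def <name>:` blocks; `#` starts a comment. Valves are numbered from 1.
#'
#' ```
#' main:
#'   o 1
#'   w 500
#'   call wash
#' end
#'
#' def wash:
#'   c 1
#' end
#' ```
#'
#' Grammar (EBNF):
#' ```
#' script    = { blank | comment } , main_block , { func_block } ;
#' main_block= "main:" , { line } , "end" ;
#' func_block= "def" , name , ":" , { line } , "end" ;
#' line      = instr | blank | comment ;
#' instr     = ("o" | "c") , integer
#'           | "w" , nonneg_integer
#'           | "call" , name ;
#' ```
#' There are no variables, arithmetic, loops or conditionals, and `call`
#' recursion (direct or mutual) is forbidden.
#' @name script_dsl
NULL

#' Diagnostic codes emitted by the parser and validator
#'
#' The closed set of machine-readable codes attached to [parse_script()]
#' failures and [validate_script()] results.
#'
#' @format A named character vector mapping code to a one-line description.
#' @export
LOC_DIAGNOSTIC_CODES <- c(
  E_SYNTAX         = "malformed line: unknown command, bad parameter or block structure",
  E_DUP_FUNC       = "function defined more than once",
  E_DEF_BEFORE_MAIN = "function definition precedes the main block",
  E_NO_MAIN        = "script has no main block",
  E_EMPTY_MAIN     = "main block contains no instructions",
  E_VALVE_RANGE    = "valve id outside the topology's valve range",
  E_UNDEF_FUNC     = "call target has no definition",
  E_RECURSION      = "call graph contains a cycle",
  W_UNUSED_FUNC    = "function defined but never called"
)

new_diagnostic <- function(severity, line_no, code, message) {
  data.frame(
    severity = severity, line_no = as.integer(line_no),
    code = code, message = message, stringsAsFactors = FALSE
  )
}

empty_diagnostics <- function() {
  new_diagnostic(character(), integer(), character(), character())
}

#' Construct a single script instruction
#'
#' Low-level constructors used when building a [loc_script()] programmatically;
#' `parse_script()` produces the same objects from text.
#'
#' @param valve_id Integer valve number (1-based).
#' @param duration_ms Non-negative integer wait, in milliseconds.
#' @param name Function name (identifier: letters, digits, `_`, not starting
#'   with a digit).
#' @param line_no Optional 1-based source line for diagnostics.
#' @return A list of class `loc_instruction` with fields `kind` (one of
#'   `"OPEN"`, `"CLOSE"`, `"WAIT"`, `"CALL"`) and exactly one of `valve_id`,
#'   `duration_ms`, `function_name`.
#' @export
op_open <- function(valve_id, line_no = NA_integer_) {
  new_instruction("OPEN", valve_id = valve_id, line_no = line_no)
}

#' @rdname op_open
#' @export
op_close <- function(valve_id, line_no = NA_integer_) {
  new_instruction("CLOSE", valve_id = valve_id, line_no = line_no)
}

#' @rdname op_open
#' @export
op_wait <- function(duration_ms, line_no = NA_integer_) {
  new_instruction("WAIT", duration_ms = duration_ms, line_no = line_no)
}

#' @rdname op_open
#' @export
op_call <- function(name, line_no = NA_integer_) {
  new_instruction("CALL", function_name = name, line_no = line_no)
}

new_instruction <- function(kind, valve_id = NULL, duration_ms = NULL,
                            function_name = NULL, line_no = NA_integer_) {
  kind <- match.arg(kind, c("OPEN", "CLOSE", "WAIT", "CALL"))
  if (kind %in% c("OPEN", "CLOSE")) {
    stopifnot(length(valve_id) == 1, valve_id == as.integer(valve_id))
    valve_id <- as.integer(valve_id)
  }
  if (kind == "WAIT") {
    stopifnot(length(duration_ms) == 1, duration_ms >= 0,
              duration_ms == as.integer(duration_ms))
    duration_ms <- as.integer(duration_ms)
  }
  if (kind == "CALL") {
    stopifnot(is.character(function_name), length(function_name) == 1)
  }
  structure(
    list(kind = kind, valve_id = valve_id, duration_ms = duration_ms,
         function_name = function_name, line_no = as.integer(line_no)),
    class = "loc_instruction"
  )
}

#' @export
format.loc_instruction <- function(x, ...) {
  switch(x$kind,
    OPEN  = paste("o", x$valve_id),
    CLOSE = paste("c", x$valve_id),
    WAIT  = paste("w", x$duration_ms),
    CALL  = paste("call", x$function_name)
  )
}

#' @export
print.loc_instruction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Construct a script object
#'
#' @param main List of [op_open()]-style instructions forming the main block.
#' @param functions Named list; each element is a list of instructions forming
#'   a user-defined function body.
#' @param source_path Optional provenance string.
#' @return An object of class `loc_script`.
#' @seealso [parse_script()], [serialize_script()], [validate_script()]
#' @export
loc_script <- function(main = list(), functions = list(), source_path = NULL) {
  stopifnot(is.list(main), is.list(functions))
  if (length(functions) > 0 && is.null(names(functions)))
    stop("`functions` must be a named list")
  structure(
    list(main = main, functions = functions, source_path = source_path),
    class = "loc_script"
  )
}

#' @export
print.loc_script <- function(x, ...) {
  cat(sprintf("<loc_script: %d main instruction(s), %d function(s)%s>\n",
              length(x$main), length(x$functions),
              if (is.null(x$source_path)) "" else paste0(", ", x$source_path)))
  invisible(x)
}

is_identifier <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

strip_comment <- function(line) sub("#.*$", "", line)

#' Parse valve-control script text
#'
#' Tokenizes and parses script source into a [loc_script()]. Every source line
#' is classified as an instruction, a block delimiter (`main:`, `def name:`,
#' `end`), a comment or a blank line; anything else is a syntax error. Parsing
#' stops at the first error, which is signalled as a condition of class
#' `loc_parse_error` carrying a one-row `diagnostics` data frame
#' (severity, line_no, code, message).
#'
#' @param source Either a single string (possibly with embedded newlines), a
#'   character vector of lines, or a file path (see `is_path`).
#' @param is_path If `TRUE`, `source` is read from file with [readLines()].
#'   Defaults to auto-detection: a single-element string without newlines that
#'   names an existing file is treated as a path.
#' @return A [loc_script()] preserving source order; `call` targets are
#'   recorded verbatim and only resolved by [validate_script()].
#' @examples
#' s <- parse_script(c("main:", "o 3", "w 500", "c 3", "end"))
#' length(s$main)
#' @export
parse_script <- function(source, is_path = NULL) {
  if (is.null(is_path)) {
    is_path <- length(source) == 1 && !grepl("\n", source) && file.exists(source)
  }
  src_path <- NULL
  if (is_path) {
    src_path <- source
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (length(source) > 1) lines <- unlist(strsplit(paste(source, collapse = "\n"),
                                                     "\n", fixed = TRUE))
  }
  if (length(lines) == 0) lines <- character()

  fail <- function(line_no, msg, code = "E_SYNTAX") {
    d <- new_diagnostic("ERROR", line_no, code, msg)
    cond <- structure(
      class = c("loc_parse_error", "error", "condition"),
      list(message = sprintf("line %d: %s", line_no, msg),
           call = sys.call(-1), diagnostics = d)
    )
    stop(cond)
  }

  main <- NULL                  # NULL until "main:" seen; list afterwards
  funcs <- list()
  block <- NULL                 # NULL | "main" | function name
  body <- list()
  seen_main_end <- FALSE

  for (i in seq_along(lines)) {
    raw <- strip_comment(lines[[i]])
    line <- trimws(raw)
    if (line == "") next

    if (grepl("^main:$", line)) {
      if (!is.null(block)) fail(i, "'main:' inside another block")
      if (!is.null(main)) fail(i, "duplicate 'main:' block")
      block <- "main"
      body <- list()
      next
    }
    if (grepl("^def\\b", line)) {
      if (!is.null(block)) fail(i, "'def' inside another block")
      m <- regmatches(line, regexec("^def[ \t]+([A-Za-z_][A-Za-z0-9_]*):$", line))[[1]]
      if (length(m) != 2)
        fail(i, sprintf("malformed function definition: '%s'", line))
      name <- m[[2]]
      if (is.null(main) || !seen_main_end)
        fail(i, sprintf("function '%s' defined before the main block", name),
             "E_DEF_BEFORE_MAIN")
      if (name %in% names(funcs))
        fail(i, sprintf("function '%s' defined more than once", name), "E_DUP_FUNC")
      block <- name
      body <- list()
      next
    }
    if (line == "end") {
      if (is.null(block)) fail(i, "'end' outside any block")
      if (identical(block, "main")) {
        main <- body
        seen_main_end <- TRUE
      } else {
        funcs[[block]] <- body
      }
      block <- NULL
      body <- list()
      next
    }

    # instruction line
    if (is.null(block)) fail(i, sprintf("instruction outside any block: '%s'", line))
    toks <- strsplit(line, "[ \t]+")[[1]]
    cmd <- toks[[1]]
    arg <- if (length(toks) >= 2) toks[[2]] else NA_character_
    if (length(toks) > 2)
      fail(i, sprintf("extra tokens after '%s %s'", cmd, arg))
    ins <- switch(cmd,
      o = , c = {
        if (is.na(arg) || !grepl("^-?[0-9]+$", arg))
          fail(i, sprintf("'%s' needs an integer valve number", cmd))
        if (cmd == "o") op_open(as.integer(arg), i) else op_close(as.integer(arg), i)
      },
      w = {
        if (is.na(arg) || !grepl("^[0-9]+$", arg))
          fail(i, "'w' needs a non-negative integer wait in milliseconds")
        op_wait(as.integer(arg), i)
      },
      call = {
        if (is.na(arg) || !is_identifier(arg))
          fail(i, "'call' needs a function name")
        op_call(arg, i)
      },
      fail(i, sprintf("unknown command '%s'", cmd))
    )
    body <- c(body, list(ins))
  }

  if (!is.null(block))
    fail(length(lines), sprintf("unterminated block '%s' (missing 'end')", block))
  if (is.null(main))
    fail(max(1L, length(lines)), "script has no 'main:' block", "E_NO_MAIN")

  loc_script(main = main, functions = funcs, source_path = src_path)
}

#' Statically validate a script against a chip topology
#'
#' Checks performed:
#' * every `o`/`c` valve id lies in `1..topology$n_valves` (`E_VALVE_RANGE`);
#' * every `call` target is defined (`E_UNDEF_FUNC`);
#' * the call graph is acyclic — no direct or mutual recursion (`E_RECURSION`);
#' * defined-but-never-called functions are flagged (`W_UNUSED_FUNC`);
#' * an empty main block is flagged (`E_EMPTY_MAIN`).
#'
#' An empty result means the script is runnable: interpretation can no longer
#' fail for script-structural reasons.
#'
#' @param script A [loc_script()].
#' @param topology A [chip_topology()]; supplies the legal valve range.
#' @return A data frame of diagnostics (columns severity, line_no, code,
#'   message), zero rows if the script is clean.
#' @export
validate_script <- function(script, topology = chip_topology()) {
  stopifnot(inherits(script, "loc_script"))
  diags <- empty_diagnostics()
  add <- function(severity, line_no, code, message) {
    diags <<- rbind(diags, new_diagnostic(severity, line_no, code, message))
  }

  if (length(script$main) == 0)
    add("ERROR", 1L, "E_EMPTY_MAIN", "main block contains no instructions")

  n_valves <- topology$n_valves
  blocks <- c(list(main = script$main), script$functions)
  for (bi in seq_along(blocks)) {
    for (ins in blocks[[bi]]) {
      ln <- if (is.na(ins$line_no)) 1L else ins$line_no
      if (ins$kind %in% c("OPEN", "CLOSE") &&
          (ins$valve_id < 1 || ins$valve_id > n_valves)) {
        add("ERROR", ln, "E_VALVE_RANGE",
            sprintf("valve %d outside range 1..%d", ins$valve_id, n_valves))
      }
      if (ins$kind == "CALL" && !(ins$function_name %in% names(script$functions))) {
        add("ERROR", ln, "E_UNDEF_FUNC",
            sprintf("call to undefined function '%s'", ins$function_name))
      }
    }
  }

  # call-graph cycle detection by depth-first search
  callees <- function(body) {
    unique(vapply(Filter(function(i) i$kind == "CALL", body),
                  function(i) i$function_name, character(1)))
  }
  graph <- lapply(script$functions, callees)
  state <- new.env(parent = emptyenv())   # name -> "active" | "done"
  cycle_hit <- character()
  visit <- function(name, stack) {
    if (!(name %in% names(graph))) return()
    st <- if (exists(name, envir = state)) get(name, envir = state) else NA
    if (identical(st, "active")) {
      cycle_hit <<- union(cycle_hit, paste(c(stack, name), collapse = " -> "))
      return()
    }
    if (identical(st, "done")) return()
    assign(name, "active", envir = state)
    for (cal in graph[[name]]) visit(cal, c(stack, name))
    assign(name, "done", envir = state)
  }
  for (name in names(graph)) visit(name, character())
  for (cy in cycle_hit)
    add("ERROR", 1L, "E_RECURSION", sprintf("recursive call chain: %s", cy))

  # reachability from main for unused-function warnings
  reach <- new.env(parent = emptyenv())
  walk <- function(body) {
    for (cal in callees(body)) {
      if (cal %in% names(graph) && !exists(cal, envir = reach)) {
        assign(cal, TRUE, envir = reach)
        walk(script$functions[[cal]])
      }
    }
  }
  if (length(cycle_hit) == 0) walk(script$main)
  unused <- setdiff(names(script$functions), ls(reach))
  if (length(cycle_hit) == 0) {
    for (name in unused)
      add("WARNING", 1L, "W_UNUSED_FUNC",
          sprintf("function '%s' is never called", name))
  }

  diags
}

#' Is a script runnable?
#'
#' @param script A [loc_script()].
#' @param topology A [chip_topology()].
#' @return `TRUE` iff [validate_script()] reports no `ERROR` diagnostics.
#' @export
script_is_runnable <- function(script, topology = chip_topology()) {
  d <- validate_script(script, topology)
  !any(d$severity == "ERROR")
}

#' Serialize a script back to source text
#'
#' Inverse of [parse_script()] modulo comments and whitespace:
#' `parse_script(serialize_script(s))` is structurally equal to `s`.
#'
#' @param script A [loc_script()].
#' @return A character vector of source lines.
#' @export
serialize_script <- function(script) {
  stopifnot(inherits(script, "loc_script"))
  fmt_block <- function(header, body) {
    c(header, vapply(body, function(i) paste0("  ", format(i)), character(1)), "end")
  }
  out <- fmt_block("main:", script$main)
  for (name in names(script$functions)) {
    out <- c(out, "", fmt_block(sprintf("def %s:", name), script$functions[[name]]))
  }
  out
}

#' Format diagnostics for terminal output
#'
#' @param diags Data frame returned by [validate_script()].
#' @param file Optional file name to prefix (`file:line: severity code message`).
#' @return Character vector, one formatted line per diagnostic.
#' @export
format_diagnostics <- function(diags, file = "<script>") {
  if (nrow(diags) == 0) return(character())
  sprintf("%s:%d: %s %s %s", file, diags$line_no, diags$severity,
          diags$code, diags$message)
}

#' Generate a random valid script
#'
#' Draws a structurally valid script over a topology: a main block of random
#' open/close/wait/call instructions and a set of user functions wired into an
#' acyclic call graph (function k may only call functions with larger index,
#' so recursion is impossible by construction). Used for fuzz-testing the
#' parser round trip and interpreter.
#'
#' Uses the current RNG state; call [set.seed()] for reproducibility.
#'
#' @param n_main Number of instructions in the main block.
#' @param n_functions Number of user-defined functions.
#' @param n_body Instructions per function body.
#' @param topology A [chip_topology()] bounding valve ids.
#' @param max_wait_ms Upper bound for generated wait durations.
#' @return A valid [loc_script()] (possibly with unused-function warnings).
#' @export
random_script <- function(n_main = 12, n_functions = 3, n_body = 5,
                          topology = chip_topology(), max_wait_ms = 1000) {
  fnames <- if (n_functions > 0) paste0("f", seq_len(n_functions)) else character()
  rand_instr <- function(allowed_calls) {
    kinds <- c("OPEN", "CLOSE", "WAIT")
    if (length(allowed_calls) > 0) kinds <- c(kinds, "CALL")
    kind <- sample(kinds, 1)
    switch(kind,
      OPEN  = op_open(sample.int(topology$n_valves, 1)),
      CLOSE = op_close(sample.int(topology$n_valves, 1)),
      WAIT  = op_wait(sample.int(max_wait_ms + 1, 1) - 1L),
      CALL  = op_call(sample(allowed_calls, 1))
    )
  }
  funcs <- list()
  for (k in seq_len(n_functions)) {
    allowed <- if (k < n_functions) fnames[(k + 1):n_functions] else character()
    funcs[[fnames[[k]]]] <- lapply(seq_len(n_body), function(j) rand_instr(allowed))
  }
  main <- lapply(seq_len(max(1, n_main)), function(j) rand_instr(fnames))
  loc_script(main = main, functions = funcs)
}
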