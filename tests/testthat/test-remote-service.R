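test_that("topic patterns match MQTT-style wildcards", {
  expect_true(topic_matches("device/chip1/command", "device/chip1/command"))
  expect_true(topic_matches("device/+/command", "device/chip7/command"))
  expect_true(topic_matches("device/#", "device/chip1/status"))
  expect_false(topic_matches("device/+/command", "device/chip1/status"))
  expect_false(topic_matches("device/chip1/command", "device/chip1"))
})

test_that("manual valve commands are applied, acknowledged and idempotent", {
  bus <- loc_bus()
  dev <- loc_device(bus, "chip1")
  st <- manual_valve_command(bus, "chip1", "open", 3)
  expect_equal(st$payload$status, "ok")
  expect_equal(st$payload$valve_id, 3)
  expect_equal(st$payload$state, "open")
  expect_true(st$payload$changed)
  expect_true(dev$backend$state$valve_open[["V3"]])

  st2 <- manual_valve_command(bus, "chip1", "open", 3)
  expect_equal(st2$payload$status, "ok")
  expect_false(st2$payload$changed)    # second identical command is a no-op

  st3 <- manual_valve_command(bus, "chip1", "open", 99)
  expect_equal(st3$payload$status, "rejected")
  expect_match(st3$payload$error, "outside range")
  expect_false(any(grepl("^V99$", names(dev$backend$state$valve_open))))
})

test_that("commands to an unknown device time out instead of vanishing", {
  bus <- loc_bus()
  st <- manual_valve_command(bus, "ghost", "open", 1)
  expect_equal(st$payload$status, "timeout")
  msgs <- run_saved_script(bus, "ghost", "wash")
  expect_equal(msgs[[1]]$payload$status, "timeout")
})

test_that("running a stored template streams progress and a dry-run-consistent summary", {
  bus <- loc_bus()
  dev <- loc_device(bus, "chip1")
  msgs <- run_saved_script(bus, "chip1", "wash")
  final <- msgs[[length(msgs)]]$payload
  expect_equal(final$status, "done")

  wash <- parse_script(store_get(dev$store, "wash"))
  dr <- dry_run(wash, dev$topology)
  expect_equal(final$n_actuations, dr$n_actuations)
  expect_equal(final$total_duration_ms, dr$total_duration_ms)
  # one progress message per actuation, plus the completion report
  expect_equal(length(msgs), dr$n_actuations + 1)
  expect_true(all(vapply(msgs[-length(msgs)],
                         function(m) m$payload$status == "progress",
                         logical(1))))

  bad <- run_saved_script(bus, "chip1", "no_such_script")
  expect_equal(bad[[1]]$payload$status, "error")
})

test_that("uploads validate on-device; diagnostics ride back on rejection", {
  bus <- loc_bus()
  dev <- loc_device(bus, "chip1")

  st <- upload_script(bus, "chip1", "stain_v2",
                      c("main:", "o 1", "w 100", "c 1", "end"))
  expect_equal(st$payload$status, "stored")
  expect_true("stain_v2" %in% store_list(dev$store))

  st2 <- upload_script(bus, "chip1", "bad",
                       c("main:", "call nope", "end"))
  expect_equal(st2$payload$status, "rejected")
  expect_match(unlist(st2$payload$diagnostics), "E_UNDEF_FUNC")
  expect_false("bad" %in% store_list(dev$store))

  st3 <- upload_script(bus, "chip1", "mangled", c("main:", "xyzzy 1", "end"))
  expect_equal(st3$payload$status, "rejected")
  expect_match(unlist(st3$payload$diagnostics), "E_SYNTAX")
})

test_that("transport transparency: upload+run equals a local run of the same source", {
  src <- c("main:", "call cycle", "w 50", "call cycle", "end",
           "def cycle:", "o 2", "w 10", "c 2", "o 5", "w 10", "c 5", "end")

  bus <- loc_bus()
  dev <- loc_device(bus, "chip1")
  upload_script(bus, "chip1", "cycle_test", src)
  run_saved_script(bus, "chip1", "cycle_test")
  remote_calls <- dev$backend$state   # state evolved through the bus

  local_backend <- chip_backend(chip_state(chip_topology()))
  local_trace <- run_script(parse_script(src), local_backend)
  expect_equal(remote_calls$valve_open, local_backend$state$valve_open)
  expect_equal(remote_calls$t_ms, local_backend$state$t_ms)

  # and the actuation sequence is identical to the local trace via progress msgs
  msgs <- Filter(function(m) identical(m$payload$status, "progress"), bus$log)
  expect_equal(vapply(msgs, function(m) m$payload$action, character(1)),
               local_trace$events$action)
  expect_equal(vapply(msgs, function(m) m$payload$valve_id, numeric(1)),
               local_trace$events$valve_id)
})

test_that("every command is answered and bus delivery is FIFO per topic", {
  bus <- loc_bus()
  loc_device(bus, "chip1")
  for (v in c(1, 2, 3)) manual_valve_command(bus, "chip1", "open", v)
  upload_script(bus, "chip1", "t", c("main:", "o 1", "end"))
  run_saved_script(bus, "chip1", "t")

  cmds <- Filter(function(m) m$topic == "device/chip1/command", bus$log)
  stats_ <- Filter(function(m) m$topic == "device/chip1/status", bus$log)
  answered <- vapply(cmds, function(cmd) {
    any(vapply(stats_, function(s) identical(s$ref_id, cmd$msg_id), logical(1)))
  }, logical(1))
  expect_true(all(answered))   # no command silently dropped

  ids <- vapply(stats_, function(m) m$msg_id, integer(1))
  expect_true(all(diff(ids) > 0))   # log order = publish order (FIFO)
})

test_that("the script store persists to disk and rejects unparsable sources", {
  dir <- withr::local_tempdir()
  store <- script_store(dir)
  store_add(store, "wash2", c("main:", "o 1", "c 1", "end"))
  expect_true(file.exists(file.path(dir, "wash2.loc")))
  store2 <- script_store(dir)      # reload from disk
  expect_equal(store_list(store2), "wash2")
  expect_error(store_add(store, "junk", "not a script"), class = "loc_parse_error")
})
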