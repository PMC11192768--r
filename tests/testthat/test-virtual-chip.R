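test_that("default topology matches the physical device's constants", {
  topo <- chip_topology()
  expect_equal(topo$n_valves, 15)
  expect_equal(length(topo$reservoirs), 6)
  expect_equal(sum(topo$reservoirs == "INLET"), 3)
  expect_true(topo$detection_node %in% topo$valves)
})

test_that("loading credits the ledger; bad loads are rejected", {
  st <- chip_state()
  st <- load_inlet(st, "R1", "ecoli_pbs", 2000)
  expect_equal(unname(st$ledger$R1$loaded["ecoli_pbs"]), 2000)
  expect_equal(unname(st$contents$R1["ecoli_pbs"]), 2000)

  st <- load_inlet(st, "R1", "ecoli_pbs", 500)   # sequential loads accumulate
  expect_equal(unname(st$ledger$R1$loaded["ecoli_pbs"]), 2500)

  expect_error(load_inlet(st, "R1", "x", 0), "positive")
  expect_error(load_inlet(st, "R4", "x", 10), "not an INLET")
  expect_error(load_inlet(st, "R99", "x", 10), "unknown reservoir")
})

test_that("opening draws from adjacent inlets up to valve capacity", {
  st <- loaded_state()
  st <- open_valve(st, 1)
  expect_true(st$valve_open[["V1"]])
  expect_equal(parcel_volume(st$contents$V1), 10)   # capacity, not the full 2 uL
  expect_equal(parcel_volume(st$contents$R1), 1990)
  st2 <- open_valve(st, 1)                          # idempotent
  expect_identical(st2, st)
  expect_error(open_valve(st, 99), "outside range")
})

test_that("merging parcels averages composition by volume", {
  p <- merge_parcels(parcel(A = 10), parcel(B = 10))
  expect_equal(parcel_volume(p), 20)
  expect_equal(parcel_composition(p), c(A = 0.5, B = 0.5))
  p2 <- merge_parcels(parcel(A = 30), parcel(A = 10, B = 10))
  expect_equal(parcel_composition(p2), c(A = 0.8, B = 0.2))
})

test_that("closing splits the parcel equally among open neighbors", {
  # V5 flanked by open V4 and V6 on the default chain
  st <- chip_state()
  st <- load_inlet(st, "R1", "dye", 100)
  st <- open_valve(st, 1)           # draws 10 nL
  st <- open_valve(st, 4)
  st <- close_valve(st, 1)          # splits V1's 10 nL between R1 and V4
  expect_equal(parcel_volume(st$contents$V4), 5)
  st <- open_valve(st, 5)
  st <- close_valve(st, 4)          # all 5 nL to V5 (V1..V3 closed)
  expect_equal(parcel_volume(st$contents$V5), 5)
  st <- open_valve(st, 4)
  st <- open_valve(st, 6)
  st <- close_valve(st, 5)          # equal split between V4 and V6
  expect_equal(parcel_volume(st$contents$V4), 2.5)
  expect_equal(parcel_volume(st$contents$V6), 2.5)
  expect_equal(parcel_composition(st$contents$V4), c(dye = 1))
})

test_that("closing an empty valve is a no-op; trapped parcels are audited", {
  st <- chip_state()
  st0 <- close_valve(st, 8)
  expect_equal(parcel_volume(st0$contents$V8), 0)
  expect_equal(nrow(st0$audit), 0)

  # park fluid in V8 with all neighbors closed, then close it
  st <- load_inlet(st, "R1", "dye", 100)
  st <- open_valve(st, 1); st <- open_valve(st, 4); st <- close_valve(st, 1)
  st <- open_valve(st, 5); st <- close_valve(st, 4)
  st <- open_valve(st, 6); st <- close_valve(st, 5)
  st <- open_valve(st, 7); st <- close_valve(st, 6)
  st <- open_valve(st, 8); st <- close_valve(st, 7)
  v_before <- parcel_volume(st$contents$V8)
  expect_gt(v_before, 0)
  st <- close_valve(st, 8)          # V7 and V9 both closed, no reservoir
  expect_equal(parcel_volume(st$contents$V8), 0)
  expect_equal(length(st$trapped), 1)
  expect_equal(st$trapped[[1]]$node, "V8")
  expect_equal(parcel_volume(st$trapped[[1]]$parcel), v_before)
  expect_true("W_TRAPPED" %in% st$audit$code)
  # still conserved
  expect_true(all(mass_balance(st)$rel_error < 1e-9))
})

test_that("a three-valve relocation matches a hand-computed ledger", {
  # Chain V4-V5-V6. Put 5 nL in V5, close toward V4, reopen, close toward V6.
  st <- chip_state()
  st <- load_inlet(st, "R1", "dye", 100)
  st <- open_valve(st, 1); st <- open_valve(st, 4); st <- close_valve(st, 1)
  st <- open_valve(st, 5); st <- close_valve(st, 4)     # 5 nL now in V5
  st <- open_valve(st, 4)
  st <- close_valve(st, 5)                              # -> all 5 nL to V4
  expect_equal(parcel_volume(st$contents$V4), 5)
  expect_equal(parcel_volume(st$contents$V5), 0)
  st <- open_valve(st, 5); st <- close_valve(st, 4)     # back to V5
  st <- open_valve(st, 6)
  st <- close_valve(st, 5)                              # -> all 5 nL to V6
  expect_equal(parcel_volume(st$contents$V6), 5)
  expect_equal(parcel_composition(st$contents$V6), c(dye = 1))
})

test_that("random actuation sequences conserve every reagent", {
  set.seed(707)
  for (rep in 1:50) {
    st <- random_actuations(loaded_state(), n_ops = 40)
    mb <- mass_balance(st)
    expect_equal(nrow(mb), 3)
    expect_true(all(mb$rel_error < 1e-9))
    # composition fractions stay in [0,1] and sum to 1 for non-empty parcels
    for (node in names(st$contents)) {
      p <- st$contents[[node]]
      if (parcel_volume(p) > 0) {
        comp <- parcel_composition(p)
        expect_true(all(comp >= 0 & comp <= 1))
        expect_equal(sum(comp), 1)
      }
    }
  }
})

test_that("open-on-open and close-on-closed-empty are state no-ops", {
  set.seed(808)
  st <- random_actuations(loaded_state(), n_ops = 20)
  for (v in 1:15) {
    node <- paste0("V", v)
    if (st$valve_open[[node]]) {
      expect_identical(open_valve(st, v), st)
    } else if (parcel_volume(st$contents[[node]]) == 0) {
      expect_identical(close_valve(st, v), st)
    }
  }
})

test_that("the reference staining protocol delivers a mixed parcel", {
  run <- run_protocol(parse_script(reference_script("staining")))
  comp <- parcel_composition(run$delivered)
  expect_gt(parcel_volume(run$delivered), 0)
  expect_gt(comp[["ecoli_pbs"]], 0)
  expect_gt(comp[["sybr_gold"]], 0)
  expect_true(all(mass_balance(run$state)$rel_error < 1e-9))
})

test_that("a script that never opens the detection-side valves delivers nothing", {
  s <- parse_script(c("main:", "o 1", "w 100", "c 1", "end"))
  run <- run_protocol(s)
  expect_equal(parcel_volume(run$delivered), 0)
})

test_that("chip state snapshots round-trip through JSON", {
  set.seed(909)
  st <- random_actuations(loaded_state(), n_ops = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_chip_state(st, path)
  st2 <- read_chip_state(path, st$topology)
  expect_equal(st2$valve_open, st$valve_open)
  expect_equal(st2$t_ms, st$t_ms)
  for (node in names(st$contents)) {
    expect_equal(sort(st2$contents[[node]]), sort(st$contents[[node]]),
                 tolerance = 1e-12)
  }
  expect_equal(mass_balance(st2), mass_balance(st), tolerance = 1e-12)
})
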