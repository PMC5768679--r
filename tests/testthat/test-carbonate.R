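# Seawater CO2-system solver: constants against frozen external references,
# speciation against the brute-force oracle, round trips, monotonicity.

test_that("equilibrium constants match frozen external reference values", {
  k <- equilibrium_constants(sw_conditions(25, 35))
  # literature check values at 25 degC, S = 35 (total scale)
  expect_equal(-log10(k$K1), 5.8472, tolerance = 1e-4)
  expect_equal(-log10(k$K2), 8.9660, tolerance = 1e-4)
  expect_equal(-log10(k$KB), 8.5975, tolerance = 1e-4)
  # Weiss solubility, hand-evaluated independently
  expect_equal(k$K0, 0.0283919, tolerance = 1e-6)
  expect_equal(co2_solubility(sw_conditions(20, 35)), 0.03240744,
               tolerance = 1e-6)
  expect_equal(k$Ksp_arag, 6.4818e-7, tolerance = 1e-4)
  # structural invariants
  expect_true(all(unlist(k[c("K0", "K1", "K2", "KB", "KW", "KP1", "KP2",
                             "KP3", "KSi", "KNH4", "KS", "KF",
                             "Ksp_arag", "BT", "CaT")]) > 0))
  expect_gt(k$K1, k$K2)
})

test_that("borate and calcium totals scale linearly with salinity", {
  k0 <- equilibrium_constants(sw_conditions(25, 1e-6))
  k35 <- equilibrium_constants(sw_conditions(25, 35))
  expect_equal(k0$BT, 0, tolerance = 1e-9)
  k17 <- equilibrium_constants(sw_conditions(25, 17.5))
  expect_equal(k17$BT, k35$BT / 2)
  expect_equal(k17$CaT, k35$CaT / 2)
})

test_that("CO2 solubility decreases with temperature and is deterministic", {
  expect_gt(co2_solubility(sw_conditions(5, 35)),
            co2_solubility(sw_conditions(25, 35)))
  expect_identical(co2_solubility(sw_conditions(13.7, 33.2)),
                   co2_solubility(sw_conditions(13.7, 33.2)))
})

test_that("out-of-range conditions raise domain errors naming the field", {
  expect_error(sw_conditions(45, 35), "temperature")
  expect_error(sw_conditions(25, 60), "salinity")
  expect_error(sw_conditions(25, 35, -1), "pressure")
})

test_that("DIC from (pH, TA) matches the brute-force oracle", {
  cond <- sw_conditions(25, 35)
  st <- carb_from_ph_ta(8.1, 2300, cond)
  expect_equal(st$DIC, oracle_dic(8.1, 2300, cond), tolerance = 1e-8)
  # frozen from the independent transcription of the same formulations
  expect_equal(st$DIC, 1967.196, tolerance = 1e-6)
  expect_equal(st$pCO2, 339.029, tolerance = 1e-5)
  expect_equal(st$omega_arag, 3.7224, tolerance = 1e-4)
})

test_that("speciation sums to DIC and responds to nutrients as expected", {
  cond <- sw_conditions(25, 35)
  st <- carb_from_ph_ta(8.1, 2300, cond)
  expect_equal(st$CO2star + st$HCO3 + st$CO3, st$DIC, tolerance = 1e-9)
  # more non-carbonate alkalinity leaves less carbonate alkalinity -> less DIC
  st_nut <- carb_from_ph_ta(8.1, 2300, cond,
                            nutrients(NH4 = 1, NO3 = 2, PO4 = 0.5))
  expect_lt(st_nut$DIC, st$DIC)
  expect_equal(st_nut$DIC, 1966.620, tolerance = 1e-6)
  st_nut2 <- carb_from_ph_ta(8.1, 2300, cond,
                             nutrients(NH4 = 2, NO3 = 4, PO4 = 1))
  expect_lt(st_nut2$DIC, st_nut$DIC)
})

test_that("pH from (TA, DIC) matches the oracle and inverts the DIC solve", {
  cond <- sw_conditions(25, 35)
  st <- carb_from_ta_dic(2300, 2000, cond)
  expect_equal(st$pH, 8.0459631, tolerance = 1e-6)
  expect_equal(st$pH, oracle_ph(2300, 2000, cond), tolerance = 1e-6)
  # monotonicity: more DIC at fixed TA -> lower pH
  expect_lt(carb_from_ta_dic(2300, 2050, cond)$pH, st$pH)
})

test_that("pH -> DIC -> pH round trips close on random feasible states", {
  states <- random_states(50)
  for (i in seq_len(nrow(states))) {
    cond <- sw_conditions(states$temp[i], states$sal[i])
    nut <- nutrients(NH4 = states$NH4[i], NO3 = states$NO3[i],
                     PO4 = states$PO4[i])
    st <- carb_from_ph_ta(states$pH[i], states$TA[i], cond, nut)
    back <- carb_from_ta_dic(states$TA[i], st$DIC, cond, nut)
    expect_lt(abs(back$pH - states$pH[i]), 1e-6)
    expect_lt(abs(st$CO2star + st$HCO3 + st$CO3 - st$DIC) / st$DIC, 1e-9)
  }
})

test_that("monotonicity of pH in DIC and of omega in pH (finite differences)", {
  states <- random_states(20, seed = 7)
  for (i in seq_len(nrow(states))) {
    cond <- sw_conditions(states$temp[i], states$sal[i])
    st <- carb_from_ph_ta(states$pH[i], states$TA[i], cond)
    up <- carb_from_ta_dic(states$TA[i], st$DIC * 1.01, cond)
    expect_lt(up$pH, st$pH)
    hi <- carb_from_ph_ta(states$pH[i] + 0.05, states$TA[i], cond)
    expect_gt(hi$omega_arag, st$omega_arag)
  }
})

test_that("omega_aragonite is linear in CO3 and zero at zero", {
  cond <- sw_conditions(25, 35)
  expect_equal(omega_aragonite(0, cond), 0)
  expect_equal(omega_aragonite(400, cond), 2 * omega_aragonite(200, cond))
})

test_that("lab-to-in-situ adjustment preserves TA/DIC and has the right sign", {
  cond <- sw_conditions(14, 34)
  st <- adjust_to_insitu(8.0, 20, 2250, cond)
  expect_equal(st$pH, 8.0915330, tolerance = 1e-6)
  # identity when lab equals in-situ temperature
  same <- adjust_to_insitu(8.0, 14, 2250, cond)
  expect_lt(abs(same$pH - 8.0), 1e-6)
  # warming at fixed TA/DIC lowers pH
  warm <- adjust_to_insitu(8.0, 20, 2250, sw_conditions(25, 34))
  cool <- adjust_to_insitu(8.0, 20, 2250, sw_conditions(15, 34))
  expect_lt(warm$pH, cool$pH)
})

test_that("infeasible pH/TA pairs and bad inputs are rejected", {
  cond <- sw_conditions(25, 35)
  expect_error(carb_from_ph_ta(5, 2300, cond), "pH")
  expect_error(carb_from_ph_ta(8.1, -10, cond), "TA")
  # huge nutrient alkalinity swamps TA at high pH -> carbonate alkalinity <= 0
  expect_error(carb_from_ph_ta(9.9, 1, cond, nutrients(NO3 = 3000)),
               "carbonate alkalinity")
  expect_error(carb_from_ta_dic(-5, 2000, cond), "TA")
})
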