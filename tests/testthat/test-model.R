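test_that("default initial state matches the published initial conditions", {
  y0 <- default_initial_state()
  expect_s3_class(y0, "glucosome_state")
  expect_equal(unname(y0[paste0("S", 1:7)]), rep(0.01, 7))
  expect_equal(unname(y0[c("P1", "P2", "P3")]), rep(0.01, 3))
  expect_equal(unname(y0[["E1"]]), 99.99)
  expect_equal(unname(y0[["E2"]]), 100)
  expect_equal(unname(y0[["E3"]]), 99.99)
  expect_equal(unname(y0[["E4"]]), 100)
  expect_equal(unname(y0[c("E_S", "E_M", "E_L")]), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(y0[["E3_star"]]), 0.01)
  expect_equal(unname(y0[["E1_gly"]]), 0.01)
  # each enzyme pool conserved at 100, PFKL split between free and glycosylated
  expect_equal(unname(y0[["E1"]] + y0[["E1_gly"]]), 100)
  expect_equal(unname(conservation_totals(y0)), rep(100, 4))
})

test_that("default parameters match the published rate constants", {
  p <- default_parameters()
  expect_equal(unname(p[c("k0", "k2", "k_m2", "k4", "k_m4", "k5")]),
               c(10, 40, 7, 14, 7, 1))
  expect_equal(unname(p[c("k1", "k_m1", "k3", "k_m3", "k_m5", "k_m6")]),
               rep(10, 6))
  expect_equal(unname(p[c("k_as", "k_mas", "k_am", "k_mam", "k_al", "k_mal")]),
               rep(10, 6))
  expect_equal(unname(p[c("k_g", "k_mg", "k_d", "k_md")]), rep(1, 4))
  expect_equal(unname(p[c("k_p", "k_s", "k_f")]), rep(5, 3))
  expect_equal(unname(p[c("delta_p", "delta_s", "delta_f")]), rep(0.5, 3))
  expect_equal(unname(p[c("c2", "c_m2", "c_m6", "c_md")]), c(0.2, 10, 10, 0.1))
  expect_equal(unname(p[c("e2", "e_m2", "e_m6", "e_md")]),
               c(2.5, 0.1, 10, 0.05))
  expect_equal(unname(p[c("alpha", "K1", "K2", "K3")]), rep(1, 4))
})

test_that("constructors validate names and non-negativity", {
  expect_error(glucosome_state(S1 = -1), "negative")
  expect_error(glucosome_state(bogus = 1), "unknown state")
  expect_error(glucosome_parameters(k99 = 1), "unknown parameter")
  expect_error(glucosome_parameters(k2 = -1), "negative")
  y <- glucosome_state(S3 = 0.5)
  expect_equal(unname(y[["S3"]]), 0.5)
  expect_equal(unname(y[["S1"]]), 0)
})

test_that("propensities reproduce hand-evaluated values at the defaults", {
  y0 <- default_initial_state()
  p <- default_parameters()
  R <- propensities(y0, p)
  expect_length(R, 28)
  expect_true(all(R >= 0))
  expect_equal(unname(R[["R1"]]), 10)                  # constant glucose input
  # R4 = 40 * (99.99 + 0 + 0 + 0) * 0.01 * 1/(1 + 0.01)
  expect_equal(unname(R[["R4"]]), 40 * 99.99 * 0.01 / 1.01, tolerance = 1e-12)
  expect_equal(unname(R[["R17"]]), 0)                  # E_M = 0 => 0^11
  # allosteric factor reduces to 1 when S3 = 0
  y <- glucosome_state(values = replace(unclass(y0), "S3", 0))
  R0 <- propensities(y, p)
  expect_equal(unname(R0[["R22"]]),
               unname(p[["k_md"]] * (y[["E3"]] + p[["c_md"]] * y[["E_M"]] +
                                       p[["e_md"]] * y[["E_L"]])))
  expect_error(propensities(unclass(y0) - 1, p), "negative")
})

test_that("derivative reproduces hand-evaluated rows at the defaults", {
  y0 <- default_initial_state()
  p_free <- glucosome_parameters(k_as = 0, k_mas = 0, k_am = 0, k_mam = 0,
                                 k_al = 0, k_mal = 0)
  dy <- derivative(y0, p_free)
  # dS1/dt = R1 - R2 + R3 = 10 - 0.1 + 0.1
  expect_equal(unname(dy[["S1"]]), 10, tolerance = 1e-12)
  dy_def <- derivative(y0, default_parameters())
  # dP1/dt = k_p S2 - delta_p P1 = 0.05 - 0.005
  expect_equal(unname(dy_def[["P1"]]), 0.045, tolerance = 1e-12)
})

test_that("propensities and derivative match the literal transcription oracle", {
  set.seed(7)
  for (i in 1:100) {
    y <- random_state()
    p <- if (i %% 2) default_parameters() else random_params()
    expect_equal(propensities(y, p), oracle_propensities(y, p),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(derivative(y, p), oracle_derivative(y, p),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("enzyme conservation is structural: weighted column sums vanish", {
  nu <- stoichiometry()
  w <- list(
    PFK = c(E1 = 1, E2 = 0, E3 = 0, E4 = 0, E_S = 1, E_M = 1, E_L = 11,
            E3_star = 0, E1_gly = 1),
    FBPase = c(E1 = 0, E2 = 1, E3 = 0, E4 = 0, E_S = 0, E_M = 1, E_L = 11,
               E3_star = 0, E1_gly = 0),
    PK = c(E1 = 0, E2 = 0, E3 = 1, E4 = 0, E_S = 0, E_M = 1, E_L = 11,
           E3_star = 1, E1_gly = 0),
    PEPCK = c(E1 = 0, E2 = 0, E3 = 0, E4 = 1, E_S = 0, E_M = 1, E_L = 11,
              E3_star = 0, E1_gly = 0))
  for (tot in w)
    expect_equal(unname(drop(tot %*% nu$nu_E)), rep(0, 10))
})

test_that("conservation totals weight large clusters 11-fold", {
  y <- glucosome_state(E_L = 2)
  expect_equal(unname(conservation_totals(y)), rep(22, 4))
})

test_that("unit medium-cluster efficiencies make E_M kinetically a free-enzyme pool", {
  p <- glucosome_parameters(c2 = 1, c_m2 = 1, c_m6 = 1, c_md = 1)
  y_clustered <- glucosome_state(S2 = 0.5, S3 = 0.3, S7 = 0.2,
                                 E1 = 50, E2 = 60, E3 = 70, E4 = 80, E_M = 5)
  y_free <- glucosome_state(S2 = 0.5, S3 = 0.3, S7 = 0.2,
                            E1 = 55, E2 = 65, E3 = 75, E4 = 85, E_M = 0)
  Rc <- propensities(y_clustered, p)
  Rf <- propensities(y_free, p)
  for (r in c("R4", "R5", "R12", "R22"))
    expect_equal(Rc[[r]], Rf[[r]], tolerance = 1e-12)
})
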