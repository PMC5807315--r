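# Independent re-transcription of the reaction propensities and the ODE
# right-hand side, written equation by equation (no shared code with the
# package implementation, which routes through stoichiometry matrices).

oracle_propensities <- function(state, params) {
  with(c(as.list(state), as.list(unclass(params))), c(
    R1 = k0,
    R2 = k1 * S1,
    R3 = k_m1 * S2,
    R4 = k2 * (E1 + E_S + c2 * E_M + e2 * E_L) * S2 * K1 / (K1 + S3),
    R5 = k_m2 * (E2 + c_m2 * E_M + e_m2 * E_L) * S3 * K2 / (K2 + S2),
    R6 = k3 * S3,
    R7 = k_m3 * S4,
    R8 = k4 * S4,
    R9 = k_m4 * S5,
    R10 = k5 * E3_star * S5,
    R11 = k_m5 * S6,
    R12 = k_m6 * (E4 + c_m6 * E_M + e_m6 * E_L) * S7,
    R13 = k_as * E1,
    R14 = k_mas * E_S,
    R15 = k_am * E_S * E2 * E3 * E4,
    R16 = k_mam * E_M,
    R17 = k_al * E_M^11,
    R18 = k_mal * E_L,
    R19 = k_g * E1,
    R20 = k_mg * E1_gly,
    R21 = k_d * E3_star,
    R22 = k_md * (E3 + c_md * E_M + e_md * E_L) *
      (1 + alpha * S3 / (S3 + K3)),
    R23 = k_p * S2,
    R24 = k_s * S4,
    R25 = k_f * S6,
    R26 = delta_p * P1,
    R27 = delta_s * P2,
    R28 = delta_f * P3))
}

oracle_derivative <- function(state, params) {
  R <- as.list(oracle_propensities(state, params))
  with(R, c(
    S1 = R1 - R2 + R3,
    S2 = R2 - R3 - R4 + R5 - R23,
    S3 = R4 - R5 - R6 + R7,
    S4 = R6 - R7 - R8 + R9 - R24,
    S5 = R8 - R9 - R10 + R12,
    S6 = R10 - R11 - R25,
    S7 = R11 - R12,
    E1 = -R13 + R14 - R19 + R20,
    E2 = -R15 + R16,
    E3 = -R15 + R16 + R21 - R22,
    E4 = -R15 + R16,
    E_S = R13 - R14 - R15 + R16,
    E_M = R15 - R16 - 11 * R17 + 11 * R18,
    E_L = R17 - R18,
    E3_star = -R21 + R22,
    E1_gly = R19 - R20,
    P1 = R23 - R26,
    P2 = R24 - R27,
    P3 = R25 - R28))
}

# Explicit residualization-on-ranks PRCC oracle: regress the ranks of
# parameter j and of the output on the ranks of the other parameters with
# lm(), then correlate the residuals. Brute force, one lm pair per cell.
oracle_prcc <- function(X, y) {
  Xr <- apply(X, 2, rank)
  yr <- rank(y)
  vapply(seq_len(ncol(X)), function(j) {
    others <- Xr[, -j, drop = FALSE]
    if (ncol(others) == 0) return(cor(Xr[, j], yr))
    rj <- residuals(lm(Xr[, j] ~ others))
    ry <- residuals(lm(yr ~ others))
    cor(rj, ry)
  }, numeric(1))
}

random_state <- function() {
  glucosome_state(values = setNames(
    c(runif(7, 0, 2), runif(9, 0, 100), runif(3, 0, 10)), state_names()))
}

random_params <- function() {
  d <- unclass(default_parameters())
  glucosome_parameters(values = d * runif(length(d), 0.5, 2))
}
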