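# Independent fixed-step RK4 integrator of the product-inhibited rate law,
# used as a brute-force oracle against the package's adaptive solver.
rk4_fraction <- function(params, times, n_sub = 400) {
  S0 <- params$S0
  deriv <- function(S) {
    S <- min(max(S, 0), S0)
    if (S == 0 || params$E0 == 0) return(0)
    -params$kcat * params$E0 * S /
      (params$K_M * (1 + (S0 - S) / params$K_P + S / params$K_M))
  }
  out <- numeric(length(times))
  S <- S0
  t_cur <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    if (target > t_cur) {
      h <- (target - t_cur) / n_sub
      for (s in seq_len(n_sub)) {
        k1 <- deriv(S)
        k2 <- deriv(S + h / 2 * k1)
        k3 <- deriv(S + h / 2 * k2)
        k4 <- deriv(S + h * k3)
        S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t_cur <- target
    }
    out[i] <- if (S0 > 0) (S0 - min(max(S, 0), S0)) / S0 else 0
  }
  out
}

base_params <- function(K_P_ratio = 1) {
  kinetic_params(kcat = 1, K_M = 10, K_P = 10 * K_P_ratio,
                 E0 = 0.5, S0 = 100)
}

# Qualitative specificity pattern of the published all-against-all
# digestion panel: Atg4-type proteases cleave only Atg8-type substrates
# (with trAtg4 also cleaving xGATE16 and trAtg8 but not xLC3B); the
# SUMO-, NEDD8- and TEV-dedicated substrates are untouched by Atg4s and
# vice versa.
fig8b_specificity <- function() {
  prots <- c("xAtg4B", "trAtg4", "bdSENP1", "bdNEDP1", "TEV")
  subs <- c("xLC3B", "xGATE16", "trAtg8", "bdSUMO", "bdNEDD8", "tevSite")
  m <- matrix(0, length(prots), length(subs),
              dimnames = list(prots, subs))
  m["xAtg4B", c("xLC3B", "xGATE16", "trAtg8")] <- 1
  m["trAtg4", c("xGATE16", "trAtg8")] <- 0.5
  m["bdSENP1", "bdSUMO"] <- 1
  m["bdNEDP1", "bdNEDD8"] <- 1
  m["TEV", "tevSite"] <- 1
  m
}

fig8b_cognates <- function() {
  c(xLC3B = "xAtg4B", xGATE16 = "xAtg4B", trAtg8 = "trAtg4",
    bdSUMO = "bdSENP1", bdNEDD8 = "bdNEDP1", tevSite = "TEV")
}
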