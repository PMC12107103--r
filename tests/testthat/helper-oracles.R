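# Independent oracles used across the suite. Written as plain loops /
# direct arithmetic so they share no code path with the package internals.

# Nested-bisection equilibrium oracle: free E by bisection, free I by inner
# bisection, C and S closed-form given (E, I). 200 halvings each.
oracle_equilibrium <- function(sys) {
  S_t <- if (is.null(sys$competitor)) 0 else sys$competitor$S_t
  K_S <- if (is.null(sys$competitor)) Inf else sys$competitor$K_S
  a_S <- if (is.null(sys$competitor)) 0 else sys$competitor$alpha_S
  C_of <- function(E, I)
    if (sys$C_t == 0) 0 else sys$C_t / (1 + (E / sys$K_C) * (1 + sys$alpha * I / sys$K_I))
  S_of <- function(E, I)
    if (S_t == 0) 0 else S_t / (1 + (E / K_S) * (1 + a_S * I / sys$K_I))
  I_of <- function(E) {
    if (sys$I_t == 0) return(0)
    lo <- 0; hi <- sys$I_t
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      C <- C_of(E, mid); S <- S_of(E, mid)
      tot <- mid * (1 + E / sys$K_I + sys$alpha * E * C / (sys$K_C * sys$K_I) +
                      (if (is.finite(K_S)) a_S * E * S / (K_S * sys$K_I) else 0))
      if (tot < sys$I_t) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  E <- 0
  if (sys$E_t > 0) {
    lo <- 0; hi <- sys$E_t
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      I <- I_of(mid); C <- C_of(mid, I); S <- S_of(mid, I)
      tot <- mid * (1 + C / sys$K_C + I / sys$K_I +
                      sys$alpha * C * I / (sys$K_C * sys$K_I) +
                      (if (is.finite(K_S)) S / K_S + a_S * S * I / (K_S * sys$K_I) else 0))
      if (tot < sys$E_t) lo <- mid else hi <- mid
    }
    E <- (lo + hi) / 2
  }
  I <- I_of(E); C <- C_of(E, I); S <- S_of(E, I)
  list(E = E, C = C, I = I, S = S,
       EC = E * C / sys$K_C,
       EI = E * I / sys$K_I,
       ECI = sys$alpha * E * C * I / (sys$K_C * sys$K_I),
       ES = if (is.finite(K_S)) E * S / K_S else 0,
       ESI = if (is.finite(K_S)) a_S * E * S * I / (K_S * sys$K_I) else 0)
}

# Random ternary systems for property tests (log-uniform draws).
random_system <- function(with_competitor = FALSE) {
  r <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  comp <- if (with_competitor)
    list(S_t = r(1, 1e5), K_S = r(10, 1e5),
         alpha_S = sample(c(0, r(0.01, 2)), 1)) else NULL
  ternary_system(E_t = r(0.1, 1e4), C_t = r(0.1, 1e5), I_t = r(0.1, 1e4),
                 K_C = r(10, 1e5), K_I = r(1, 1e4), alpha = r(0.1, 100),
                 competitor = comp)
}

# Direct tally of tag reads by string comparison.
oracle_tally <- function(reads, ids) {
  out <- integer(length(ids))
  for (r in reads) {
    j <- which(ids == r)
    if (length(j)) out[j] <- out[j] + 1L
  }
  out
}

# The standard desk-scale screen used by the DEL round-trip tests:
# a 12 x 15 x 14 library with one planted MTA-cooperative series on
# position 2 (mM-weak apo binding, 20-fold MTA potentiation).
demo_screen <- function() {
  list(lib = gen_library(3, c(12, 15, 14)),
       truth = ground_truth(planted_series(c(pos2 = "P2.B007"),
                                           kd_apo = 6e6,
                                           alpha = c(MTA = 20, SIN = 1))),
       config = selection_config(conditions = c("MTA", "SIN"), depth = 1e5))
}
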