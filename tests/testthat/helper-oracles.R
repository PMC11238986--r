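# Independent oracles used across tests: plain closed-form arithmetic,
# written without reference to the package internals.

oracle_hill_up <- function(x, m, e, h) m * x^h / (e^h + x^h)
oracle_hill_down <- function(x, m, e, h) m / (1 + (x / e)^h)

# hand evaluation of the thalamocortical right-hand side, term by term
oracle_thalamo_rhs <- function(S, T, V, a, b, theta = 1, tau = 0.5,
                               m1 = 100, m2 = 80, e = 20, e0 = 20,
                               h = 2.5) {
  f1 <- m1 * (b * V)^h / (e^h + (b * V)^h)
  f2 <- m2 * (b * V + b * S)^h / (e^h + (b * V + b * S)^h)
  g <- m1 / (1 + (a * T / e)^h)
  fa <- e0 + m2 * (a * T)^h / (e^h + (a * T)^h)
  drive <- g * (b * S)^h / (fa^h + (b * S)^h)
  c((f1 - theta * S) / tau, (f2 - theta * T) / tau,
    (drive - theta * V) / tau)
}

# hand evaluation of the endocrine right-hand side
oracle_endo_rhs <- function(HPA, HPG, e_x = 28, h_x = 4.2, e_k = 25.57,
                            h_k = 6.6, alpha = 0.48, tau = 30) {
  f <- function(x) 100 / (1 + (x / e_x)^h_x)
  k <- function(x) 1 + 4 / (1 + (alpha * x / e_k)^h_k)
  c((f(HPG) - k(HPA) * HPA) / tau, (f(HPA) - k(HPG) * HPG) / tau)
}

# experimental rows of the packaged GABA-A dose-response table
t003_experimental <- function() {
  t3 <- load_table("t003")
  t3[t3$model != "Median values", ]
}
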