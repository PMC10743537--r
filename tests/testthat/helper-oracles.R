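# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Isodesmic shift via the mass balance L0 = m / (1 - ka*m)^2, solved for
# the monomer concentration m by bisection on [0, 1/ka); then
# delta = delta_max * ka * m.
oracle_isodesmic <- function(ka, conc, delta_max, tol = 1e-14) {
  vapply(conc, function(L0) {
    if (L0 == 0) return(0)
    lo <- 0
    hi <- (1 - 1e-12) / ka
    f <- function(m) m / (1 - ka * m)^2 - L0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol * max(hi, 1)) break
    }
    delta_max * ka * (lo + hi) / 2
  }, numeric(1))
}

# 1:1 equilibrium complex concentration by bisection on the mass-action
# relation ka = x / ((c_dna - x) * (c_ligand - x)).
oracle_equilibrium <- function(ka, c_dna, c_ligand) {
  if (ka == 0) return(0)
  upper <- min(c_dna, c_ligand)
  f <- function(x) x - ka * (c_dna - x) * (c_ligand - x)
  lo <- 0; hi <- upper * (1 - 1e-13)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exhaustive search for the isodesmic least-squares optimum: for each
# candidate ka the optimal delta_max is the closed-form linear
# least-squares solution (the model is linear in delta_max, constrained
# to [-1000, 1000]); ka is scanned over (0.01, 50] on a log grid that is
# iteratively refined.  Independent of the Levenberg-Marquardt path.
oracle_grid_fit <- function(conc, shift, n = 201, passes = 4) {
  rss_at <- function(k) {
    x <- isodesmic_shift(k, conc, 1)
    d <- sum(x * shift) / sum(x * x)
    d <- min(max(d, -1000), 1000)
    c(rss = sum((shift - d * x)^2), delta_max = d)
  }
  ka_rng <- c(0.01, 50)
  best <- NULL
  for (p in seq_len(passes)) {
    kas <- exp(seq(log(ka_rng[1]), log(ka_rng[2]), length.out = n))
    fits <- vapply(kas, rss_at, numeric(2))
    i <- which.min(fits["rss", ])
    best <- list(ka = kas[i], delta_max = unname(fits["delta_max", i]),
                 rss = unname(fits["rss", i]))
    kw <- diff(log(range(kas))) / (n - 1)
    ka_rng <- exp(log(best$ka) + c(-2, 2) * kw)
  }
  best
}

example_path <- function(file) nmrbind_example(file)

dilution1 <- function() {
  read_dilution_table(example_path("dilution_compound1.csv"), "1")
}
dilution2 <- function() {
  read_dilution_table(example_path("dilution_compound2.csv"), "2")
}
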