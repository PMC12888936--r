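# Independent oracles used against the package implementation.
#
# The refraction oracles are verbatim transcriptions of the published
# closed-form expressions of each formula (single-expression form), coded
# separately from the package's shared vergence chain so that the two routes
# share no code.

oracle_srkt_ref <- function(A, al, r, P, V = 12) {
  na <- 1.336; ncm1 <- 0.333
  K <- 337.5 / r
  LCOR <- ifelse(al > 24.2, -3.446 + 1.716 * al - 0.0237 * al^2, al)
  Cw <- -5.41 + 0.58412 * LCOR + 0.098 * K
  H <- r - sqrt(pmax(r^2 - Cw^2 / 4, 0))
  C <- H + 0.62467 * A - 68.747 - 3.336
  L <- al + 0.65696 - 0.02029 * al
  (1000 * na * (na * r - ncm1 * L) - P * (L - C) * (na * r - ncm1 * C)) /
    (na * (V * (na * r - ncm1 * L) + L * r) -
       0.001 * P * (L - C) * (V * (na * r - ncm1 * C) + C * r))
}

oracle_holladay_ref <- function(sf, al, r, P, V = 12) {
  na <- 1.336; ncm1 <- 1 / 3
  rag <- pmax(r, 7)
  ag <- pmin(12.5 * al / 23.45, 13.5)
  C <- 0.56 + rag - sqrt(rag^2 - ag^2 / 4) + sf
  L <- al + 0.2
  (1000 * na * (na * r - ncm1 * L) - P * (L - C) * (na * r - ncm1 * C)) /
    (na * (V * (na * r - ncm1 * L) + L * r) -
       0.001 * P * (L - C) * (V * (na * r - ncm1 * C) + C * r))
}

oracle_hofferq_ref <- function(pacd, al, K, P) {
  alc <- pmin(pmax(al, 18.5), 31)
  M <- ifelse(alc <= 23, 1, -1)
  G <- ifelse(alc <= 23, 28, 23.5)
  tand <- function(x) tan(x * pi / 180)
  ACD <- pacd + 0.3 * (alc - 23.5) + tand(K)^2 +
    0.1 * M * (23.5 - alc)^2 * tand(0.1 * (G - alc)^2) - 0.99166
  Q <- 1336 / (al - ACD - 0.05) - P
  Rc <- 1.336 / (1.336 / Q + (ACD + 0.05) / 1000) - K
  Rc / (1 + 0.012 * Rc)
}

oracle_haigis_ref <- function(a0, a1, a2, al, acd, r, P) {
  n <- 1.336
  Dc <- (1.3315 - 1) / (r / 1000)
  d <- (a0 + a1 * acd + a2 * al) / 1000
  L <- al / 1000
  z <- n / (d + n / (n / (L - d) - P))
  Refc <- z - Dc
  Refc / (1 + 0.012 * Refc)
}

oracle_ref <- function(formula, k, rec) {
  r12 <- 2 * rec$r1 * rec$r2 / (rec$r1 + rec$r2)
  switch(formula,
         SRKT = oracle_srkt_ref(k$fc, rec$al, r12, rec$iolp),
         HOLLADAY1 = oracle_holladay_ref(k$fc, rec$al, r12, rec$iolp),
         HOFFERQ = oracle_hofferq_ref(k$fc, rec$al, 337.5 / r12, rec$iolp),
         HAIGIS = oracle_haigis_ref(k$fc, k$a1, k$a2, rec$al, rec$acd, r12,
                                    rec$iolp))
}

# Type-7 quantile from first principles (sort + linear interpolation).
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Exhaustive grid search refined around the coarse minimum. The refinement
# window is validated: the fine-grid minimum must not sit on the window edge
# unless that edge is a search bound, so under unimodality the result equals
# a full grid at the fine resolution.
oracle_grid_min <- function(obj, bounds, coarse = 1e-2, fine = 1e-4,
                            window = 0.05) {
  g1 <- seq(bounds[1], bounds[2], by = coarse)
  v1 <- vapply(g1, obj, numeric(1))
  x0 <- g1[which.min(v1)]
  lo <- max(bounds[1], x0 - window)
  hi <- min(bounds[2], x0 + window)
  g2 <- seq(lo, hi, by = fine)
  v2 <- vapply(g2, obj, numeric(1))
  i <- which.min(v2)
  if ((i == 1 && lo > bounds[1]) || (i == length(g2) && hi < bounds[2])) {
    stop("grid oracle: refinement window missed the minimum")
  }
  list(minimum = g2[i], objective = v2[i])
}

# Plausible random pseudophakic eyes (uniform marginals; for formula-level
# property tests where distributional realism is irrelevant).
random_eyes <- function(n, seed) {
  set.seed(seed)
  r1 <- runif(n, 7.2, 8.4)
  data.frame(eye_id = sprintf("re%04d", seq_len(n)),
             al = runif(n, 21, 27.5), acd = runif(n, 2.4, 3.9),
             lt = runif(n, 3.8, 5.4), r1 = r1,
             r2 = r1 - runif(n, 0, 0.25),
             iolp = round(runif(n, 10, 30) * 2) / 2,
             seq_achieved = runif(n, -2.5, 0.5))
}

# Synthetic study cohort shortcut.
make_cohort <- function(formula = "SRKT", n = 400, seed = 1, noise_sd = 0.42,
                        ro_true = 0, fc_true = NULL, dataset = 1) {
  cfg <- preset_config(dataset, n = n, seed = seed, noise_sd = noise_sd,
                       true_formula = formula, ro_true = ro_true,
                       fc_true = fc_true)
  suppressMessages(generate_cohort(cfg))
}

pe_objective <- function(formula, cohort, metric, ro = 0, nk = NULL) {
  function(fc) {
    k <- formula_constants(formula, fc = fc, ro = ro, nk = nk)
    pe <- suppressWarnings(prediction_errors(k, cohort))
    switch(metric, mpe = mean(pe), sdpe = sd(pe), rmspe = sqrt(mean(pe^2)),
           absmpe = abs(mean(pe)))
  }
}
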