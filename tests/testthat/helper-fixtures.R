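# shared fixture builders (all data generated in code)

# random 4-class label map with background margin
random_label_map <- function(n = 32L, seed = 1L, p = c(0.3, 0.2, 0.2, 0.2, 0.1),
                             spacing = 0.25) {
  set.seed(seed)
  lab <- matrix(sample(0:4, n * n, TRUE, prob = p), n, n)
  region_label_map(lab, spacing)
}

# label map with exactly two single pixels
two_pixel_map <- function(n, r1, c1, lab1, r2, c2, lab2, spacing = 0.25) {
  m <- matrix(0L, n, n)
  m[r1, c1] <- lab1
  m[r2, c2] <- lab2
  region_label_map(m, spacing)
}

# small cohort with pure-noise component scores appended
null_cohort_with_noise_fpcs <- function(n_cases, n_controls, n_fpcs,
                                        cohort_seed = 21L, fpc_seed = 5L) {
  cs <- cohort_spec(n_cases, n_controls, beta = c(age = 0),
                    seed = cohort_seed)
  co <- as_cohort_table(generate_cohort(cs)$cohort)
  set.seed(fpc_seed)
  for (k in seq_len(n_fpcs))
    co[[sprintf("fpc%02d", k)]] <- rnorm(nrow(co))
  co
}

# orthonormalised eigenfunction pair on the standard 180-angle grid
fixture_basis <- function(grid = seq(0, 358, by = 2)) {
  phi1 <- cos(grid * pi / 180)
  phi2 <- sin(2 * grid * pi / 180)
  cbind(phi1 / sqrt(sum(phi1^2)), phi2 / sqrt(sum(phi2^2)))
}

# brute-force between-class variance maximiser over all 3-class splits
otsu3_bruteforce <- function(h) {
  p <- h / sum(h); lev <- 0:255
  best <- -Inf; bt <- c(NA, NA)
  for (t1 in 0:253) for (t2 in (t1 + 1):254) {
    w1 <- sum(p[1:(t1 + 1)]); w2 <- sum(p[(t1 + 2):(t2 + 1)])
    w3 <- 1 - w1 - w2
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) next
    mu <- sum(p * lev)
    m1 <- sum((p * lev)[1:(t1 + 1)]) / w1
    m2 <- sum((p * lev)[(t1 + 2):(t2 + 1)]) / w2
    m3 <- sum((p * lev)[(t2 + 2):256]) / w3
    s <- w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2
    if (s > best + 1e-15) { best <- s; bt <- c(t1, t2) }
  }
  bt
}

# closed-form G statistic 2 * sum O log(O/E) on a 2 x k table
g_statistic <- function(cases, controls) {
  O <- rbind(cases, controls)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
}
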