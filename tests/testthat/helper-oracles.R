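# Independent brute-force oracles used across the suite. These deliberately
# use direct-sum formulas and exhaustive enumeration, never the package's
# own code paths or stats::-based shortcuts.

# population central moments by direct summation
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, m2 = m2, m3 = m3, m4 = m4,
       sd = sqrt(m2),
       skew = if (m2 == 0) 0 else m3 / m2^1.5,
       kurt = if (m2 == 0) 0 else m4 / m2^2)
}

# tie-corrected Kruskal-Wallis H from first principles
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(pooled)
  c_tie <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / c_tie
}

# Mann-Whitney U (mid-ranks) and exact two-sided p by full enumeration of
# all C(n+m, n) group labelings of the pooled values
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n * (n + 1) / 2
  u0 <- u_of(seq_len(n))
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= u0), mean(us >= u0))
  list(u = u0, p = min(p, 1))
}

# small two-factor layout with one injected effect pattern, noiseless
noiseless_factorial <- function(a_levels = 3, b_levels = 2, reps = 4,
                                a_effect = c(0, 1, 2)) {
  d <- tidyr::expand_grid(a = LETTERS[seq_len(a_levels)],
                          b = letters[seq_len(b_levels)],
                          rep = seq_len(reps))
  d$y <- a_effect[match(d$a, LETTERS[seq_len(a_levels)])]
  d
}

# small patient-cohort design used by unit tests (fast sizes)
tiny_patient_design <- function(n_per_cell = 8) {
  cells <- tibble::tibble(
    diagnosis = c("BD", "BD", "MDD", "MDD", "SCH", "SCH"),
    sa_status = c("SA", "NONSA", "SA", "NONSA", "SA", "NONSA"),
    n = n_per_cell,
    n_female = ceiling(n_per_cell / 2))
  cohort_design(cells)
}

# Table-1 patient cells scaled to n = 200 with a common female fraction;
# the layout used by the power and pipeline-calibration studies
scaled_patient_design <- function() {
  n <- c(23, 28, 39, 37, 27, 46)
  cells <- tibble::tibble(
    diagnosis = c("BD", "BD", "MDD", "MDD", "SCH", "SCH"),
    sa_status = c("SA", "NONSA", "SA", "NONSA", "SA", "NONSA"),
    n = n, n_female = round(0.65 * n))
  cohort_design(cells)
}

fast_params <- function(...) kinetic_defaults(t_end = 60, ...)
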