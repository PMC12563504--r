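test_that("the default study design reproduces the published cohort layout", {
  d <- default_study_design()
  expect_equal(sum(d$cells$n), 392 + 140)
  pat <- d$cells[d$cells$diagnosis != "UNAFFECTED", ]
  expect_equal(sum(pat$n), 392)
  expect_equal(sum(pat$n[pat$sa_status == "SA"]), 175)
  expect_equal(sum(pat$n[pat$sa_status == "NONSA"]), 217)
  expect_equal(pat$n[pat$diagnosis == "BD"], c(46, 55))
  expect_equal(sum(pat$n[pat$diagnosis == "MDD"]), 148)
  expect_equal(sum(pat$n[pat$diagnosis == "SCH"]), 143)
  expect_equal(d$cells$n[d$cells$diagnosis == "UNAFFECTED"], 140)
  # female counts per the demographic table
  expect_equal(sum(pat$n_female[pat$sa_status == "SA"]), 118)
  expect_equal(sum(pat$n_female[pat$sa_status == "NONSA"]), 140)
})

test_that("degenerate allele frequencies give all-reference cohorts", {
  af <- list(
    rs111798998 = c(A = 1, G = 0), rs4290270 = c(T = 1, A = 0),
    rs7305115 = c(G = 1, A = 0), HTTLPR = c(S = 1, L = 0),
    uVNTR = c("2R" = 0, "3R" = 1, "3.5R" = 0, "4R" = 0, "5R" = 0))
  d <- cohort_design(tiny_patient_design()$cells, allele_freqs = af)
  g <- generate_genotypes(d, seed = 5)
  act <- compute_activity(g)
  expect_true(all(act$c_tph2 == 1 & act$c_sert == 1 & act$c_maoa == 1))
})

test_that("genotype draws follow Hardy-Weinberg proportions at large n", {
  cells <- tibble::tibble(diagnosis = "UNAFFECTED", sa_status = NA,
                          n = 10000, n_female = 5000)
  g <- generate_genotypes(cohort_design(cells), seed = 9)
  # HTTLPR L frequency 0.55: heterozygote fraction 2pq within 3 SE
  p <- 0.55
  het <- mean(g$HTTLPR == "L/S")
  se <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / nrow(g))
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * se)
  # HWE chi-square goodness of fit, not significant at n = 10,000
  counts <- table(factor(g$HTTLPR, levels = c("L/L", "L/S", "S/S")))
  expected <- nrow(g) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(x2, df = 1, lower.tail = FALSE), 0.05)
  # X-linkage: all males hemizygous, all females diploid at uVNTR
  male <- g$sex == "male"
  expect_true(all(!grepl("/", g$uVNTR[male])))
  expect_true(all(grepl("/", g$uVNTR[!male])))
  # male hemizygous allele frequency matches the design within 3 SE
  p4 <- mean(g$uVNTR[male] == "4R")
  expect_lt(abs(p4 - 0.35), 3 * sqrt(0.35 * 0.65 / sum(male)))
})

test_that("cohort generation is deterministic and substream-stable", {
  d <- default_study_design()
  g1 <- generate_genotypes(d, seed = 123)
  g2 <- generate_genotypes(d, seed = 123)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_false(identical(as.data.frame(generate_genotypes(d, seed = 124)),
                         as.data.frame(g1)))
  # shrinking one cell leaves every other cell's draws untouched
  d2 <- d
  d2$cells$n[1] <- 10
  d2$cells$n_female[1] <- 5
  g3 <- generate_genotypes(d2, seed = 123)
  keep <- c("sex", "diagnosis", "sa_status", "rs111798998", "rs4290270",
            "rs7305115", "HTTLPR", "uVNTR")
  not_first <- function(g) {
    first <- g$diagnosis == "BD" & g$sa_status == "SA"
    as.data.frame(g[!first, keep])
  }
  expect_equal(not_first(g3), not_first(g1), ignore_attr = TRUE)
})

test_that("sex counts per cell match the design exactly", {
  d <- default_study_design()
  g <- generate_genotypes(d, seed = 2)
  obs <- dplyr::count(g[g$sex == "female", ], diagnosis, sa_status)
  want <- d$cells[, c("diagnosis", "sa_status", "n_female")]
  merged <- dplyr::left_join(want, obs, by = c("diagnosis", "sa_status"))
  expect_equal(merged$n, merged$n_female)
})

test_that("effect injection shifts one group's frequency and is reversible", {
  d <- default_study_design()
  d1 <- inject_effect(d, "SCH", "uVNTR", "4R", 0.3)
  expect_equal(d1$group_freqs$SCH$uVNTR[["4R"]], 0.65)
  expect_equal(sum(d1$group_freqs$SCH$uVNTR), 1, tolerance = 1e-12)
  # original design untouched, other groups unaffected
  expect_null(d$group_freqs$SCH)
  expect_null(d1$group_freqs$BD)
  # delta = 0 is the identity; shifting back restores the baseline
  d0 <- inject_effect(d, "SCH", "uVNTR", "4R", 0)
  expect_equal(d0$group_freqs$SCH$uVNTR, d$allele_freqs$uVNTR)
  d2 <- inject_effect(d1, "SCH", "uVNTR", "4R", -0.3)
  expect_equal(d2$group_freqs$SCH$uVNTR, d$allele_freqs$uVNTR,
               tolerance = 1e-12)
  expect_error(inject_effect(d, "SCH", "uVNTR", "4R", 0.9), "outside")
  expect_error(inject_effect(d, "XX", "uVNTR", "4R", 0.1),
               "unknown diagnosis")
})

test_that("a 4R enrichment raises the target group's mean MAOA activity", {
  d <- scaled_patient_design()
  d1 <- inject_effect(d, "SCH", "uVNTR", "4R", 0.3)
  act <- compute_activity(generate_genotypes(d1, seed = 11))
  m <- tapply(act$c_maoa, act$diagnosis, mean)
  expect_gt(m[["SCH"]], m[["BD"]])
  expect_gt(m[["SCH"]], m[["MDD"]])
})

test_that("invalid designs are rejected", {
  cells <- tibble::tibble(diagnosis = "BD", sa_status = "SA", n = 5,
                          n_female = 7)
  expect_error(cohort_design(cells), "n_female")
  af <- default_allele_freqs()
  af$HTTLPR <- c(S = 0.6, L = 0.6)
  expect_error(cohort_design(tiny_patient_design()$cells,
                             allele_freqs = af), "sum to 1")
})
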