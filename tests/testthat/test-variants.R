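test_that("default variant specs carry the published fold-changes", {
  specs <- default_variant_specs()
  get <- function(vid, allele) {
    specs$multiplier[specs$variant_id == vid & specs$allele == allele]
  }
  expect_equal(get("rs111798998", "G"), 3.0)
  expect_equal(get("rs7305115", "A"), 1.7)
  expect_equal(get("rs4290270", "A"), 1 / 1.4)
  expect_equal(get("HTTLPR", "L"), 3.0)
  expect_equal(get("uVNTR", "4R"), 5.5)
  expect_equal(get("uVNTR", "3.5R"), 5.5)
  expect_equal(get("uVNTR", "3R"), 1.0)
  expect_true(all(specs$inheritance[specs$variant_id == "uVNTR"] ==
                    "x_linked"))
  # overrides merge over defaults and are validated
  sp2 <- default_variant_specs(overrides = list(uVNTR = c("4R" = 6)))
  expect_equal(sp2$multiplier[sp2$variant_id == "uVNTR" &
                                sp2$allele == "4R"], 6)
  expect_error(default_variant_specs(overrides = list(uVNTR = c(Q = 2))),
               "unknown allele")
})

test_that("allele pairs combine by arithmetic mean, hemizygous calls pass through", {
  specs <- default_variant_specs()
  htt <- specs[specs$variant_id == "HTTLPR", ]
  expect_equal(variant_coefficient("L/S", htt), 2.0)
  expect_equal(variant_coefficient("S/S", htt), 1.0)
  vntr <- specs[specs$variant_id == "uVNTR", ]
  expect_equal(variant_coefficient("4R", vntr), 5.5)
  expect_equal(variant_coefficient("3R/4R", vntr), 3.25)
  expect_error(variant_coefficient("Q/S", htt), "unknown allele 'Q'")
})

make_genotype <- function(rs111798998 = "A/A", rs4290270 = "T/T",
                          rs7305115 = "G/G", HTTLPR = "S/S", uVNTR = "3R/3R",
                          sex = "female", diagnosis = "BD",
                          sa_status = "SA", sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, sex = sex, diagnosis = diagnosis,
                 sa_status = sa_status, rs111798998 = rs111798998,
                 rs4290270 = rs4290270, rs7305115 = rs7305115,
                 HTTLPR = HTTLPR, uVNTR = uVNTR)
}

test_that("activity coefficients multiply across TPH2 variants and respect X-linkage", {
  # all-reference identity, any sex
  expect_equal(unlist(compute_activity(make_genotype())[, c("c_tph2",
    "c_sert", "c_maoa")]), c(c_tph2 = 1, c_sert = 1, c_maoa = 1))
  expect_equal(compute_activity(make_genotype(sex = "male",
    uVNTR = "3R"))$c_maoa, 1)
  # product-of-means across the three TPH2 variants
  g <- make_genotype(rs111798998 = "G/G", rs7305115 = "A/A")
  expect_equal(compute_activity(g)$c_tph2, 3.0 * 1.7)
  g2 <- make_genotype(rs111798998 = "A/G")
  expect_equal(compute_activity(g2)$c_tph2, 2.0)
  # hemizygous male MAOA
  g3 <- make_genotype(sex = "male", uVNTR = "4R")
  expect_equal(compute_activity(g3)$c_maoa, 5.5)
})

test_that("activity is monotone in single-allele upgrades and bounded", {
  base <- compute_activity(make_genotype())$c_tph2
  up <- compute_activity(make_genotype(rs111798998 = "A/G"))$c_tph2
  upup <- compute_activity(make_genotype(rs111798998 = "G/G"))$c_tph2
  expect_true(base < up && up < upup)
  # exhaustive enumeration of all 27 TPH2 diploid combinations
  calls <- function(a, b) c(paste(a, a, sep = "/"), paste(a, b, sep = "/"),
                            paste(b, b, sep = "/"))
  combos <- expand.grid(v1 = calls("A", "G"), v2 = calls("T", "A"),
                        v3 = calls("G", "A"), stringsAsFactors = FALSE)
  cts <- vapply(seq_len(nrow(combos)), function(i) {
    compute_activity(make_genotype(rs111798998 = combos$v1[i],
                                   rs4290270 = combos$v2[i],
                                   rs7305115 = combos$v3[i]))$c_tph2
  }, numeric(1))
  expect_equal(length(cts), 27L)
  expect_true(all(cts <= 3.0 * 1.7 * 1.0 + 1e-12))
  expect_true(all(cts >= 1 / 1.4 - 1e-12))
  expect_equal(max(cts), 5.1)
})

test_that("genotype validation names the offending row and rule", {
  specs <- default_variant_specs()
  expect_error(validate_genotypes(make_genotype(HTTLPR = "Q/S"), specs),
               "unknown allele 'Q' at variant HTTLPR")
  expect_error(validate_genotypes(make_genotype(sex = "male"), specs),
               "males must carry exactly one uVNTR allele")
  expect_error(validate_genotypes(make_genotype(uVNTR = "3R"), specs),
               "females must carry two")
  expect_error(validate_genotypes(
    make_genotype(diagnosis = "UNAFFECTED", sa_status = "SA"), specs),
    "unaffected individuals must have sa_status NA")
  expect_error(validate_genotypes(
    dplyr::bind_rows(make_genotype(), make_genotype()), specs),
    "duplicate sample_id")
  expect_error(validate_genotypes(make_genotype()[, -5], specs),
               "missing column")
})

test_that("genotype tables round-trip through disk in both delimiters", {
  g <- generate_genotypes(tiny_patient_design(), seed = 7)
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_genotypes(g, path)
    expect_equal(as.data.frame(read_genotypes(path)), as.data.frame(g))
  }
  # unaffected rows keep literal NA sa_status
  cells <- tibble::tibble(diagnosis = "UNAFFECTED", sa_status = NA,
                          n = 4, n_female = 2)
  gu <- generate_genotypes(cohort_design(cells), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gu, path)
  back <- read_genotypes(path)
  expect_true(all(is.na(back$sa_status)))
})

test_that("reachable coefficient grid covers exactly the genotype-expressible triples", {
  grid <- enumerate_activity_grid()
  expect_equal(nrow(grid), 27 * 3 * 3)
  expect_equal(sort(unique(grid$c_sert)), c(1, 2, 3))
  expect_equal(sort(unique(grid$c_maoa)), c(1, 3.25, 5.5))
  expect_equal(max(grid$c_tph2), 5.1)
  expect_equal(min(grid$c_tph2), 1 / 1.4)
})
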