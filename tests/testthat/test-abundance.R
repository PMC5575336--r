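test_that("rarefaction hits the target depth exactly and is idempotent", {
  tab <- toy_table(matrix(c(100, 0, 30, 20), 2))
  r <- rarefy(tab, 10, seed = 1)
  expect_equal(unname(colSums(r$values)), c(10, 10))
  expect_equal(unname(r$values[, 1]), c(10, 0))  # zero stays zero
  # column with total exactly depth is unchanged
  tab2 <- toy_table(matrix(c(6, 4), 2))
  expect_equal(rarefy(tab2, 10, seed = 3)$values, tab2$values)
  expect_equal(rarefy(r, 10, seed = 5)$values, r$values)
  expect_error(rarefy(tab, 0, seed = 1), "> 0")
  expect_warning(rarefy(toy_table(matrix(c(100, 100, 1, 1), 2)), 50, seed = 1),
                 "dropping 1 sample")
})

test_that("rarefying can only lose observed species", {
  set.seed(42)
  base <- rmultinom(1, 50000, prob = rgamma(300, 0.3))
  tab <- toy_table(base)
  obs0 <- alpha_diversity(tab$values[, 1])$observed
  for (s in 1:50) {
    r <- rarefy(tab, 5000, seed = s)
    expect_lte(alpha_diversity(r$values[, 1])$observed, obs0)
  }
})

test_that("singleton removal uses the whole-table total", {
  tab <- toy_table(matrix(c(1, 2, 0, 0, 0, 0), 3))  # totals 1, 2, 0
  out <- remove_singletons(tab)
  expect_equal(rownames(out$values), c("OTU_2", "OTU_3"))  # all-zero kept
  # one read in each of two samples is not a singleton
  tab2 <- toy_table(matrix(c(1, 1), 1, 2))
  expect_equal(nrow(remove_singletons(tab2)$values), 1)
})

test_that("prevalence filter keeps OTUs at the sample threshold", {
  m <- matrix(0, 3, 31)
  m[1, 1:10] <- 1  # present in 10 of 31
  m[2, 1:9] <- 1   # present in 9 of 31
  m[3, 1] <- 1
  tab <- toy_table(m)
  out <- prevalence_filter(tab, 10)
  expect_equal(rownames(out$values), "OTU_1")
  expect_equal(nrow(prevalence_filter(tab, 1)$values), 3)
  expect_error(prevalence_filter(tab, 32), "exceeds")
})

test_that("qPCR scaling renormalizes within domain", {
  tax <- taxonomy_map(data.frame(
    otu_id = c("B1", "B2", "A1"),
    domain = c("Bacteria", "Bacteria", "Archaea"),
    stringsAsFactors = FALSE))
  # single bacterial OTU at rel 1.0 with the beech mean copy number
  tab1 <- toy_table(matrix(1, 1, 1), scale = "relative", otus = "B1")
  q1 <- qpcr_table("S1", bacterial = 6.7e4)
  expect_equal(unname(to_absolute(tab1, tax, q1)$values[1, 1]), 6.7e4)
  # two bacterial OTUs split 0.25 / 0.75 of Q = 1000
  tab2 <- toy_table(matrix(c(0.25, 0.75), 2, 1), scale = "relative",
                    otus = c("B1", "B2"))
  q2 <- qpcr_table("S1", bacterial = 1000)
  expect_equal(unname(to_absolute(tab2, tax, q2)$values[, 1]), c(250, 750))
  # archaeal OTU at rel 0.01 within archaeal mass 0.02, Q_arc = 2e3
  tab3 <- toy_table(matrix(c(0.49, 0.49, 0.01, 0.01), 4, 1),
                    scale = "relative", otus = c("B1", "B2", "A1", "A2"))
  tax3 <- taxonomy_map(data.frame(
    otu_id = c("B1", "B2", "A1", "A2"),
    domain = c("Bacteria", "Bacteria", "Archaea", "Archaea"),
    stringsAsFactors = FALSE))
  q3 <- qpcr_table("S1", bacterial = 1e4, archaeal = 2e3)
  expect_equal(unname(to_absolute(tab3, tax3, q3)$values["A1", 1]), 1e3)
  # pooled mode scales the raw relative abundance by summed copies
  abs_pooled <- to_absolute(tab3, tax3, q3, mode = "pooled")
  expect_equal(unname(abs_pooled$values["A1", 1]), 0.01 * 1.2e4)
  expect_error(to_absolute(tab1, tax, qpcr_table("S9", bacterial = 1)),
               "missing from qPCR")
})

test_that("absolute scaling preserves within-domain relative profiles", {
  set.seed(8)
  m <- matrix(rlnorm(40), 8, 5)
  tax <- taxonomy_map(data.frame(
    otu_id = paste0("OTU_", 1:8),
    domain = rep(c("Bacteria", "Archaea"), each = 4),
    stringsAsFactors = FALSE))
  rel <- to_relative(toy_table(m))
  q <- qpcr_table(paste0("S", 1:5), bacterial = runif(5, 1e4, 1e5),
                  archaeal = runif(5, 1e2, 1e3))
  abs_tab <- to_absolute(rel, tax, q)
  for (d in c("Bacteria", "Archaea")) {
    rows <- which(tax$domain == d)
    prof_in <- sweep(rel$values[rows, ], 2, colSums(rel$values[rows, ]), "/")
    prof_out <- sweep(abs_tab$values[rows, ], 2,
                      colSums(abs_tab$values[rows, ]), "/")
    expect_equal(prof_out, prof_in, tolerance = 1e-12)
  }
})

test_that("alpha diversity matches the closed forms", {
  a <- alpha_diversity(c(5, 5, 5, 5))
  expect_equal(a$observed, 4)
  expect_equal(a$chao1, 4)
  expect_equal(a$shannon, log(4))
  expect_equal(alpha_diversity(c(1, 1, 2))$chao1, 3.5)
  expect_equal(alpha_diversity(c(3, 4, 9))$chao1, 3)  # no singletons
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
  # shannon agrees with vegan
  set.seed(2)
  v <- rpois(20, 4)
  v[1] <- 1
  expect_equal(alpha_diversity(v)$shannon,
               unname(vegan::diversity(v[v > 0])))
})

test_that("chao1 never falls below observed richness", {
  set.seed(31)
  for (r in 1:60) {
    v <- rpois(50, rexp(50, 0.2))
    if (all(v == 0)) v[1] <- 1
    a <- alpha_diversity(v)
    expect_gte(a$chao1, a$observed)
  }
  # shannon is maximal for the uniform vector of given richness
  expect_gt(alpha_diversity(rep(7, 9))$shannon,
            alpha_diversity(c(rep(1, 8), 55))$shannon)
})

test_that("standard curves quantify and report efficiency", {
  copies <- 10^(1:6)
  curve <- fit_standard_curve(copies, 40 - 3.3219 * log10(copies))
  expect_equal(curve$slope, -3.3219, tolerance = 1e-6)
  expect_equal(amplification_efficiency(curve), 100, tolerance = 1e-2)
  expect_equal(curve$r_squared, 1)
  # 10-fold series with Ct step 3.5
  curve2 <- fit_standard_curve(copies, 42 - 3.5 * log10(copies))
  expect_equal(curve2$slope, -3.5, tolerance = 1e-9)
  expect_equal(amplification_efficiency(curve2), 93.07, tolerance = 1e-2)
  # inversion: ct at the intercept corresponds to one copy
  curve3 <- fit_standard_curve(copies, 40 - 3.3219 * log10(copies))
  expect_equal(quantify_copies(curve3, 40), 1, tolerance = 1e-6)
  expect_error(fit_standard_curve(copies, 10 + 2 * log10(copies)),
               "invalid qPCR curve")
  expect_error(fit_standard_curve(c(10, 20, 30), c(30, 29, 28)),
               "orders of magnitude")
})
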