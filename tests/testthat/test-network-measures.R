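test_that("association scores match their independent oracles", {
  set.seed(14)
  m <- matrix(rlnorm(100), 10, 10)
  tab <- toy_table(m, scale = "absolute")
  # Spearman: rank rows, then Pearson
  sp <- score_all_pairs(tab, "spearman")
  ranks <- t(apply(m, 1, rank))
  sp_oracle <- cor(t(ranks))
  diag(sp_oracle) <- NA
  dimnames(sp_oracle) <- dimnames(sp)
  expect_equal(sp, sp_oracle, tolerance = 1e-12)
  # Pearson straight from cor()
  pe <- score_all_pairs(tab, "pearson")
  pe_oracle <- cor(t(m))
  diag(pe_oracle) <- NA
  dimnames(pe_oracle) <- dimnames(pe)
  expect_equal(pe, pe_oracle, tolerance = 1e-12)
  # Bray-Curtis against vegan
  bc <- score_all_pairs(tab, "braycurtis")
  bc_oracle <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(bc_oracle) <- NA
  dimnames(bc_oracle) <- dimnames(bc)
  expect_equal(bc, bc_oracle, tolerance = 1e-12)
  # KL and MI against plain-R oracles
  kl <- score_all_pairs(tab, "kl")
  mi <- score_all_pairs(tab, "mi")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(kl[i, j], oracle_kl(m[i, ], m[j, ]), tolerance = 1e-12)
    expect_equal(mi[i, j], oracle_mi(m[i, ], m[j, ]), tolerance = 1e-12)
  }
})

test_that("degenerate and boundary scores behave", {
  x <- c(1, 2, 4, 5, 6, 9)  # increasing, so rev(x) is a monotone flip
  tab <- toy_table(rbind(x, x, rev(x)), scale = "absolute")
  s <- score_all_pairs(tab, "spearman")
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], -1)
  expect_equal(score_all_pairs(tab, "pearson")[1, 2], 1)
  expect_equal(score_all_pairs(tab, "braycurtis")[1, 2], 0)
  expect_equal(score_all_pairs(tab, "kl")[1, 2], 0)
  # constant row: correlation undefined, pair skipped with a message
  tabc <- toy_table(rbind(x, rep(2, 6)), scale = "absolute")
  expect_message(sc <- score_all_pairs(tabc, "pearson"), "skipped")
  expect_true(is.na(sc[1, 2]))
  expect_error(score_all_pairs(toy_table(matrix(1:6, 2, 3)), "spearman"),
               ">= 4 samples")
  expect_error(score_all_pairs(tab, "kendall"), "unknown measure")
})

test_that("candidate selection takes top and bottom with tie inclusion", {
  ids <- paste0("O", 1:5)  # 10 pairs
  s <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0)
  s[upper.tri(s)] <- vals
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  cand <- candidate_edges(list(pearson = s), top_n = 2, bottom_n = 2)
  expect_equal(nrow(cand), 4)
  expect_true(all(cand$proposed_by == "pearson"))
  # tie at the cutoff: all tied pairs included
  s2 <- s
  s2[upper.tri(s2)] <- c(0.9, 0.8, 0.8, 0.8, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0)
  s2[lower.tri(s2)] <- t(s2)[lower.tri(s2)]
  cand2 <- candidate_edges(list(pearson = s2), top_n = 2, bottom_n = 0)
  expect_equal(nrow(cand2), 4)  # 0.9 plus three tied 0.8
  # a pair proposed by several measures is tagged with exactly those
  cand3 <- candidate_edges(list(pearson = s, spearman = s, mi = -s),
                           top_n = 1, bottom_n = 0)
  top_pair <- cand3[cand3$proposed_by == "pearson,spearman", ]
  expect_equal(nrow(top_pair), 1)
  # fewer pairs than requested: everything becomes a candidate
  expect_message(cand4 <- candidate_edges(list(pearson = s), 8, 8),
                 "all become candidates")
  expect_equal(nrow(cand4), 10)
})

test_that("permutation p-values hit the documented boundaries", {
  pp <- nitroguild:::perm_pvalue
  # observed equal to every null score
  expect_equal(pp(0.5, rep(0.5, 100), "pearson"), 1)
  # observed beyond every null score: minimum attainable p
  expect_equal(pp(0.99, runif(100, -0.3, 0.3), "pearson"), 1 / 101)
  expect_equal(pp(-0.99, runif(100, -0.3, 0.3), "spearman"), 1 / 101)
  set.seed(1)
  # calibration: p is discrete-uniform under exchangeability
  p <- replicate(2000, pp(rnorm(1), rnorm(100), "pearson"))
  expect_lt(abs(mean(p) - mean((2:102) / 101)), 0.02)
})

test_that("strongly coupled rows are stable, independent rows are not", {
  set.seed(77)
  stable_true <- stable_false <- logical(40)
  p_true <- numeric(40)
  for (r in 1:40) {
    rows <- coupled_rows(30, 0.95)
    tab <- sample_table(rows, scale = "absolute")
    st <- edge_null_and_stability(tab, rownames(tab$values), "spearman",
                                  seed = r)
    stable_true[r] <- st$stable
    p_true[r] <- st$p_perm
    tab0 <- sample_table(rbind(a = rlnorm(30), b = rlnorm(30)),
                         scale = "absolute")
    stable_false[r] <- edge_null_and_stability(tab0, c("a", "b"),
                                               "spearman", seed = r)$stable
  }
  expect_gte(mean(stable_true), 0.95)
  expect_gte(mean(p_true == 1 / 101), 0.95)
  expect_gte(mean(!stable_false), 0.90)
})

test_that("edge statistics are reproducible under a fixed seed", {
  tab <- sample_table(rbind(a = rlnorm(20), b = rlnorm(20)),
                      scale = "absolute")
  s1 <- edge_null_and_stability(tab, c("a", "b"), "mi", seed = 9)
  s2 <- edge_null_and_stability(tab, c("a", "b"), "mi", seed = 9)
  expect_identical(s1, s2)
})

test_that("inferred networks recover a planted block and sign it", {
  sim <- generate_community(20, 30, blocks = list(1:5), block_rho = 0.9,
                            depth = 5000, seed = 21)
  net <- suppressWarnings(suppressMessages(
    infer_network(sim$absolute, seed = 21)))
  truth <- combn(sort(sprintf("OTU_%04d", 1:5)), 2)
  truth_keys <- paste(truth[1, ], truth[2, ])
  ret <- net$edges[net$edges$retained, ]
  keys <- paste(ret$otu_a, ret$otu_b)
  expect_gte(mean(truth_keys %in% keys), 0.8)
  expect_true(all(ret$sign[keys %in% truth_keys] == "co-presence"))
  # within-block mean Spearman exceeds between-block mean
  sp <- suppressMessages(score_all_pairs(sim$absolute, "spearman"))
  within <- sp[1:5, 1:5][upper.tri(sp[1:5, 1:5])]
  between <- sp[1:5, 6:20]
  expect_gt(mean(within), mean(between))
})
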