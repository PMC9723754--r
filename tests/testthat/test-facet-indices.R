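test_that("diversity indices match direct summation and vegan on toys", {
  m <- toy_counts()
  d <- diversity_indices(m)

  # brute-force oracle: -sum p log p
  x <- c(5, 3, 2); p <- x / sum(x)
  expect_equal(d$H[d$sample == "mixed"], -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(d$G[d$sample == "mixed"], sum(p^2), tolerance = 1e-12)

  # independent cross-check against vegan
  expect_equal(d$H, unname(vegan::diversity(t(m), index = "shannon")),
               tolerance = 1e-12)

  # uniform community: H = ln S, J = 1
  u <- matrix(rep(3L, 8), ncol = 1, dimnames = list(NULL, "u"))
  du <- diversity_indices(u)
  expect_equal(du$H, log(8), tolerance = 1e-12)
  expect_identical(du$J, 1)
  expect_identical(du$S, 8L)

  # monodominant community: H = 0, J = 0, dominance maximal
  mono <- d[d$sample == "mono", ]
  expect_identical(mono$H, 0)
  expect_identical(mono$J, 0)
  expect_identical(mono$S, 1L)
  expect_identical(mono$G, 1)

  expect_error(diversity_indices(matrix(0L, 2, 1)), "zero total")
})

test_that("rarefaction preserves depth, identity cases and the hypergeometric mean", {
  m <- toy_counts()  # totals 19, 7, 10... columns mixed=10? totals: 5+4+10=19
  one <- matrix(c(0L, 0L, 12L), ncol = 1, dimnames = list(NULL, "s"))
  r1 <- rarefy_counts(one, depth = 10, seed = 1)
  expect_identical(unname(r1[, 1]), c(0L, 0L, 10L))

  # sample total exactly at depth is untouched
  m2 <- matrix(c(6L, 3L, 1L), ncol = 1, dimnames = list(NULL, "a"))
  expect_identical(rarefy_counts(m2, depth = 10, seed = 3), m2)

  # every retained column sums to depth; shallow samples dropped w/ warning
  m3 <- cbind(m2, b = c(2L, 1L, 0L))
  expect_warning(r3 <- rarefy_counts(m3, depth = 5, seed = 2), "dropped")
  expect_identical(colnames(r3), "a")
  expect_identical(sum(r3), 5L)
  expect_error(rarefy_counts(m3, depth = 5, seed = 2, drop_below = FALSE),
               "below depth")
  expect_error(rarefy_counts(m2, depth = 0), "positive integer")

  # Monte-Carlo hypergeometric mean on the (6,3,1) toy at depth 5:
  # E[retained count of taxon 1] = 5 * 6/10 = 3
  reps <- 10000
  big <- matrix(rep(c(6L, 3L, 1L), reps), nrow = 3,
                dimnames = list(NULL, paste0("r", seq_len(reps))))
  rb <- rarefy_counts(big, depth = 5, seed = 99)
  expect_equal(mean(rb[1, ]), 3.0, tolerance = 0.05)

  # determinism given seed
  expect_identical(rarefy_counts(big[, 1:50], depth = 5, seed = 7),
                   rarefy_counts(big[, 1:50], depth = 5, seed = 7))
})

test_that("biomass summaries follow group sums and flag zero fungal biomass", {
  map <- plfa_marker_map()
  plfa <- toy_plfa()
  bs <- biomass_summary(plfa, map)

  # brute-force oracle
  kingdom <- map$kingdom[match(rownames(plfa), map$marker)]
  expect_equal(bs$total_biomass, unname(colSums(plfa)), tolerance = 1e-12)
  expect_equal(bs$bf_ratio,
               unname(colSums(plfa[kingdom == "bacteria", ]) /
                      colSums(plfa[kingdom == "fungi", ])),
               tolerance = 1e-12)

  # equal bacterial and fungal sums give B:F = 1
  m <- matrix(0, nrow(map), 1, dimnames = list(map$marker, "s1"))
  m[map$kingdom == "bacteria", 1] <- 10 / sum(map$kingdom == "bacteria")
  m[map$kingdom == "fungi", 1] <- 10 / sum(map$kingdom == "fungi")
  expect_equal(biomass_summary(m, map)$bf_ratio, 1)

  # zero fungal biomass: NA, not Inf
  m[map$kingdom == "fungi", 1] <- 0
  expect_warning(bs0 <- biomass_summary(m, map), "zero fungal")
  expect_true(is.na(bs0$bf_ratio))

  expect_error(biomass_summary(matrix(1, 1, 1, dimnames = list("xx", "s")),
                               map), "not covered")
})

test_that("gene scores honor the scaling scheme and evenness definition", {
  # two-point min-max scaling
  g <- matrix(c(0, 10), 1, 2, dimnames = list("gA", c("s1", "s2")))
  gs <- gene_scores(g, catabolic = "gA")
  expect_equal(gs$cata_score, c(0, 1))
  expect_identical(attr(gs, "scaling"), "minmax")

  # sample with all genes equal is perfectly even
  ge <- matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
               dimnames = list(paste0("g", 1:3), c("even", "uneven")))
  expect_equal(gene_scores(ge)$fg_evenness[1], 1)

  # 3-gene toy against hand-computed column-wise min-max sums
  gm <- matrix(c(1, 4, 2,
                 3, 0, 5,
                 2, 2, 2), 3, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  hand <- rbind((gm[1, ] - 1) / 3, (gm[2, ] - 0) / 5)  # g3 constant -> 0
  expect_message(gs3 <- gene_scores(gm, catabolic = c("g1", "g2", "g3")),
                 "constant gene")
  expect_equal(gs3$cata_score, unname(colSums(hand)), tolerance = 1e-12)

  # z-score alternative: per-gene mean 0, sd 1
  gz <- suppressMessages(gene_scores(gm, scaling = "zscore"))
  expect_identical(attr(gz, "scaling"), "zscore")

  # cata_score under minmax is bounded by the number of catabolic genes
  set.seed(1)
  gr <- matrix(rexp(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
  expect_true(all(gene_scores(gr)$cata_score >= 0 - 1e-12))
  expect_true(all(gene_scores(gr)$cata_score <= 4 + 1e-12))
  expect_error(gene_scores(gm[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("SIR efficiency and range behave as evenness and signed difference", {
  subs <- microresp_substrates()$substrate
  even <- matrix(2, 14, 1, dimnames = list(subs, "e"))
  expect_equal(unname(sir_efficiency(even)), 1)

  onehot <- matrix(0, 14, 1, dimnames = list(subs, "o"))
  onehot["glucose", 1] <- 5
  expect_identical(unname(sir_efficiency(onehot)), 0)

  # direct-formula oracle on a 3-substrate vector
  v3 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  p <- c(1, 2, 3) / 6
  expect_equal(unname(sir_efficiency(v3)), -sum(p * log(p)) / log(3),
               tolerance = 1e-12)

  m <- toy_microresp()
  expect_equal(unname(sir_range(m)),
               unname(m["oxalic acid", ] - m["alanine", ]))
  # antisymmetry under substrate swap, on random inputs
  expect_equal(sir_range(m, upper = "alanine", lower = "oxalic acid"),
               -sir_range(m))
  eq <- matrix(5, 14, 1, dimnames = list(subs, "s"))
  expect_identical(unname(sir_range(eq)), 0)
  expect_error(sir_range(m[1:3, ]), "oxalic acid")

  # permutation invariance of efficiency over substrates
  perm <- sample(14)
  expect_equal(sir_efficiency(m[perm, ]), sir_efficiency(m))
})

test_that("substrate-selection sensitivity matches brute-force recomputation", {
  m <- toy_microresp(n_samples = 10, seed = 3)
  full <- substrate_sensitivity(m, scheme = "loo")
  expect_equal(nrow(full), 14)
  # brute-force oracle on a 4-substrate toy
  m4 <- m[c("glucose", "alanine", "oxalic acid", "citric acid"), ]
  s4 <- substrate_sensitivity(m4, scheme = "loo")
  for (i in seq_len(4)) {
    sub <- m4[-i, , drop = FALSE]
    expect_equal(s4$cor_efficiency[i],
                 cor(sir_efficiency(sub), sir_efficiency(m4)),
                 tolerance = 1e-12)
  }
  # dropping a range substrate blanks the range correlation
  expect_true(is.na(s4$cor_range[s4$subset == "drop:oxalic acid"]))

  # random scheme deterministic under a fixed seed
  r1 <- substrate_sensitivity(m, scheme = "random", k = 6, reps = 20, seed = 5)
  r2 <- substrate_sensitivity(m, scheme = "random", k = 6, reps = 20, seed = 5)
  expect_identical(r1, r2)
  expect_error(substrate_sensitivity(m, scheme = "random", k = 1, reps = 2),
               "fewer than 2")
})

test_that("soil stoichiometry is the elementwise ratio with NA on zero denominators", {
  s <- soil_stoichiometry(c(20, 3), c(2, 3), c(1, 1))
  expect_equal(s$cn, c(10, 1))
  expect_equal(s$cp, c(20, 3))
  # vectorized equals a scalar loop
  set.seed(4)
  toc <- runif(20, 5, 40); tn <- runif(20, 0.5, 3); tp <- runif(20, 0.1, 1)
  v <- soil_stoichiometry(toc, tn, tp)
  loop <- vapply(seq_len(20), function(i)
    soil_stoichiometry(toc[i], tn[i], tp[i])$cn, numeric(1))
  expect_equal(v$cn, loop, tolerance = 1e-15)
  expect_warning(z <- soil_stoichiometry(1, 0, 1), "zero TN or TP")
  expect_true(is.na(z$cn))
})
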