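test_that("abundance simulation: determinism, effects, truth table", {
  a <- simulate_abundances(50, 4, effects = list(n_site = 5), seed = 3)
  b <- simulate_abundances(50, 4, effects = list(n_site = 5), seed = 3)
  expect_identical(a$mat, b$mat)
  expect_equal(dim(a$mat), c(50L, 16L))
  expect_equal(sum(a$truth$site_de), 5L)
  # no effects: truth has no DE proteins
  z <- simulate_abundances(20, 3, seed = 1)
  expect_false(any(z$truth$site_de | z$truth$age_de_both))
  # a +1.79 site effect is recovered in expectation
  big <- simulate_abundances(200, 12,
                             effects = list(n_site = 50,
                                            site_effect = 1.79), seed = 9)
  fc <- group_log2fc(big$mat, big$design, "mand_vs_sub_mean")
  expect_lt(abs(mean(fc[big$truth$site_de]) - 1.79), 0.15)
  expect_lt(abs(mean(fc[!big$truth$site_de])), 0.1)
  expect_error(simulate_abundances(10, 1))
})

test_that("log2 fold changes are group-mean differences", {
  sim <- simulate_abundances(10, 4, seed = 5)
  mat <- sim$mat
  # identical groups: zero fold change
  mat[1, ] <- 7
  fc <- group_log2fc(mat, sim$design, "mand_vs_sub_mean")
  expect_equal(unname(fc[1]), 0)
  # linear means 8 vs 2 on the log2 scale: log2(8) - log2(2) = 2
  mat[2, sim$design$site == "mandibular"] <- log2(8)
  mat[2, sim$design$site == "subiliac"] <- log2(2)
  fc <- group_log2fc(mat, sim$design, "mand_vs_sub_mean")
  expect_equal(unname(fc[2]), 2)
  # reversed contrast flips the sign
  fc_rev <- group_log2fc(mat, sim$design, "sub_vs_mand_mean")
  expect_equal(unname(fc_rev[2]), -2)
  expect_error(group_log2fc(mat, sim$design, "bogus"), "unknown contrast")
  # the canonical fold-change report: 2^1.79 prints as 3.46
  expect_equal(round(2^1.79, 2), 3.46)
})

test_that("adaptive test gates on Shapiro-Wilk and routes correctly", {
  sim <- simulate_abundances(30, 3, seed = 11)
  mat <- sim$mat
  # force the Wilcoxon branch with an impossible normality gate:
  # {1,2,3} vs {4,5,6} has exact two-sided p = 0.1
  mat[1, sim$design$site == "mandibular" &
        sim$design$age == "young"] <- c(1, 2, 3)
  mat[1, sim$design$site == "subiliac" &
        sim$design$age == "young"] <- c(4, 5, 6)
  rows <- adaptive_test(mat, sim$design, "mand_vs_sub_young",
                        alpha_norm = 1)
  expect_true(all(rows$test_used == "wilcoxon"))
  expect_equal(rows$p[rows$protein_id == rownames(mat)[1]], 0.1)
  # identical groups give p = 1 under either branch
  mat[2, sim$design$age == "young"] <- rep(c(10, 11, 12), 2)
  for (al in c(1, 0)) {
    r2 <- adaptive_test(mat, sim$design, "mand_vs_sub_young",
                        alpha_norm = al)
    expect_equal(r2$p[r2$protein_id == rownames(mat)[2]], 1)
  }
  # zero-variance groups route to Wilcoxon
  mat[3, sim$design$age == "young" & sim$design$site == "mandibular"] <- 5
  r3 <- adaptive_test(mat, sim$design, "mand_vs_sub_young",
                      alpha_norm = 0.05)
  expect_equal(r3$test_used[r3$protein_id == rownames(mat)[3]], "wilcoxon")
  expect_error(adaptive_test(sim$mat[, 1:4],
                             sim$design[1:4, ], "mand_vs_sub_young"),
               "n >= 3")
})

test_that("missingness filter drops sparsely quantified proteins", {
  sim <- simulate_abundances(20, 5, seed = 13)
  mat <- sim$mat
  idx <- which(sim$design$site == "mandibular")[1:5]
  mat[1, idx] <- NA   # 50% missing in the mandibular group (< 60% quantified)
  rows <- adaptive_test(mat, sim$design, "mand_vs_sub_mean")
  expect_false(rownames(mat)[1] %in% rows$protein_id)
  expect_equal(nrow(rows), 19L)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # invariant to input order
  ord <- sample.int(100)
  expect_equal(bh_adjust(p[ord]), q[ord])
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("age-independent filter removes jointly age-up proteins only", {
  mk <- function(ids, fc, q) data.frame(protein_id = ids, log2fc = fc,
                                        p = q, q = q)
  ids <- paste0("P", 1:5)
  site <- mk(ids, c(2, 2, 2, 2, 2), rep(0.01, 5))
  # P1 and P2 age-up in both sites; P3 only in one; P4/P5 null
  mand <- mk(ids, c(1, 1, 1, -1, 0), c(0.01, 0.01, 0.01, 0.01, 0.9))
  sub <- mk(ids, c(1, 1, -1, 1, 0), c(0.01, 0.01, 0.01, 0.01, 0.9))
  out <- age_independent_filter(site, mand, sub)
  expect_setequal(out$removed, c("P1", "P2"))
  expect_equal(nrow(out$rows), 3L)
  # no protein age-up in both: untouched
  out2 <- age_independent_filter(site, mk(ids, rep(-1, 5), rep(0.01, 5)),
                                 sub)
  expect_equal(out2$rows, site)
  # all proteins age-up in both: empty
  out3 <- age_independent_filter(site, mk(ids, rep(1, 5), rep(0.01, 5)),
                                 mk(ids, rep(1, 5), rep(0.01, 5)))
  expect_equal(nrow(out3$rows), 0L)
  expect_error(age_independent_filter(site, mand[1:4, ], sub), "universes")
})

test_that("volcano categories follow the fold/significance bands", {
  rows <- data.frame(protein_id = c("MZB1-like", "b", "c", "d"),
                     log2fc = c(1.79, log2(1.7), log2(3), -1.79),
                     q = c(0.01, 0.01, 0.2, 0.01))
  v <- volcano_table(rows)
  expect_equal(v$category, c("strong", "moderate", "none", "strong"))
  expect_equal(v$fold[1], 3.46)
})

test_that("ssGSEA matches a direct running-sum oracle and is rank-invariant", {
  m <- matrix(c(5, 4, 3, 2, 1, 1, 2, 3, 4, 5), 5, 2,
              dimnames = list(paste0("P", 1:5), c("s1", "s2")))
  ss <- ssgsea_scores(m, list(top = c("P1", "P2")), weight_alpha = 0.25)
  # direct summation oracle for sample 1
  r <- c(5, 4, 3, 2, 1)
  w <- r^0.25
  inset <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  oracle <- sum(cumsum(w * inset) / sum(w[inset]) - cumsum(!inset) / 3)
  expect_equal(unname(ss$scores["top", "s1"]), oracle, tolerance = 1e-12)
  # invariance under strictly monotone transform of one sample
  m2 <- m
  m2[, 1] <- exp(m2[, 1]) + 100
  ss2 <- ssgsea_scores(m2, list(top = c("P1", "P2")), 0.25)
  expect_equal(ss$scores[, 1], ss2$scores[, 1])
  # a top-ranked set outscores a bottom-ranked set in every sample
  both <- ssgsea_scores(m, list(top = c("P1", "P2"),
                                bottom = c("P4", "P5")), 0.25)
  expect_equal(unname(both$scores["top", "s1"] >
                      both$scores["bottom", "s1"]), TRUE)
  expect_equal(unname(both$scores["top", "s2"] <
                      both$scores["bottom", "s2"]), TRUE)
  expect_error(ssgsea_scores(m, list(x = "NOPE")), "empty intersection")
})

test_that("pre-ranked GSEA: degenerate set, closed-form top-k, determinism", {
  ts <- setNames(seq(10, 1, length.out = 10), paste0("P", 1:10))
  # whole-universe set has zero enrichment
  g <- preranked_gsea(ts, list(all = paste0("P", 1:10)), nperm = 100,
                      seed = 1)
  expect_equal(g$es, 0)
  # set occupying the top k ranks: ES equals the running-sum maximum at k
  k <- 3
  w <- abs(ts)
  es_closed <- sum(w[1:k]) / sum(w[1:k]) - 0   # P_hit(k) - P_miss(k)
  g2 <- preranked_gsea(ts, list(topk = paste0("P", 1:k)), nperm = 100,
                       seed = 1)
  expect_equal(g2$es, es_closed)
  # determinism given a seed
  g3 <- preranked_gsea(ts, list(topk = paste0("P", 1:k)), nperm = 100,
                       seed = 1)
  expect_identical(g2, g3)
  expect_error(preranked_gsea(ts, list(x = paste0("Q", 1:3)), nperm = 100))
})

test_that("pre-ranked ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  ts <- setNames(rnorm(60), paste0("P", 1:60))
  sets <- list(a = paste0("P", 1:9), b = paste0("P", c(3, 12, 40, 55)))
  mine <- preranked_gsea(ts, sets, nperm = 100, seed = 2)
  st <- sort(ts, decreasing = TRUE)
  for (i in seq_along(sets)) {
    ref <- fgsea::calcGseaStat(st, which(names(st) %in% sets[[i]]),
                               gseaParam = 1)
    expect_equal(mine$es[i], ref, tolerance = 1e-9)
  }
})

test_that("score group tests: separation, identity, BH bound", {
  scores <- rbind(sep = c(1, 2, 3, 10, 11, 12),
                  same = rep(5, 6))
  design <- data.frame(site = rep(c("mandibular", "subiliac"), each = 3))
  out <- group_test_scores(scores, design, "site")
  expect_equal(out$p[out$set == "sep"], 0.1)   # exact rank enumeration
  expect_equal(out$p[out$set == "same"], 1)
  expect_true(all(out$q >= out$p))
  expect_error(group_test_scores(scores,
                                 data.frame(site = rep("a", 6)), "site"))
})

test_that("simulation-based error control: FDR and power at q <= 0.05", {
  sim <- simulate_abundances(400, 10,
                             effects = list(n_site = 60,
                                            site_effect = 1.5), seed = 23)
  rows <- adaptive_test(sim$mat, sim$design, "mand_vs_sub_mean")
  hits <- rows$protein_id[rows$q <= 0.05]
  truth <- sim$truth$protein_id[sim$truth$site_de]
  fdr <- if (length(hits)) mean(!hits %in% truth) else 0
  power <- mean(truth %in% hits)
  expect_lte(fdr, 0.10)
  expect_gt(power, 0.8)
})

test_that("total-abundance normalization equalizes column sums before log2", {
  set.seed(25)
  m <- matrix(rexp(60, 1 / 1000), 10, 6)
  m[, 2] <- m[, 2] * 3
  out <- normalize_total(m, log2_transform = FALSE)
  expect_equal(diff(range(colSums(out))), 0, tolerance = 1e-9)
  lg <- normalize_total(m)
  expect_true(all(is.na(lg) | lg > 0))
  expect_error(normalize_total(matrix(c(0, 0, 1, 1), 2)))
})

test_that("over-representation test matches the hypergeometric tail", {
  universe <- paste0("P", 1:100)
  sel <- paste0("P", 1:10)
  sets <- list(hit = paste0("P", 1:5), miss = paste0("P", 90:99))
  out <- overrepresentation_test(sel, universe, sets)
  expect_equal(out$p[1], phyper(4, 5, 95, 10, lower.tail = FALSE))
  expect_gt(out$p[2], 0.5)
  expect_true(all(out$q >= out$p))
})
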