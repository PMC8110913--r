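mk_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(mirna = r[[1]], target = r[[2]], kind = r[[3]],
               score = as.numeric(r[[4]]),
               source = if (length(r) > 4) r[[5]] else "src",
               stringsAsFactors = FALSE)))
}
mk_de <- function(genes, dirs) {
  data.frame(gene = genes, kind = "mRNA", signed_fc = 3, p_value = 0.01,
             direction = dirs, stringsAsFactors = FALSE)
}
mk_cat <- function(mirnas) {
  data.frame(mirna = mirnas, direction = "up", status = "retained",
             stringsAsFactors = FALSE)
}

test_that("score filtering is strict and respects catalogue and DE sets", {
  edges <- mk_edges(list("m1", "g1", "mRNA", 80),     # exactly at cutoff
                    list("m1", "g2", "mRNA", 80.01),
                    list("m2", "g2", "mRNA", 95),     # m2 not retained
                    list("m1", "g3", "mRNA", 95))     # g3 not DE
  out <- filter_targets(edges, mk_cat("m1"),
                        mk_de(c("g1", "g2"), c("up", "down")))
  expect_equal(out$target, "g2")
  expect_equal(out$score, 80.01)
})

test_that("cross-source duplicates collapse to the maximum score", {
  edges <- mk_edges(list("m1", "g1", "mRNA", 85, "db_a"),
                    list("m1", "g1", "mRNA", 92, "db_b"))
  out <- filter_targets(edges, mk_cat("m1"), mk_de("g1", "up"))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 92)
  expect_equal(out$source, "db_b")
})

test_that("filtering is a subset operation and idempotent", {
  set.seed(21)
  edges <- data.frame(mirna = sample(sprintf("m%d", 1:4), 30, TRUE),
                      target = sample(sprintf("g%d", 1:6), 30, TRUE),
                      kind = "mRNA", score = runif(30, 0, 100),
                      source = "s", stringsAsFactors = FALSE)
  cat <- mk_cat(c("m1", "m2"))
  de <- mk_de(sprintf("g%d", 1:4), rep(c("up", "down"), 2))
  once <- filter_targets(edges, cat, de)
  expect_true(all(paste(once$mirna, once$target) %in%
                    paste(edges$mirna, edges$target)))
  twice <- filter_targets(once, cat, de)
  attr(twice, "thresholds") <- attr(once, "thresholds")
  expect_identical(once, twice)
  expect_equal(nrow(filter_targets(edges[0, ], cat, de)), 0)
  bad <- edges; bad$kind[1] <- "circRNA"
  expect_error(filter_targets(bad, cat, de), "unknown target kind")
})

test_that("lncRNA cutoff defaults to the upper decile of supplied scores", {
  edges <- data.frame(mirna = "m1", target = sprintf("l%d", 1:20),
                      kind = "lncRNA", score = 1:20 * 10, source = "s",
                      stringsAsFactors = FALSE)
  de <- data.frame(gene = sprintf("l%d", 1:20), kind = "lncRNA",
                   signed_fc = 3, p_value = 0.01, direction = "up",
                   stringsAsFactors = FALSE)
  out <- filter_targets(edges, mk_cat("m1"), de)
  cut <- attr(out, "thresholds")[["lncRNA"]]
  expect_equal(cut, unname(quantile(edges$score, 0.9)))
  expect_true(all(out$score > cut))
})

test_that("generator's planted edges survive filtering, decoys do not", {
  cfg <- sim_config(noise_sd = 0, conflict_fraction = 0,
                    missing_db_fraction = 0, seed = 3)
  b <- generate_bundle(cfg)
  de_l <- de_screen(b$lnc_mat, b$groups, kind = "lncRNA")
  de_m <- de_screen(b$mrna_mat, b$groups, kind = "mRNA")
  cat <- retained_mirnas(reconcile_mirna(b$mirna_evidence, b$db_universe))
  mrna_f <- filter_targets(b$mrna_edges, cat, de_m)
  planted <- b$ground_truth$planted_triplets
  expect_true(all(paste(planted$mirna, planted$mrna) %in%
                    paste(mrna_f$mirna, mrna_f$target)))
  dec <- b$ground_truth$decoys
  at_cut <- dec[dec$reason == "mrna_score_at_cutoff", ]
  expect_false(paste(at_cut$mirna, at_cut$mrna) %in%
                 paste(mrna_f$mirna, mrna_f$target))
  lnc_f <- filter_targets(b$lnc_edges, cat, de_l)
  low <- dec[dec$reason == "lnc_score_below_cutoff", ]
  expect_false(paste(low$mirna, low$lncrna) %in%
                 paste(lnc_f$mirna, lnc_f$target))
})

test_that("correlation matches the direct covariance formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 2, 3, 4, 5, 7)
  lnc <- matrix(x, 1, dimnames = list("l1", sprintf("S%d", 1:6)))
  mr <- matrix(y, 1, dimnames = list("g1", sprintf("S%d", 1:6)))
  de_l <- data.frame(gene = "l1", signed_fc = 3, p_value = .01,
                     direction = "up")
  de_m <- data.frame(gene = "g1", signed_fc = 3, p_value = .01,
                     direction = "up")
  out <- coexpression_pairs(lnc, mr, de_l, de_m, r_threshold = 0.9)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  t_or <- r_oracle * sqrt(4 / (1 - r_oracle^2))
  expect_equal(out$p_value, 2 * pt(abs(t_or), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$n, 6L)
})

test_that("collinear pairs hit r = 1, anti-correlated pairs are excluded", {
  s <- sprintf("S%d", 1:6)
  lnc <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("l1", s))
  mr <- rbind(g_pos = 2 * c(1, 2, 3, 4, 5, 6) + 3,
              g_neg = 14 - c(1, 2, 3, 4, 5, 6))
  colnames(mr) <- s
  de_l <- data.frame(gene = "l1", signed_fc = 3, p_value = .01,
                     direction = "up")
  de_m <- data.frame(gene = c("g_pos", "g_neg"), signed_fc = c(3, -3),
                     p_value = .01, direction = c("up", "down"))
  out <- coexpression_pairs(lnc, mr, de_l, de_m)
  expect_equal(out$mrna, "g_pos")
  expect_equal(out$r, 1)
  # |r| mode readmits the negative pair
  out2 <- coexpression_pairs(lnc, mr, de_l, de_m, abs_r = TRUE)
  expect_setequal(out2$mrna, c("g_pos", "g_neg"))
})

test_that("correlation is symmetric and affine invariant", {
  set.seed(9)
  s <- sprintf("S%d", 1:6)
  x <- runif(6, 1, 10); y <- x + rnorm(6, 0, 0.01)
  de1 <- data.frame(gene = "a", signed_fc = 3, p_value = .01,
                    direction = "up")
  de2 <- data.frame(gene = "b", signed_fc = 3, p_value = .01,
                    direction = "up")
  m1 <- matrix(x, 1, dimnames = list("a", s))
  m2 <- matrix(y, 1, dimnames = list("b", s))
  r_ab <- coexpression_pairs(m1, m2, de1, de2, r_threshold = 0.5)$r
  r_ba <- coexpression_pairs(m2, m1, de2, de1, r_threshold = 0.5)$r
  expect_equal(r_ab, r_ba)
  m2s <- matrix(5 * y + 100, 1, dimnames = list("b", s))
  r_scaled <- coexpression_pairs(m1, m2s, de1, de2, r_threshold = 0.5)$r
  expect_equal(r_ab, r_scaled, tolerance = 1e-12)
})

test_that("retention at r > 0.99 implies clearing the p < 0.05 critical r", {
  set.seed(14)
  s <- sprintf("S%d", 1:6)
  # critical |r| at alpha = 0.05 with n = 6: t quantile transform
  t_crit <- qt(0.975, 4)
  r_crit <- t_crit / sqrt(4 + t_crit^2)
  for (i in 1:20) {
    x <- runif(6, 1, 10)
    y <- x * 2^rnorm(6, 0, 0.05)
    m1 <- matrix(x, 1, dimnames = list("a", s))
    m2 <- matrix(y, 1, dimnames = list("b", s))
    de1 <- data.frame(gene = "a", signed_fc = 3, p_value = .01,
                      direction = "up")
    de2 <- data.frame(gene = "b", signed_fc = 3, p_value = .01,
                      direction = "up")
    out <- coexpression_pairs(m1, m2, de1, de2)
    if (nrow(out)) expect_true(all(out$r > r_crit))
  }
})

test_that("sample mismatches and degenerate vectors are handled", {
  s <- sprintf("S%d", 1:6)
  lnc <- matrix(1:6, 1, dimnames = list("l1", s))
  mr <- matrix(rep(5, 6), 1, dimnames = list("g1", s))
  de_l <- data.frame(gene = "l1", signed_fc = 3, p_value = .01,
                     direction = "up")
  de_m <- data.frame(gene = "g1", signed_fc = 3, p_value = .01,
                     direction = "up")
  expect_warning(out <- coexpression_pairs(lnc, mr, de_l, de_m),
                 "zero-variance")
  expect_equal(nrow(out), 0)
  mr2 <- matrix(1:2, 1, dimnames = list("g1", s[1:2]))
  expect_error(coexpression_pairs(lnc, mr2, de_l, de_m), "sample")
  lnc3 <- matrix(1:2, 1, dimnames = list("l1", s[1:2]))
  expect_error(coexpression_pairs(lnc3, mr2, de_l, de_m),
               "at least 3")
})
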