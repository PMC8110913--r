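simple_de <- function(genes, fc = 3) {
  data.frame(gene = genes, kind = "x", signed_fc = fc, p_value = 0.01,
             direction = ifelse(fc > 0, "up", "down"),
             stringsAsFactors = FALSE)
}
simple_pairs <- function(l, g) {
  data.frame(lncrna = l, mrna = g, r = 0.999, p_value = 0.001, n = 6L,
             stringsAsFactors = FALSE)
}
simple_edges <- function(m, t, kind) {
  data.frame(mirna = m, target = t, kind = kind, score = 90,
             source = "s", stringsAsFactors = FALSE)
}

test_that("a correlated pair without a shared miRNA yields no triplet", {
  pairs <- simple_pairs("l1", "g1")
  le <- simple_edges("m1", "l1", "lncRNA")
  me <- simple_edges("m2", "g1", "mRNA")
  de <- simple_de(c("l1", "g1"))
  expect_equal(nrow(assemble_triplets(pairs, le, me, de)), 0)
})

test_that("the fold-change refinement applies to both pair members", {
  pairs <- simple_pairs(c("l1", "l2"), c("g1", "g2"))
  le <- simple_edges(c("m1", "m2"), c("l1", "l2"), "lncRNA")
  me <- simple_edges(c("m1", "m2"), c("g1", "g2"), "mRNA")
  de <- rbind(simple_de(c("l1", "g1"), 3),
              simple_de("l2", 3), simple_de("g2", 1.8))
  out <- assemble_triplets(pairs, le, me, de)
  expect_equal(out$lncrna, "l1")  # l2/g2 pair fails |FC| > 2 on g2
  # relaxing the refinement can only add triplets
  relaxed <- assemble_triplets(pairs, le, me, de, refine_fc = 1.5)
  expect_true(all(paste(out$lncrna, out$mirna, out$mrna) %in%
                    paste(relaxed$lncrna, relaxed$mirna, relaxed$mrna)))
  expect_equal(nrow(relaxed), 2)
})

test_that("assembly equals exhaustive triple enumeration on random instances", {
  set.seed(77)
  for (i in 1:25) {
    inst <- random_triplet_instance(n_l = sample(3:5, 1),
                                    n_m = sample(3:5, 1),
                                    n_g = sample(3:5, 1))
    got <- assemble_triplets(inst$pairs, inst$lnc_edges, inst$mrna_edges,
                             inst$de)
    want <- brute_triplets(inst$pairs, inst$lnc_edges, inst$mrna_edges,
                           inst$de)
    expect_identical(paste(got$lncrna, got$mirna, got$mrna), want)
  }
})

test_that("strict miRNA direction mode keeps only opposing miRNAs", {
  pairs <- simple_pairs("l1", "g1")
  le <- simple_edges(c("m_opp", "m_same"), "l1", "lncRNA")
  me <- simple_edges(c("m_opp", "m_same"), "g1", "mRNA")
  de <- simple_de(c("l1", "g1"))
  dirs <- data.frame(mirna = c("m_opp", "m_same"),
                     direction = c("down", "up"), stringsAsFactors = FALSE)
  loose <- assemble_triplets(pairs, le, me, de)
  expect_setequal(loose$mirna, c("m_opp", "m_same"))
  strict <- assemble_triplets(pairs, le, me, de, mirna_directions = dirs,
                              strict_mirna_direction = TRUE)
  expect_equal(strict$mirna, "m_opp")
})

test_that("network construction counts nodes and edges correctly", {
  t1 <- data.frame(lncrna = "l1", mirna = "m1", mrna = "g1",
                   stringsAsFactors = FALSE)
  de <- simple_de(c("l1", "g1"))
  n1 <- build_network(t1, de)
  expect_equal(nrow(n1$nodes), 3)
  expect_equal(nrow(n1$edges), 2)

  t2 <- rbind(t1, data.frame(lncrna = "l2", mirna = "m1", mrna = "g2"))
  de2 <- simple_de(c("l1", "g1", "l2", "g2"))
  n2 <- build_network(t2, de2)
  expect_equal(nrow(n2$nodes), 5)   # shared miRNA merges
  expect_equal(nrow(n2$edges), 4)

  n0 <- build_network(t1[0, ])
  expect_equal(nrow(n0$nodes), 0)
  expect_equal(nrow(n0$edges), 0)
})

test_that("node and edge counts are bounded by triplet counts", {
  set.seed(78)
  for (i in 1:10) {
    inst <- random_triplet_instance()
    tr <- assemble_triplets(inst$pairs, inst$lnc_edges, inst$mrna_edges,
                            inst$de)
    if (!nrow(tr)) next
    net <- build_network(tr, inst$de)
    expect_lte(nrow(net$nodes), 3 * nrow(tr))
    expect_lte(nrow(net$edges), 2 * nrow(tr))
    expect_false(any(net$edges$from == net$edges$to))
    expect_equal(anyDuplicated(net$edges[, c("from", "to", "etype")]), 0)
    # every edge is backed by at least one triplet
    expect_true(all(nzchar(net$edges$triplets)))
  }
})

test_that("conflicting node annotations abort network construction", {
  tr <- data.frame(lncrna = "x1", mirna = "m1", mrna = "x1",
                   stringsAsFactors = FALSE)
  expect_error(build_network(tr, simple_de("x1")), "more than one type")
})
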