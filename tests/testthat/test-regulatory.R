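layer_fixture <- function() {
  triplets <- data.frame(
    lncrna = c("l_key", "l_key", "l_key2", "l_other"),
    mirna = c("m1", "m1", "m1", "m9"),
    mrna = c("g_shared", "g_multi", "g_shared", "g_far"),
    stringsAsFactors = FALSE)
  coll <- gene_set_collection(
    list(P1 = c("g_shared", "g_pad1"), P2 = c("g_multi", "g_shared"),
         P3 = c("g_far", "g_pad2")),
    universe = c("g_shared", "g_multi", "g_far", "g_pad1", "g_pad2"))
  enr <- data.frame(term = c("P1", "P2", "P3"),
                    name = c("path one", "path two", "path three"),
                    namespace = "pathway", k = 1, K = 2, n = 2, N = 5,
                    p_value = c(0.01, 0.01, 0.8),
                    adjusted_p = c(0.02, 0.02, 0.8),
                    significant = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  list(triplets = triplets, coll = coll, enr = enr)
}

test_that("pathway layering restricts to key lncRNAs, attaches all terms", {
  fx <- layer_fixture()
  pn <- pathway_network(c("l_key", "l_key2"), fx$triplets, fx$enr, fx$coll)
  expect_setequal(unique(pn$triplets$lncrna), c("l_key", "l_key2"))
  # an mRNA sitting in two significant terms links to both
  expect_setequal(pn$mrna_terms$term[pn$mrna_terms$mrna == "g_shared"],
                  c("P1", "P2"))
  # non-significant terms never attach
  expect_false("P3" %in% pn$mrna_terms$term)
  counts <- pn$lncrna_pathway_counts
  expect_equal(counts$n_pathways[counts$lncrna == "l_key"], 2L)
  expect_equal(counts$n_pathways[counts$lncrna == "l_key2"], 2L)
})

test_that("a key lncRNA absent from every triplet is warned and omitted", {
  fx <- layer_fixture()
  expect_warning(pn <- pathway_network(c("l_key", "ghost"), fx$triplets,
                                       fx$enr, fx$coll),
                 "ghost")
  expect_false("ghost" %in% pn$lncrna_pathway_counts$lncrna)
})

test_that("a key lncRNA with unannotated partners keeps zero pathways", {
  fx <- layer_fixture()
  fx$triplets$mrna[fx$triplets$lncrna == "l_key2"] <- "g_pad1"
  pn <- pathway_network("l_key2", fx$triplets, fx$enr, fx$coll)
  # g_pad1 sits in significant P1, so swap to a gene in no significant term
  fx$triplets$mrna[fx$triplets$lncrna == "l_key2"] <- "g_far"
  pn <- pathway_network("l_key2", fx$triplets, fx$enr, fx$coll)
  expect_equal(pn$lncrna_pathway_counts$n_pathways, 0L)
})

test_that("two key lncRNAs sponging one miRNA onto one mRNA give 2 axes", {
  fx <- layer_fixture()
  pn <- pathway_network(c("l_key", "l_key2"), fx$triplets, fx$enr, fx$coll)
  ax <- extract_axes(pn, focus = "g_shared")
  expect_equal(nrow(ax), 2)
  expect_setequal(ax$lncrna, c("l_key", "l_key2"))
  expect_true(all(ax$mirna == "m1"))
  expect_true(all(grepl("P1", ax$pathways)))
  expect_warning(none <- extract_axes(pn, focus = "nope"), "not present")
  expect_equal(nrow(none), 0)
})

test_that("axes are the key-lncRNA projection of the triplet table", {
  cfg <- sim_config(noise_sd = 0, conflict_fraction = 0,
                    missing_db_fraction = 0, seed = 13)
  b <- generate_bundle(cfg)
  res <- suppressWarnings(run_pipeline(b))
  trip_keys <- paste(res$triplets$lncrna, res$triplets$mirna,
                     res$triplets$mrna)
  ax_keys <- paste(res$axes$lncrna, res$axes$mirna, res$axes$mrna)
  expect_true(all(ax_keys %in% trip_keys))
  expect_true(all(res$axes$lncrna %in% res$key_lncrnas$id))
})

test_that("TF network filters by site count and ranks by out-degree", {
  bind <- data.frame(
    tf = c("tf_a", "tf_a", "tf_a", "tf_b", "tf_b", "tf_c", "tf_d"),
    gene = c("g1", "g2", "g3", "g1", "g4", "g1", "g9"),
    site_count = c(5, 3, 2, 8, 1, 1, 20), stringsAsFactors = FALSE)
  net <- tf_network(bind, target_mrnas = c("g1", "g2", "g3", "g4"),
                    min_sites = 2)
  expect_equal(net$edges$tf, c("tf_a", "tf_a", "tf_a", "tf_b"))
  expect_equal(net$ranking$tf[1], "tf_a")
  expect_equal(net$ranking$n_targets, c(3L, 1L))
  # a TF binding k retained mRNAs has out-degree k
  expect_equal(sum(net$edges$tf == "tf_a"), 3)
  # below-threshold everything: empty network
  empty <- tf_network(bind, target_mrnas = "g1", min_sites = 100)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$ranking), 0)
  # row order invariance
  shuf <- bind[sample(nrow(bind)), ]
  net2 <- tf_network(shuf, target_mrnas = c("g1", "g2", "g3", "g4"),
                     min_sites = 2)
  expect_identical(net$ranking, net2$ranking)
  expect_error(tf_network(transform(bind, site_count = -1), "g1"),
               "non-negative")
})

test_that("planted TF regulators rank at the top on synthetic data", {
  cfg <- sim_config(noise_sd = 0, conflict_fraction = 0,
                    missing_db_fraction = 0, seed = 19)
  b <- generate_bundle(cfg)
  net <- tf_network(b$tf_bindings, b$ground_truth$planted_triplets$mrna)
  expect_setequal(net$ranking$tf[1:2], b$ground_truth$planted_tfs)
})
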