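ev_row <- function(mirna, dataset, direction) {
  data.frame(mirna = mirna, dataset = dataset, direction = direction,
             method = "test", stringsAsFactors = FALSE)
}

test_that("a clean single-dataset catalogue passes through unchanged", {
  ev <- rbind(ev_row("miR-a", "D1", "up"), ev_row("miR-b", "D1", "down"))
  cat <- reconcile_mirna(ev)
  expect_equal(nrow(cat), 2)
  expect_true(all(cat$status == "retained"))
  expect_equal(cat$direction[cat$mirna == "miR-a"], "up")
})

test_that("direction conflicts across datasets drop the miRNA entirely", {
  ev <- rbind(ev_row("miR-a", "D1", "up"), ev_row("miR-a", "D2", "down"),
              ev_row("miR-b", "D1", "up"), ev_row("miR-b", "D2", "up"))
  cat <- reconcile_mirna(ev)
  expect_equal(cat$status[cat$mirna == "miR-a"], "dropped_conflict")
  # same direction in several datasets: retained once, k supporters
  b <- cat[cat$mirna == "miR-b", ]
  expect_equal(b$status, "retained")
  expect_equal(b$n_datasets, 2L)
})

test_that("precursors expand into mature children inheriting direction", {
  ev <- rbind(ev_row("miR-pre", "D1", "down"), ev_row("miR-b", "D1", "up"))
  em <- data.frame(precursor = "miR-pre",
                   mature = c("miR-pre-3p", "miR-pre-5p"),
                   stringsAsFactors = FALSE)
  cat <- reconcile_mirna(ev, expansion_map = em)
  kids <- cat[cat$status == "expanded_child", ]
  expect_setequal(kids$mirna, c("miR-pre-3p", "miR-pre-5p"))
  expect_true(all(kids$direction == "down"))
  expect_true(all(kids$precursor == "miR-pre"))
  expect_false("miR-pre" %in% retained_mirnas(cat)$mirna)
})

test_that("database membership is checked on mature names after expansion", {
  ev <- rbind(ev_row("miR-pre", "D1", "up"), ev_row("miR-b", "D1", "up"))
  em <- data.frame(precursor = "miR-pre",
                   mature = c("miR-pre-3p", "miR-pre-5p"),
                   stringsAsFactors = FALSE)
  db <- c("miR-pre-3p", "miR-b")  # one child missing from the database
  cat <- reconcile_mirna(ev, db_universe = db, expansion_map = em)
  expect_equal(cat$status[cat$mirna == "miR-pre-5p"], "dropped_not_in_db")
  expect_equal(cat$status[cat$mirna == "miR-pre-3p"], "expanded_child")
})

test_that("reconciliation is order independent and obeys the size identity", {
  set.seed(33)
  ev <- rbind(ev_row(sprintf("miR-%02d", 1:10), "D1",
                     sample(c("up", "down"), 10, replace = TRUE)),
              ev_row("miR-01", "D2", "down"), ev_row("miR-01", "D3", "up"),
              ev_row("miR-pre", "D2", "up"))
  em <- data.frame(precursor = "miR-pre", mature = c("m1", "m2"),
                   stringsAsFactors = FALSE)
  db <- c(sprintf("miR-%02d", 1:9), "m1", "m2")  # miR-10 not in db
  cat1 <- reconcile_mirna(ev, db, em)
  shuffled <- ev[sample(nrow(ev)), ]
  cat2 <- reconcile_mirna(shuffled, db, em)
  expect_identical(cat1, cat2)

  # |retained| = distinct - conflicts - not_in_db + (children - 1) per prec
  n_distinct <- length(unique(ev$mirna))
  n_conf <- sum(cat1$status == "dropped_conflict")
  n_db <- sum(cat1$status == "dropped_not_in_db")
  expect_equal(nrow(retained_mirnas(cat1)),
               n_distinct - n_conf - n_db + (2 - 1))
})

test_that("synthetic corruption is flagged exactly as generated", {
  cfg <- sim_config(conflict_fraction = 0.2, missing_db_fraction = 0.1,
                    seed = 5)
  b <- generate_bundle(cfg)
  cat <- reconcile_mirna(b$mirna_evidence, b$db_universe)
  expect_setequal(cat$mirna[cat$status == "dropped_conflict"],
                  b$ground_truth$conflicted_mirnas)
  expect_setequal(cat$mirna[cat$status == "dropped_not_in_db"],
                  b$ground_truth$missing_db_mirnas)
})

test_that("evidence validation catches bad input, empty input is fine", {
  empty <- data.frame(mirna = character(), dataset = character(),
                      direction = character(), stringsAsFactors = FALSE)
  expect_equal(nrow(reconcile_mirna(empty)), 0)
  ev <- ev_row("miR-a", "D9", "up")
  expect_error(reconcile_mirna(ev, datasets = c("D1", "D2")),
               "undeclared dataset")
  bad <- ev_row("miR-a", "D1", "increased")
  expect_error(reconcile_mirna(bad), "'up' or 'down'")
})
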