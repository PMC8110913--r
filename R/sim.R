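#' Configuration for the synthetic ceRNA study generator
#'
#' Bundles and validates the knobs of [generate_bundle()]. Defaults emulate
#' a small two-group microarray study: 3 case vs 3 control samples,
#' multiplicative group effects with ratio fold changes between 1.5 and 4
#' (one planted lncRNA additionally receives an extreme fold change in the
#' hundreds, as such values do occur in re-annotated lncRNA probes), log2
#' noise around group means, miRNA evidence spread over 9 literature
#' datasets, and scored target edges on a 0-100 (mRNA) and miRanda-like
#' (lncRNA) scale.
#'
#' @param n_lncrna,n_mrna,n_mirna numbers of simulated genes per class.
#' @param n_case,n_ctrl samples per group (default 3 each).
#' @param n_planted_triplets how many true ceRNA triplets to plant.
#' @param fc_range length-2 positive ratio range for dysregulated genes;
#'   lower bound must exceed 1. Triplet members are drawn from the part of
#'   the range above the assembly refinement cutoff so that planting
#'   guarantees |FC| > 2.
#' @param noise_sd log2-scale standard deviation of expression noise.
#' @param target_score_range score interval (lo, hi] with hi <= 100 for
#'   planted miRNA->mRNA edges; decoy edges score at or below the
#'   conventional cutoff of 80.
#' @param n_evidence_datasets number of simulated literature miRNA
#'   datasets (default 9).
#' @param conflict_fraction fraction of miRNAs whose evidence is corrupted
#'   with an opposite-direction call in a second dataset.
#' @param missing_db_fraction fraction of miRNAs dropped from the simulated
#'   target-database universe.
#' @param seed integer seed governing all sub-generators.
#' @return validated list of class "sim_config".
#' @export
sim_config <- function(n_lncrna = 60, n_mrna = 80, n_mirna = 30,
                       n_case = 3, n_ctrl = 3,
                       n_planted_triplets = 12,
                       fc_range = c(1.5, 4),
                       noise_sd = 0.25,
                       target_score_range = c(80, 100),
                       n_evidence_datasets = 9,
                       conflict_fraction = 0.1,
                       missing_db_fraction = 0.05,
                       seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1)
      stop("invalid sim_config field '", nm, "': must be a count >= 1",
           call. = FALSE)
  }
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < 0 || x > 1)
      stop("invalid sim_config field '", nm, "': must be in [0, 1]",
           call. = FALSE)
  }
  for (nm in c("n_lncrna", "n_mrna", "n_mirna", "n_case", "n_ctrl",
               "n_planted_triplets", "n_evidence_datasets"))
    chk_count(get(nm), nm)
  chk_prop(conflict_fraction, "conflict_fraction")
  chk_prop(missing_db_fraction, "missing_db_fraction")
  if (length(fc_range) != 2L || any(!is.finite(fc_range)) ||
      fc_range[1] <= 1 || fc_range[2] < fc_range[1])
    stop("invalid sim_config field 'fc_range': need 1 < lo <= hi",
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid sim_config field 'noise_sd': must be >= 0", call. = FALSE)
  if (length(target_score_range) != 2L ||
      target_score_range[1] <= 0 || target_score_range[2] > 100 ||
      target_score_range[2] <= target_score_range[1])
    stop("invalid sim_config field 'target_score_range': need 0 < lo < hi <= 100",
         call. = FALSE)
  n_hub <- min(2L, n_planted_triplets %/% 6L)
  n_single <- n_planted_triplets - 6L * n_hub
  if (n_lncrna < n_hub + n_single + 10L)
    stop("invalid sim_config field 'n_lncrna': too small for ",
         n_planted_triplets, " planted triplets plus decoys", call. = FALSE)
  if (n_mrna < n_planted_triplets + 10L)
    stop("invalid sim_config field 'n_mrna': too small for ",
         n_planted_triplets, " planted triplets plus decoys", call. = FALSE)
  if (n_mirna < n_planted_triplets + 6L)
    stop("invalid sim_config field 'n_mirna': too small for ",
         n_planted_triplets, " planted triplets plus decoys", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("invalid sim_config field 'seed': must be a single integer",
         call. = FALSE)
  structure(list(n_lncrna = as.integer(n_lncrna),
                 n_mrna = as.integer(n_mrna),
                 n_mirna = as.integer(n_mirna),
                 n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 n_planted_triplets = as.integer(n_planted_triplets),
                 fc_range = as.numeric(fc_range),
                 noise_sd = as.numeric(noise_sd),
                 target_score_range = as.numeric(target_score_range),
                 n_evidence_datasets = as.integer(n_evidence_datasets),
                 conflict_fraction = as.numeric(conflict_fraction),
                 missing_db_fraction = as.numeric(missing_db_fraction),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic ceRNA study with planted ground truth
#'
#' Produces every input the inference pipeline consumes -- lncRNA and mRNA
#' expression matrices, a multi-dataset miRNA evidence table with a
#' database universe, scored miRNA->lncRNA and miRNA->mRNA target tables,
#' a gene-set collection, and a TF binding-site table -- together with a
#' ground-truth record of what was planted.
#'
#' The expression model is log-normal: each gene has a log2 baseline drawn
#' uniformly in [5, 9], a multiplicative group effect equal to its planted
#' fold change, and i.i.d. Gaussian log2 noise of sd `noise_sd`. Planted
#' lncRNA-mRNA partners are built near-collinear: the mRNA partner's
#' profile is the lncRNA's profile rescaled with attenuated residual noise
#' (one tenth of `noise_sd`), so with zero noise the pair correlates
#' exactly and correlation retention degrades gracefully as noise grows.
#'
#' Decoys are planted per filter, each designed to be rejected by exactly
#' one rule: a non-dysregulated partner pair; a pair with fold changes
#' between the screening (1.5) and refinement (2) cutoffs; an
#' anti-correlated pair; a pair whose miRNA->mRNA edge scores exactly at
#' the score cutoff (strictness check); a pair whose miRNA->lncRNA edge
#' scores below the lncRNA score cutoff; dysregulated genes with no shared
#' miRNA; plus bulk low-score edges onto non-dysregulated background genes
#' that anchor the lncRNA score distribution. When evidence corruption is
#' enabled, conflicted miRNAs also contribute high-score edges onto a
#' planted pair, which only the catalogue conflict rule removes.
#'
#' @param config a [sim_config()].
#' @return list of class "sim_bundle" with elements `ground_truth`,
#'   `lnc_mat`, `mrna_mat`, `groups`, `mirna_evidence`, `db_universe`,
#'   `lnc_edges`, `mrna_edges`, `gene_sets`, `tf_bindings`, `config`.
#'   `ground_truth` carries planted_triplets, hub_lncrnas, planted fold
#'   changes, pathway assignments and enriched terms, tf_regulators,
#'   conflicted/missing-db miRNA ids, and the decoy ledger.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n_samp <- config$n_case + config$n_ctrl
  groups <- c(rep("case", config$n_case), rep("control", config$n_ctrl))
  samples <- sprintf("S%02d_%s", seq_len(n_samp),
                     ifelse(groups == "case", "case", "ctrl"))

  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrna))
  mir_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
  datasets <- sprintf("DS%d", seq_len(config$n_evidence_datasets))

  # ---- planted triplet layout -------------------------------------------
  n_hub <- min(2L, config$n_planted_triplets %/% 6L)
  n_single <- config$n_planted_triplets - 6L * n_hub
  hub_lnc <- lnc_ids[seq_len(n_hub)]
  single_lnc <- lnc_ids[n_hub + seq_len(n_single)]
  trip_lnc <- c(rep(hub_lnc, each = 6L), single_lnc)
  trip_mrna <- mrna_ids[seq_len(config$n_planted_triplets)]
  trip_mir <- mir_ids[seq_len(config$n_planted_triplets)]
  planted <- data.frame(lncrna = trip_lnc, mirna = trip_mir,
                        mrna = trip_mrna, stringsAsFactors = FALSE)

  # directions: hubs alternate up/down; singles random
  lnc_dir <- stats::setNames(rep(NA_character_, config$n_lncrna), lnc_ids)
  if (n_hub >= 1L) lnc_dir[hub_lnc[1L]] <- "up"
  if (n_hub >= 2L) lnc_dir[hub_lnc[2L]] <- "down"
  lnc_dir[single_lnc] <- sample(c("up", "down"), n_single, replace = TRUE)

  # fold changes for triplet members: above the refinement cutoff of 2
  fc_lo <- max(2.5, config$fc_range[1])
  fc_hi <- max(config$fc_range[2], fc_lo + 0.5)
  planted_lnc <- unique(planted$lncrna)
  lnc_fc <- stats::setNames(rep(1, config$n_lncrna), lnc_ids)
  for (l in planted_lnc) {
    mag <- stats::runif(1, fc_lo, fc_hi)
    lnc_fc[l] <- if (lnc_dir[l] == "up") mag else -mag
  }
  if (n_hub >= 1L) {
    # one extreme fold change mimicking the long tail of real lncRNA FCs
    mag <- stats::runif(1, 200, 400)
    lnc_fc[hub_lnc[1L]] <- if (lnc_dir[hub_lnc[1L]] == "up") mag else -mag
  }

  # ---- decoy layout ------------------------------------------------------
  free_lnc <- setdiff(lnc_ids, planted_lnc)
  free_mrna <- setdiff(mrna_ids, trip_mrna)
  free_mir <- setdiff(mir_ids, trip_mir)
  decoy <- list(
    nonde = list(lnc = free_lnc[1L], mrna = free_mrna[1L],
                 mir = free_mir[1L]),
    weak_fc = list(lnc = free_lnc[2L], mrna = free_mrna[2L],
                   mir = free_mir[2L]),
    anticorr = list(lnc = free_lnc[3L], mrna = free_mrna[3L],
                    mir = free_mir[3L]),
    low_mrna_score = list(lnc = free_lnc[4L], mrna = free_mrna[4L],
                          mir = free_mir[4L]),
    low_lnc_score = list(lnc = free_lnc[5L], mrna = free_mrna[5L],
                         mir = free_mir[5L]),
    no_shared_mirna = list(lnc = free_lnc[6L], mrna = free_mrna[6L])
  )
  decoy_lnc <- vapply(decoy, `[[`, "", "lnc")
  decoy_mrna <- vapply(decoy, `[[`, "", "mrna")

  lnc_dir[decoy_lnc["weak_fc"]] <- sample(c("up", "down"), 1L)
  lnc_fc[decoy_lnc["weak_fc"]] <-
    stats::runif(1, 1.6, 1.9) * ifelse(lnc_dir[decoy_lnc["weak_fc"]] == "up",
                                       1, -1)
  for (nm in c("anticorr", "low_mrna_score", "low_lnc_score",
               "no_shared_mirna")) {
    id <- decoy_lnc[[nm]]
    lnc_dir[id] <- sample(c("up", "down"), 1L)
    mag <- stats::runif(1, fc_lo, fc_hi)
    lnc_fc[id] <- if (lnc_dir[id] == "up") mag else -mag
  }
  # nonde decoy keeps fc = 1 (not dysregulated)

  # ---- expression matrices ----------------------------------------------
  # case/control multiplier per gene on log2 scale; fc is a signed ratio
  gene_profile <- function(fc) {
    mu <- stats::runif(1, 5, 9)
    shift <- if (fc == 1) 0 else sign(fc) * log2(abs(fc))
    means <- mu + ifelse(groups == "case", shift, 0)
    2^(means + stats::rnorm(n_samp, 0, config$noise_sd))
  }
  lnc_mat <- t(vapply(lnc_ids, function(id) gene_profile(lnc_fc[id]),
                      numeric(n_samp)))
  colnames(lnc_mat) <- samples

  # mRNA partners of a planted/decoy pair are rescaled copies of their
  # lncRNA profile with attenuated residual noise (near-collinear)
  partner_of <- stats::setNames(rep(NA_character_, config$n_mrna), mrna_ids)
  partner_of[planted$mrna] <- planted$lncrna
  for (nm in c("nonde", "weak_fc", "low_mrna_score", "low_lnc_score",
               "no_shared_mirna"))
    partner_of[decoy[[nm]]$mrna] <- decoy[[nm]]$lnc

  mrna_fc <- stats::setNames(rep(1, config$n_mrna), mrna_ids)
  mrna_dir <- stats::setNames(rep(NA_character_, config$n_mrna), mrna_ids)
  mrna_mat <- matrix(NA_real_, config$n_mrna, n_samp,
                     dimnames = list(mrna_ids, samples))
  resid_sd <- config$noise_sd * 0.1
  for (g in mrna_ids) {
    p <- partner_of[g]
    if (!is.na(p)) {
      scale <- 2^stats::runif(1, -2, 2)
      mrna_mat[g, ] <- lnc_mat[p, ] * scale *
        2^stats::rnorm(n_samp, 0, resid_sd)
      mrna_fc[g] <- lnc_fc[p]
      mrna_dir[g] <- lnc_dir[p]
    } else if (g == decoy$anticorr$mrna) {
      # reciprocal profile: anti-correlated, opposite direction, |FC| > 2
      p2 <- decoy$anticorr$lnc
      scale <- 2^stats::runif(1, 10, 14)
      mrna_mat[g, ] <- scale / lnc_mat[p2, ] *
        2^stats::rnorm(n_samp, 0, resid_sd)
      mrna_fc[g] <- -lnc_fc[p2]
      mrna_dir[g] <- setdiff(c("up", "down"), lnc_dir[p2])
    } else {
      mrna_mat[g, ] <- gene_profile(1)
    }
  }

  # ---- miRNA evidence table ---------------------------------------------
  mir_dir <- stats::setNames(sample(c("up", "down"), config$n_mirna,
                                    replace = TRUE), mir_ids)
  # sponge-consistent: a planted miRNA opposes its lncRNA's direction
  for (i in seq_len(nrow(planted)))
    mir_dir[planted$mirna[i]] <-
      setdiff(c("up", "down"), lnc_dir[planted$lncrna[i]])

  home <- sample(datasets, config$n_mirna, replace = TRUE)
  evidence <- data.frame(mirna = mir_ids, dataset = home,
                         direction = unname(mir_dir),
                         method = "simulated", stringsAsFactors = FALSE)
  # replicate ~1/3 of calls in a second dataset, same direction
  rep_idx <- which(stats::runif(config$n_mirna) < 1 / 3 &
                     config$n_evidence_datasets > 1L)
  if (length(rep_idx)) {
    second <- vapply(home[rep_idx], function(d)
      sample(setdiff(datasets, d), 1L), character(1))
    evidence <- rbind(evidence,
                      data.frame(mirna = mir_ids[rep_idx], dataset = second,
                                 direction = unname(mir_dir[rep_idx]),
                                 method = "simulated",
                                 stringsAsFactors = FALSE))
  }

  # corruption: conflicting calls and database absences, never touching
  # planted or per-filter decoy miRNAs
  protect <- c(trip_mir, vapply(decoy[names(decoy) != "no_shared_mirna"],
                                `[[`, "", "mir"))
  pool <- setdiff(mir_ids, protect)
  n_conf <- min(round(config$conflict_fraction * config$n_mirna),
                length(pool))
  conflicted <- if (n_conf > 0) sample(pool, n_conf) else character()
  if (length(conflicted) && config$n_evidence_datasets > 1L) {
    other <- vapply(conflicted, function(m) {
      used <- evidence$dataset[evidence$mirna == m]
      cand <- setdiff(datasets, used)
      if (length(cand)) sample(cand, 1L) else datasets[1L]
    }, character(1))
    evidence <- rbind(evidence,
                      data.frame(mirna = conflicted, dataset = other,
                                 direction = ifelse(mir_dir[conflicted] == "up",
                                                    "down", "up"),
                                 method = "simulated",
                                 stringsAsFactors = FALSE))
  }
  pool2 <- setdiff(pool, conflicted)
  n_miss <- min(round(config$missing_db_fraction * config$n_mirna),
                length(pool2))
  missing_db <- if (n_miss > 0) sample(pool2, n_miss) else character()
  db_universe <- setdiff(mir_ids, missing_db)
  evidence <- evidence[order(evidence$mirna, evidence$dataset), ,
                       drop = FALSE]
  rownames(evidence) <- NULL

  # ---- target edge tables ------------------------------------------------
  sc <- config$target_score_range
  hi_mrna <- function(n) stats::runif(n, sc[1] + 1e-6, sc[2])
  lnc_hi <- function(n) stats::runif(n, 160, 200)
  lnc_lo <- function(n) stats::runif(n, 50, 150)

  lnc_edges <- data.frame(mirna = planted$mirna, target = planted$lncrna,
                          kind = "lncRNA",
                          score = lnc_hi(nrow(planted)),
                          source = "sim_miranda", stringsAsFactors = FALSE)
  mrna_edges <- data.frame(mirna = planted$mirna, target = planted$mrna,
                           kind = "mRNA", score = hi_mrna(nrow(planted)),
                           source = "sim_mirdb", stringsAsFactors = FALSE)
  add_edge <- function(tab, mirna, target, kind, score, source) {
    rbind(tab, data.frame(mirna = mirna, target = target, kind = kind,
                          score = score, source = source,
                          stringsAsFactors = FALSE))
  }
  # per-filter decoy edges
  for (nm in c("nonde", "weak_fc", "anticorr")) {
    d <- decoy[[nm]]
    lnc_edges <- add_edge(lnc_edges, d$mir, d$lnc, "lncRNA", lnc_hi(1),
                          "sim_miranda")
    mrna_edges <- add_edge(mrna_edges, d$mir, d$mrna, "mRNA", hi_mrna(1),
                           "sim_mirdb")
  }
  d <- decoy$low_mrna_score   # edge score exactly at the cutoff (strict >)
  lnc_edges <- add_edge(lnc_edges, d$mir, d$lnc, "lncRNA", lnc_hi(1),
                        "sim_miranda")
  mrna_edges <- add_edge(mrna_edges, d$mir, d$mrna, "mRNA", sc[1],
                         "sim_mirdb")
  d <- decoy$low_lnc_score
  lnc_edges <- add_edge(lnc_edges, d$mir, d$lnc, "lncRNA",
                        stats::runif(1, 50, 100), "sim_miranda")
  mrna_edges <- add_edge(mrna_edges, d$mir, d$mrna, "mRNA", hi_mrna(1),
                         "sim_mirdb")
  # conflicted miRNAs target a planted pair with high scores: only the
  # catalogue conflict rule can remove these
  if (length(conflicted)) {
    lnc_edges <- add_edge(lnc_edges, conflicted, planted$lncrna[1L],
                          "lncRNA", lnc_hi(length(conflicted)),
                          "sim_miranda")
    mrna_edges <- add_edge(mrna_edges, conflicted, planted$mrna[1L],
                           "mRNA", hi_mrna(length(conflicted)), "sim_mirdb")
  }
  # bulk low-score decoy edges onto non-dysregulated background genes;
  # these anchor the lncRNA score distribution so that its upper decile
  # sits below every planted lncRNA edge score
  bg_lnc <- setdiff(lnc_ids, c(planted_lnc, decoy_lnc))
  bg_mrna <- setdiff(mrna_ids, c(trip_mrna, decoy_mrna))
  n_bulk <- max(50L, 19L * nrow(lnc_edges))
  lnc_edges <- add_edge(lnc_edges,
                        sample(mir_ids, n_bulk, replace = TRUE),
                        sample(bg_lnc, n_bulk, replace = TRUE),
                        "lncRNA", lnc_lo(n_bulk), "sim_miranda")
  n_bulk_m <- 100L
  mrna_edges <- add_edge(mrna_edges,
                         sample(mir_ids, n_bulk_m, replace = TRUE),
                         sample(bg_mrna, n_bulk_m, replace = TRUE),
                         "mRNA", stats::runif(n_bulk_m, 1, sc[1]),
                         "sim_mirdb")
  dedup <- function(tab) {
    tab <- tab[order(tab$mirna, tab$target, -tab$score), , drop = FALSE]
    tab <- tab[!duplicated(tab[, c("mirna", "target")]), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  lnc_edges <- dedup(lnc_edges)
  mrna_edges <- dedup(mrna_edges)

  # ---- gene sets ---------------------------------------------------------
  # two enriched terms concentrate the planted triplet mRNAs; four null
  # terms draw uniformly from the background
  half <- ceiling(nrow(planted) / 2)
  enr1 <- planted$mrna[seq_len(half)]
  enr2 <- planted$mrna[(half + 1):nrow(planted)]
  pad <- function(members, size) {
    extra <- sample(bg_mrna, max(0L, size - length(members)))
    sort(unique(c(members, extra)))
  }
  sets <- list(PW_PLANTED1 = pad(enr1, length(enr1) + 2L),
               PW_PLANTED2 = pad(enr2, length(enr2) + 2L),
               PW_NULL1 = sort(sample(bg_mrna, 10L)),
               PW_NULL2 = sort(sample(bg_mrna, 10L)),
               PW_NULL3 = sort(sample(bg_mrna, 12L)),
               PW_NULL4 = sort(sample(bg_mrna, 8L)))
  gene_sets <- gene_set_collection(sets,
                                   names = paste("pathway", names(sets)),
                                   namespace = "pathway",
                                   universe = mrna_ids)

  # ---- TF bindings -------------------------------------------------------
  tf_ids <- sprintf("TF%02d", 1:5)
  reg <- tf_ids[1:2]      # planted regulators bind most triplet mRNAs
  tf_rows <- list()
  for (tf in reg) {
    tg <- planted$mrna[stats::runif(nrow(planted)) < 0.8]
    if (length(tg) < 3L) tg <- planted$mrna[1:3]
    tf_rows[[tf]] <- data.frame(tf = tf, gene = tg,
                                site_count = sample(5:20, length(tg),
                                                    replace = TRUE),
                                stringsAsFactors = FALSE)
  }
  for (tf in tf_ids[3:5]) {
    tg <- sample(bg_mrna, 4L)
    tf_rows[[tf]] <- data.frame(tf = tf, gene = tg,
                                site_count = sample(1:4, 4L, replace = TRUE),
                                stringsAsFactors = FALSE)
  }
  tf_bindings <- do.call(rbind, tf_rows)
  tf_bindings$window_up <- 1000L
  tf_bindings$window_down <- 100L
  tf_bindings <- tf_bindings[order(tf_bindings$tf, tf_bindings$gene), ,
                             drop = FALSE]
  rownames(tf_bindings) <- NULL

  # ---- ground truth ------------------------------------------------------
  decoy_tab <- data.frame(
    lncrna = decoy_lnc,
    mrna = decoy_mrna,
    mirna = c(vapply(decoy[names(decoy) != "no_shared_mirna"], `[[`, "",
                     "mir"), NA_character_),
    reason = c("non_de_partner", "fc_below_refine", "anti_correlated",
               "mrna_score_at_cutoff", "lnc_score_below_cutoff",
               "no_shared_mirna"),
    stringsAsFactors = FALSE)
  rownames(decoy_tab) <- NULL

  ground_truth <- list(
    planted_triplets = planted,
    hub_lncrnas = data.frame(id = hub_lnc,
                             direction = unname(lnc_dir[hub_lnc]),
                             stringsAsFactors = FALSE),
    lnc_fc = lnc_fc, lnc_direction = lnc_dir,
    mrna_fc = mrna_fc, mrna_direction = mrna_dir,
    mirna_direction = mir_dir,
    pathway_assignments = sets,
    enriched_terms = c("PW_PLANTED1", "PW_PLANTED2"),
    tf_regulators = tf_bindings[tf_bindings$tf %in% reg,
                                c("tf", "gene"), drop = FALSE],
    planted_tfs = reg,
    conflicted_mirnas = sort(conflicted),
    missing_db_mirnas = sort(missing_db),
    decoys = decoy_tab)

  structure(list(ground_truth = ground_truth,
                 lnc_mat = lnc_mat, mrna_mat = mrna_mat, groups = groups,
                 mirna_evidence = evidence, db_universe = sort(db_universe),
                 lnc_edges = lnc_edges, mrna_edges = mrna_edges,
                 gene_sets = gene_sets, tf_bindings = tf_bindings,
                 config = config),
            class = "sim_bundle")
}

#' Write a simulated bundle to pipeline input files
#'
#' Emits the TSV/GMT formats the pipeline readers consume plus a manifest
#' recording the generating configuration and seed.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$lnc_mat, bundle$groups,
                   p("lncrna_matrix.tsv"), p("samples.tsv"))
  write_expression(bundle$mrna_mat, bundle$groups,
                   p("mrna_matrix.tsv"), p("samples.tsv"))
  write_tsv_file(bundle$mirna_evidence, p("mirna_evidence.tsv"))
  writeLines(bundle$db_universe, p("db_universe.txt"))
  write_tsv_file(bundle$lnc_edges, p("lncrna_edges.tsv"))
  write_tsv_file(bundle$mrna_edges, p("mrna_edges.tsv"))
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  write_tsv_file(bundle$tf_bindings, p("tf_bindings.tsv"))
  cfg <- bundle$config
  manifest <- c(sprintf("generator=cernet %s",
                        as.character(utils::packageVersion("cernet"))),
                vapply(names(unclass(cfg)), function(nm)
                  sprintf("%s=%s", nm,
                          paste(format(cfg[[nm]]), collapse = ",")),
                  character(1)))
  writeLines(manifest, p("manifest.txt"))
  files <- c("lncrna_matrix.tsv", "mrna_matrix.tsv", "samples.tsv",
             "mirna_evidence.tsv", "db_universe.txt", "lncrna_edges.tsv",
             "mrna_edges.tsv", "gene_sets.gmt", "tf_bindings.tsv",
             "manifest.txt")
  stats::setNames(file.path(dir, files), files)
}
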