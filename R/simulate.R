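#' Configuration for the synthetic-collection generator
#'
#' Defines the conditions of a simulated genebank collection: clonal
#' cultivars genotyped at a multi-allelic SSR panel, replicate trees per
#' cultivar, per-allele sizing error, amplification failure, sample
#' mislabeling, sports, and trueness-to-type codes. Defaults emulate a
#' historic pear collection genotyped at the 17-marker panel: small groups
#' of replicate trees, a 2% per-allele +/-1 bp miscall rate, 5% per-marker
#' amplification failure, rare mislabels, and trueness codes skewed toward
#' the assessed true-to-type classes.
#'
#' @param n_cultivars number of cultivars (>= 1).
#' @param panel [ssr_panel()]; default [gfg_pear_panel()].
#' @param prop_triploid fraction of triploid cultivars (3 alleles/marker;
#'   the rest are diploid with 2); pear collections hold a sizeable
#'   triploid minority.
#' @param trees_per_cultivar integer range `c(min, max)` of trees.
#' @param replicates_per_tree integer range of samples per tree.
#' @param miscall_rate per-allele probability of a +/-1 bp sizing error.
#' @param missing_rate per-(sample, marker) amplification-failure
#'   probability.
#' @param mislabel_rate per-sample probability that the recorded cultivar
#'   name is wrong (metadata perturbation; alleles untouched).
#' @param sport_rate probability a cultivar carries named sports (default
#'   7/421, the rate observed in the curated pear collection).
#' @param trueness_distribution named numeric vector of probabilities over
#'   codes `"0"`..`"5"`.
#' @param n_pool_range range of allele-pool sizes per marker.
#' @param size_range bp window the allele pools live in.
#' @param min_cultivar_distance minimum tolerance-aware Dice distance
#'   enforced between true cultivar genotypes (rejection sampling); keeps
#'   cultivars separable the way distinct real cultivars are.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cultivars = 50,
                       panel = gfg_pear_panel(),
                       prop_triploid = 0.2,
                       trees_per_cultivar = c(1L, 3L),
                       replicates_per_tree = c(1L, 2L),
                       miscall_rate = 0.02,
                       missing_rate = 0.05,
                       mislabel_rate = 0.01,
                       sport_rate = 7 / 421,
                       trueness_distribution = c(`0` = 0.02, `1` = 0.45,
                                                 `2` = 0.08, `3` = 0.10,
                                                 `4` = 0.15, `5` = 0.20),
                       n_pool_range = c(5L, 15L),
                       size_range = c(100L, 300L),
                       min_cultivar_distance = 0.3,
                       seed = 1L) {
  rates <- c(miscall_rate, missing_rate, mislabel_rate, sport_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (n_cultivars < 1) stop("need at least one cultivar", call. = FALSE)
  if (nrow(panel) == 0L) stop("panel has no markers", call. = FALSE)
  stopifnot(abs(sum(trueness_distribution) - 1) < 1e-8,
            identical(sort(names(trueness_distribution)), as.character(0:5)))
  structure(list(
    n_cultivars = as.integer(n_cultivars), panel = panel,
    prop_triploid = prop_triploid,
    trees_per_cultivar = as.integer(trees_per_cultivar),
    replicates_per_tree = as.integer(replicates_per_tree),
    miscall_rate = miscall_rate, missing_rate = missing_rate,
    mislabel_rate = mislabel_rate, sport_rate = sport_rate,
    trueness_distribution = trueness_distribution,
    n_pool_range = as.integer(n_pool_range),
    size_range = as.integer(size_range),
    min_cultivar_distance = min_cultivar_distance,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a genebank SSR collection with known ground truth
#'
#' Draws per-marker allele pools on the repeat-unit grid, samples one true
#' genotype per cultivar (rejection-sampled to keep cultivars at least
#' `min_cultivar_distance` apart), derives samples by copying the cultivar
#' genotype over trees and replicates, and perturbs them with +/-1 bp
#' miscalls, amplification failures and metadata mislabels. Every
#' perturbation is logged so the emitted profiles can be replayed exactly
#' from the truth.
#'
#' @param config a [sim_config()].
#' @return A list: `profiles` (an `ssr_profiles` tibble) and `truth`, a
#'   list with `genotypes` (tibble `cultivar_id`, `cultivar_name`, `ploidy`,
#'   `sports`, one list-column per marker), `sample_map` (tibble
#'   `sample_id`, `cultivar_id`), and `perturbations` (tibble `sample_id`,
#'   `marker`, `type`, `detail`).
#' @export
simulate_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  withr::local_seed(config$seed)

  pools <- lapply(seq_len(nrow(panel)), function(k) {
    ru <- panel$repeat_unit[k]
    if (is.na(ru) || ru < 1L) ru <- 2L
    n_pool <- sample_range(config$n_pool_range)
    lo <- config$size_range[1]; hi <- config$size_range[2]
    start <- sample.int(max(1L, hi - lo - n_pool * ru), 1L) + lo
    start + ru * (seq_len(n_pool) - 1L)
  })
  names(pools) <- panel$marker

  n_cv <- config$n_cultivars
  ploidy <- ifelse(stats::runif(n_cv) < config$prop_triploid, 3L, 2L)
  genotypes <- vector("list", n_cv)
  geno_sets <- vector("list", n_cv)
  for (i in seq_len(n_cv)) {
    for (attempt in seq_len(200L)) {
      g <- lapply(panel$marker, function(mk) {
        sort(sample(pools[[mk]], ploidy[i]))
      })
      ok <- TRUE
      if (config$min_cultivar_distance > 0 && i > 1L) {
        for (j in seq_len(i - 1L)) {
          d <- dice_distance_sets(g, geno_sets[[j]], tolerance_bp = 1L)
          if (!is.na(d) && d <= config$min_cultivar_distance) { ok <- FALSE; break }
        }
      }
      if (ok) break
      if (attempt == 200L) stop("cannot place cultivar ", i,
                                " at the required distance; enlarge pools",
                                call. = FALSE)
    }
    geno_sets[[i]] <- g
  }
  cultivar_id <- sprintf("CV%03d", seq_len(n_cv))
  cultivar_name <- paste0("Cultivar ", cultivar_id)
  has_sport <- stats::runif(n_cv) < config$sport_rate
  sports <- lapply(seq_len(n_cv), function(i) {
    if (has_sport[i]) paste0("Sport of ", cultivar_name[i]) else character(0)
  })
  truth_geno <- tibble::tibble(cultivar_id = cultivar_id,
                               cultivar_name = cultivar_name,
                               ploidy = ploidy, sports = sports)
  for (k in seq_along(panel$marker)) {
    truth_geno[[panel$marker[k]]] <- lapply(geno_sets, `[[`, k)
  }

  rows <- list(); pert <- list()
  sample_no <- 0L
  for (i in seq_len(n_cv)) {
    n_trees <- sample_range(config$trees_per_cultivar)
    for (tr in seq_len(n_trees)) {
      tree_id <- sprintf("%s_T%02d", cultivar_id[i], tr)
      n_rep <- sample_range(config$replicates_per_tree)
      for (rp in seq_len(n_rep)) {
        sample_no <- sample_no + 1L
        sid <- sprintf("S%04d", sample_no)
        alleles <- geno_sets[[i]]
        for (k in seq_along(panel$marker)) {
          mk <- panel$marker[k]
          if (stats::runif(1) < config$missing_rate) {
            pert[[length(pert) + 1L]] <- tibble::tibble(
              sample_id = sid, marker = mk, type = "missing", detail = "")
            alleles[[k]] <- integer(0)
            next
          }
          a <- alleles[[k]]
          hit <- stats::runif(length(a)) < config$miscall_rate
          if (any(hit)) {
            shift <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
            new <- a
            new[hit] <- new[hit] + shift
            pert[[length(pert) + 1L]] <- tibble::tibble(
              sample_id = sid, marker = mk, type = "miscall",
              detail = paste(a[hit], "->", new[hit], collapse = "; "))
            alleles[[k]] <- sort(unique(new))
          }
        }
        name_given <- if (has_sport[i] && stats::runif(1) < 0.5) {
          sports[[i]][1]
        } else cultivar_name[i]
        if (stats::runif(1) < config$mislabel_rate && n_cv > 1L) {
          wrong <- sample(cultivar_name[-i], 1L)
          pert[[length(pert) + 1L]] <- tibble::tibble(
            sample_id = sid, marker = NA_character_, type = "mislabel",
            detail = paste(name_given, "->", wrong))
          name_given <- wrong
        }
        code <- sample(0:5, 1L, prob = config$trueness_distribution[as.character(0:5)])
        rows[[sample_no]] <- list(
          meta = tibble::tibble(sample_id = sid, tree_id = tree_id,
                                accession_id = sprintf("%s_A%02d", cultivar_id[i], tr),
                                location = "SimLocation",
                                cultivar_name_given = name_given,
                                trueness_code = code),
          alleles = alleles, cultivar = cultivar_id[i])
      }
    }
  }
  meta <- dplyr::bind_rows(lapply(rows, `[[`, "meta"))
  allele_cols <- stats::setNames(lapply(seq_along(panel$marker), function(k) {
    lapply(rows, function(r) r$alleles[[k]])
  }), panel$marker)
  profiles <- ssr_profiles(meta, allele_cols, panel)
  truth <- list(
    genotypes = truth_geno,
    sample_map = tibble::tibble(sample_id = meta$sample_id,
                                cultivar_id = vapply(rows, `[[`, character(1), "cultivar")),
    perturbations = if (length(pert)) dplyr::bind_rows(pert) else
      tibble::tibble(sample_id = character(), marker = character(),
                     type = character(), detail = character())
  )
  list(profiles = profiles, truth = truth)
}

sample_range <- function(r) {
  if (r[1] >= r[2]) return(r[1])
  sample.int(r[2] - r[1] + 1L, 1L) + r[1] - 1L
}

#' Replay a truth's perturbation log onto its genotypes
#'
#' Reconstructs emitted profiles (allele content only) from the true
#' cultivar genotypes plus the logged miscalls and missings; used to verify
#' that the perturbation log is complete.
#'
#' @param truth the `truth` component of [simulate_collection()].
#' @param panel the simulated [ssr_panel()].
#' @return Named list: per sample id, a named list of allele vectors.
#' @export
replay_perturbations <- function(truth, panel) {
  geno <- truth$genotypes
  out <- lapply(seq_len(nrow(truth$sample_map)), function(i) {
    cid <- truth$sample_map$cultivar_id[i]
    sid <- truth$sample_map$sample_id[i]
    g <- stats::setNames(lapply(panel$marker, function(mk) {
      geno[[mk]][[match(cid, geno$cultivar_id)]]
    }), panel$marker)
    pl <- truth$perturbations[truth$perturbations$sample_id == sid, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      mk <- pl$marker[r]
      if (pl$type[r] == "missing") {
        g[[mk]] <- integer(0)
      } else if (pl$type[r] == "miscall") {
        moves <- strsplit(strsplit(pl$detail[r], "; ")[[1]], " -> ")
        a <- g[[mk]]
        for (mv in moves) {
          a[match(as.integer(mv[1]), a)] <- as.integer(mv[2])
        }
        g[[mk]] <- sort(unique(a))
      }
    }
    g
  })
  stats::setNames(out, truth$sample_map$sample_id)
}

#' Score an inferred grouping against simulated truth
#'
#' Pairwise co-membership precision and recall plus the adjusted Rand index
#' of the inferred partition against the true cultivar partition, computed
#' from the contingency-table pair counts.
#'
#' @param inferred an `ssr_groups` tibble (`group_id`, `sample_id`)
#'   covering all truth samples.
#' @param truth the `truth` component of [simulate_collection()] (or any
#'   tibble `sample_id`, `cultivar_id` passed as `truth$sample_map`).
#' @return A tibble with `adjusted_rand_index`, `precision`, `recall`,
#'   `n_samples`, `n_groups_inferred`, `n_groups_true`.
#' @export
evaluate_recovery <- function(inferred, truth) {
  map <- truth$sample_map
  extra <- setdiff(inferred$sample_id, map$sample_id)
  if (length(extra)) stop("samples not in truth: ",
                          paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  if (!all(map$sample_id %in% inferred$sample_id)) {
    stop("inferred grouping does not cover all truth samples", call. = FALSE)
  }
  inf <- inferred$group_id[match(map$sample_id, inferred$sample_id)]
  tru <- map$cultivar_id
  ct <- table(tru, inf)
  choose2 <- function(x) x * (x - 1) / 2
  n <- length(tru)
  sum_ij <- sum(choose2(ct))
  sum_i <- sum(choose2(rowSums(ct)))
  sum_j <- sum(choose2(colSums(ct)))
  total <- choose2(n)
  expected <- sum_i * sum_j / total
  max_idx <- (sum_i + sum_j) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)
  tibble::tibble(
    adjusted_rand_index = ari,
    precision = if (sum_j > 0) sum_ij / sum_j else NA_real_,
    recall = if (sum_i > 0) sum_ij / sum_i else NA_real_,
    n_samples = n,
    n_groups_inferred = length(unique(inf)),
    n_groups_true = length(unique(tru)))
}
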