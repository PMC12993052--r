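#' Binary AFL-variant encoding of SSR profiles
#'
#' Converts multi-allelic SSR data to presence/absence vectors over every
#' (marker, AFL) variant observed anywhere in the input -- the encoding the
#' retraceability check compares fingerprints in. The variant index is
#' sorted by panel marker order then AFL ascending, so the encoding is
#' deterministic; a missing marker contributes all zeros for its variants.
#'
#' @param profiles an `ssr_profiles` tibble (or any tibble with the panel's
#'   marker list-columns and a `sample_id`-like id column named by `id_col`).
#' @param panel the [ssr_panel()].
#' @param id_col name of the id column (default `"sample_id"`).
#' @return A list: `variant_index` (tibble `marker`, `afl`) and `vectors`
#'   (0/1 integer matrix, one row per profile, rownames = ids).
#' @export
binarize <- function(profiles, panel = profile_panel(profiles),
                     id_col = "sample_id") {
  if (nrow(profiles) == 0L) stop("no profiles to encode", call. = FALSE)
  idx <- dplyr::bind_rows(lapply(panel$marker, function(mk) {
    afl <- sort(unique(unlist(profiles[[mk]])))
    afl <- afl[!is.na(afl)]
    tibble::tibble(marker = mk, afl = afl)
  }))
  key <- paste(idx$marker, idx$afl)
  vecs <- t(vapply(seq_len(nrow(profiles)), function(i) {
    present <- unlist(lapply(panel$marker, function(mk) {
      a <- profiles[[mk]][[i]]
      paste(mk, a[!is.na(a)])
    }))
    as.integer(key %in% present)
  }, integer(length(key))))
  rownames(vecs) <- profiles[[id_col]]
  list(variant_index = idx, vectors = vecs)
}

#' Dice-Sorensen similarity of two presence/absence vectors
#'
#' `2|u AND v| / (|u| + |v|)` over the 1-entries; defined as 1 when both
#' vectors are all-zero (degenerate but needed for empty encodings).
#'
#' @param u,v 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
binary_dice_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vector length mismatch", call. = FALSE)
  su <- sum(u); sv <- sum(v)
  if (su + sv == 0) return(1)
  2 * sum(u & v) / (su + sv)
}

# distinct resolved AFLs per marker of one representative row
rep_allele_sets <- function(rep_row, panel) {
  stats::setNames(lapply(panel$marker, function(mk) {
    a <- rep_row[[mk]][[1]]
    sort(unique(a[!is.na(a)]))
  }), panel$marker)
}

#' Retrace representative genotypes to measured samples
#'
#' A representative fingerprint is *retraceable* when at least one member
#' sample of its molecular group matches it at 100% binary Dice similarity
#' (exact AFL-variant identity); otherwise the fingerprint is truly
#' synthetic -- it represents the group without coinciding with any
#' measured sample. Representatives still carrying unresolved CHECK flags
#' cannot be verified and come back `NA`.
#'
#' @param reps an `ssr_representatives` tibble.
#' @param profiles the member `ssr_profiles`.
#' @param groups the `ssr_groups` membership tibble.
#' @param panel the [ssr_panel()].
#' @return A tibble, one row per group: `group_id`, `retraceable`,
#'   `best_similarity`, `best_sample`, `n_members`.
#' @export
retrace_representatives <- function(reps, profiles, groups,
                                    panel = profile_panel(profiles)) {
  out <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    gid <- reps$group_id[i]
    member_ids <- groups$sample_id[groups$group_id == gid]
    if (!length(member_ids)) stop("group ", gid, " has no members", call. = FALSE)
    members <- profiles[match(member_ids, profiles$sample_id), , drop = FALSE]
    if (nrow(reps$checks[[i]])) {
      out[[i]] <- tibble::tibble(group_id = gid, retraceable = NA,
                                 best_similarity = NA_real_,
                                 best_sample = NA_character_,
                                 n_members = length(member_ids))
      next
    }
    rep_sets <- rep_allele_sets(reps[i, ], panel)
    aug <- tibble::as_tibble(members)[, c("sample_id", panel$marker)]
    aug <- dplyr::bind_rows(aug, tibble::tibble(
      sample_id = ".rep",
      !!!stats::setNames(lapply(rep_sets, list), panel$marker)))
    enc <- binarize(aug, panel)
    rep_vec <- enc$vectors[nrow(aug), ]
    sims <- vapply(seq_len(nrow(members)), function(j) {
      binary_dice_similarity(enc$vectors[j, ], rep_vec)
    }, numeric(1))
    best <- which.max(sims)
    out[[i]] <- tibble::tibble(group_id = gid,
                               retraceable = sims[best] == 1,
                               best_similarity = sims[best],
                               best_sample = members$sample_id[best],
                               n_members = length(member_ids))
  }
  dplyr::bind_rows(out)
}

#' Frequency of the representative AFL variant among group members
#'
#' Per resolved marker position, the fraction of member samples amplified at
#' that marker that carry the representative AFL (exact, no bp tolerance --
#' tolerance lives upstream in clustering and grid snapping). High
#' variability positions flag markers or genotypes worth review.
#'
#' @param rep one-row `ssr_representatives`.
#' @param members the group's `ssr_profiles`.
#' @param panel the [ssr_panel()].
#' @return A tibble, one row per resolved position: `group_id`, `marker`,
#'   `position`, `afl`, `n_carrying`, `n_amplified`, `frequency`; the mean
#'   over positions is attached as attribute `"average_score"`.
#' @export
variant_frequencies <- function(rep, members, panel = profile_panel(members)) {
  stopifnot(inherits(rep, "ssr_representatives"), nrow(rep) == 1L)
  rows <- list()
  for (mk in panel$marker) {
    vals <- rep[[mk]][[1]]
    if (!length(vals)) next
    msets <- members[[mk]]
    amp <- msets[lengths(msets) > 0L]
    for (p in seq_along(vals)) {
      if (is.na(vals[p])) next
      if (!length(amp)) {
        warning("marker ", mk, " amplified in no member; position omitted",
                call. = FALSE)
        next
      }
      carrying <- sum(vapply(amp, function(s) vals[p] %in% s, logical(1)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_id = rep$group_id, marker = mk, position = p, afl = vals[p],
        n_carrying = carrying, n_amplified = length(amp),
        frequency = carrying / length(amp))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(group_id = character(), marker = character(),
                   position = integer(), afl = integer(),
                   n_carrying = integer(), n_amplified = integer(),
                   frequency = numeric())
  attr(out, "average_score") <- if (nrow(out)) mean(out$frequency) else NA_real_
  out
}

#' Frequencies for every group
#'
#' @inheritParams retrace_representatives
#' @return One tibble stacking [variant_frequencies()] over all groups.
#' @export
frequency_report <- function(reps, profiles, groups,
                             panel = profile_panel(profiles)) {
  dplyr::bind_rows(lapply(seq_len(nrow(reps)), function(i) {
    gid <- reps$group_id[i]
    members <- profiles[profiles$sample_id %in%
                          groups$sample_id[groups$group_id == gid], , drop = FALSE]
    variant_frequencies(reps[i, ], members, panel)
  }))
}

#' Collection accounting per location
#'
#' Counts, per location and in total, the final (curated) samples, distinct
#' trees, distinct accessions, and the samples with molecular and with
#' pomological data. Trees and accessions are counted among final samples;
#' blank tree ids (e.g. reference DNA samples) do not count as trees.
#'
#' @param meta a data frame with `sample_id`, `location`, `tree_id`,
#'   `accession_id`, and optional logical `is_final`, `has_molecular`,
#'   `has_pomological` (all default `TRUE`). An `ssr_profiles` tibble works
#'   directly.
#' @return A tibble with one row per location plus a `"Total"` row:
#'   `location`, `final_samples`, `trees`, `accessions`,
#'   `molecular_samples`, `pomological_samples`.
#' @export
collection_summary <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) == 0L) {
    per <- tibble::tibble(location = character(), final_samples = integer(),
                          trees = integer(), accessions = integer(),
                          molecular_samples = integer(),
                          pomological_samples = integer())
    return(dplyr::bind_rows(per, tibble::tibble(
      location = "Total", final_samples = 0L, trees = 0L, accessions = 0L,
      molecular_samples = 0L, pomological_samples = 0L)))
  }
  for (fl in c("is_final", "has_molecular", "has_pomological")) {
    if (!fl %in% names(meta)) meta[[fl]] <- TRUE
  }
  per <- dplyr::summarise(
    dplyr::group_by(meta, .data$location),
    final_samples = sum(.data$is_final),
    trees = dplyr::n_distinct(.data$tree_id[.data$is_final & !is.na(.data$tree_id)]),
    accessions = dplyr::n_distinct(.data$accession_id[.data$is_final &
                                                        !is.na(.data$accession_id)]),
    molecular_samples = sum(.data$has_molecular),
    pomological_samples = sum(.data$has_pomological),
    .groups = "drop")
  total <- dplyr::summarise(per, location = "Total",
                            dplyr::across(dplyr::where(is.numeric), sum))
  dplyr::bind_rows(per, total)
}

#' Expand a per-location accounting table into synthetic per-sample rows
#'
#' The published accounting prints only per-location aggregates. This
#' deterministic inverse of [collection_summary()] synthesizes one metadata
#' row per sample such that summarising them reproduces the aggregates
#' exactly: final samples carry molecular/pomological flags up to the
#' printed counts (surplus counts become non-final flag-only rows), tree and
#' accession ids are assigned cyclically among the final samples, and a
#' location printed with zero trees gets blank tree ids (reference DNA
#' samples). The rows are synthetic -- ids carry no meaning beyond their
#' multiplicities.
#'
#' @param summary_tbl tibble with columns `location`, `final_samples`,
#'   `trees`, `accessions`, `molecular_samples`, `pomological_samples`
#'   (no `"Total"` row; see
#'   `system.file("extdata", "gfg_pear_collection_summary.csv", package = "ssrcurate")`).
#' @return A per-sample metadata tibble accepted by [collection_summary()].
#' @export
expand_location_summary <- function(summary_tbl) {
  summary_tbl <- dplyr::filter(tibble::as_tibble(summary_tbl),
                               .data$location != "Total")
  dplyr::bind_rows(lapply(seq_len(nrow(summary_tbl)), function(i) {
    r <- summary_tbl[i, ]
    slug <- paste0("L", i)
    n_fin <- r$final_samples
    mol_in_fin <- min(r$molecular_samples, n_fin)
    pom_in_fin <- min(r$pomological_samples, n_fin)
    extra_mol <- r$molecular_samples - mol_in_fin
    extra_pom <- r$pomological_samples - pom_in_fin
    n <- n_fin + extra_mol + extra_pom
    idx_fin <- seq_len(n_fin)
    tibble::tibble(
      location = r$location,
      sample_id = paste0(slug, "_S", seq_len(n)),
      tree_id = c(if (r$trees > 0) paste0(slug, "_T", rep_len(seq_len(r$trees), n_fin))
                  else rep(NA_character_, n_fin),
                  rep(NA_character_, n - n_fin)),
      accession_id = c(paste0(slug, "_A", rep_len(seq_len(r$accessions), n_fin)),
                       rep(NA_character_, n - n_fin)),
      is_final = c(rep(TRUE, n_fin), rep(FALSE, n - n_fin)),
      has_molecular = c(seq_len(n_fin) <= mol_in_fin,
                        rep(TRUE, extra_mol), rep(FALSE, extra_pom)),
      has_pomological = c(seq_len(n_fin) <= pom_in_fin,
                          rep(FALSE, extra_mol), rep(TRUE, extra_pom))
    )
  }))
}
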