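#' Majority-rule representative fingerprint of a set of member profiles
#'
#' Builds one "synthetic" fingerprint from the samples of a molecular group.
#' Per marker: members with failed amplification are dropped; the number of
#' positions is the modal allele count among the remaining members (ties go
#' to the larger count, so triploid signal is kept); only members with that
#' allele count vote; per position -- alleles sorted ascending -- the most
#' frequent AFL wins. A tie at a position yields no value but a CHECK flag,
#' which [resolve_ties()] can later clear by rule or leave for human review.
#' Markers amplified in no member are missing in the output (with a
#' warning).
#'
#' The group's trueness-to-type code is compiled by [propagate_trueness()],
#' its cultivar name is the most frequent recorded member name (ties to the
#' alphabetically first), and other names observed in the group are listed
#' as sports.
#'
#' @param members an `ssr_profiles` tibble holding the group's samples.
#' @param panel the [ssr_panel()]; defaults to the members' panel.
#' @param group_id optional group identifier carried into the output.
#' @return A one-row tibble of class `ssr_representatives`: `group_id`,
#'   `cultivar_name`, `trueness_code`, `sports` (list), `ploidy`, `punq`,
#'   `retraceable`, one list-column per marker (integer positions, `NA`
#'   where flagged), and `checks` -- a list-column of tibbles
#'   (`marker`, `position`, `candidates`).
#' @export
majority_fingerprint <- function(members, panel = profile_panel(members),
                                 group_id = NA_character_) {
  if (nrow(members) == 0L) stop("empty member list", call. = FALSE)
  rep_row <- tibble::tibble(
    group_id = group_id,
    cultivar_name = modal_name(members$cultivar_name_given),
    trueness_code = propagate_trueness(members$trueness_code, quiet = TRUE),
    sports = list(sport_names(members$cultivar_name_given)),
    ploidy = NA_integer_,
    punq = NA_character_,
    retraceable = NA
  )
  checks <- list()
  for (mk in panel$marker) {
    v <- vote_marker(members[[mk]])
    if (is.null(v)) {
      warning("marker ", mk, " amplified in no member of ",
              if (is.na(group_id)) "group" else group_id, call. = FALSE)
      rep_row[[mk]] <- list(integer(0))
      next
    }
    rep_row[[mk]] <- list(v$values)
    if (nrow(v$ties)) checks[[mk]] <- v$ties
  }
  checks_tbl <- if (length(checks)) {
    dplyr::bind_rows(checks, .id = "marker")
  } else {
    tibble::tibble(marker = character(), position = integer(), candidates = list())
  }
  rep_row$checks <- list(checks_tbl)
  new_ssr_representatives(rep_row, panel)
}

new_ssr_representatives <- function(tbl, panel) {
  attr(tbl, "panel") <- panel
  class(tbl) <- unique(c("ssr_representatives", class(tbl)))
  tbl
}

#' @export
print.ssr_representatives <- function(x, ...) {
  n_check <- sum(vapply(x$checks, nrow, integer(1)))
  cat("<ssr_representatives> ", nrow(x), " group(s), ",
      n_check, " unresolved CHECK flag(s)\n", sep = "")
  NextMethod()
}

# per-marker majority vote; NULL when no member amplified
vote_marker <- function(allele_list) {
  amp <- allele_list[lengths(allele_list) > 0L]
  if (length(amp) == 0L) return(NULL)
  cnt <- lengths(amp)
  tab <- table(cnt)
  k <- max(as.integer(names(tab)[tab == max(tab)]))  # modal count, ties -> larger
  voters <- amp[cnt == k]
  vals <- integer(k)
  ties <- list()
  for (p in seq_len(k)) {
    tp <- table(vapply(voters, `[`, integer(1), p))
    best <- as.integer(names(tp)[tp == max(tp)])
    if (length(best) == 1L) {
      vals[p] <- best
    } else {
      vals[p] <- NA_integer_
      ties[[length(ties) + 1L]] <- tibble::tibble(position = p, candidates = list(best))
    }
  }
  list(values = vals,
       ties = if (length(ties)) dplyr::bind_rows(ties) else
         tibble::tibble(position = integer(), candidates = list()),
       n_voters = length(voters), n_amplified = length(amp))
}

modal_name <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (!length(x)) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  nm <- names(tab)[tab == max(tab)]
  sort(nm)[1]
}

sport_names <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  main <- modal_name(x)
  sort(setdiff(x, main))
}

#' Resolve CHECK flags on a representative fingerprint
#'
#' Each tied position is resolved by the first applicable rule, in order:
#' * **R2** -- prefer the candidate yielding more distinct alleles at the
#'   marker (the more heterogeneous combination; a candidate that collapses
#'   onto an existing allele is usually a dropped peak).
#' * **R3** -- when the marker's repeat unit is known, prefer the candidate
#'   whose differences to the marker's other alleles are all multiples of
#'   the repeat unit (perfect-repeat loci drift in whole motif steps, so a
#'   1 bp offset marks a sizing error).
#' * **R1** -- prefer the candidate whose full marker combination is
#'   observed verbatim in at least one member (the most frequent such
#'   member combination wins); mirrors "pick an existing sample where
#'   possible" and keeps reshuffling to a minimum.
#' * **R4** -- otherwise the flag stays CHECK for human review.
#'
#' The evidence-based rules run before the existing-sample preference:
#' a sizing error replicated in two members is still a combination
#' "observed verbatim", so letting R1 decide first would systematically
#' endorse duplicated miscalls that the motif-consistency rule catches.
#' Every decision is logged: reviewability is part of the contract.
#'
#' @param rep a one-row `ssr_representatives` from [majority_fingerprint()].
#' @param members the group's `ssr_profiles` used to build `rep`.
#' @param panel the [ssr_panel()].
#' @return `rep` with resolvable flags cleared; the log (one row per flag:
#'   `marker`, `position`, `candidates`, `rule`, `chosen`) is attached as
#'   attribute `"resolution_log"`.
#' @export
resolve_ties <- function(rep, members, panel = profile_panel(members)) {
  stopifnot(inherits(rep, "ssr_representatives"), nrow(rep) == 1L)
  checks <- rep$checks[[1]]
  log <- list()
  remaining <- list()
  if (nrow(checks)) {
    member_sets <- function(mk) {
      s <- members[[mk]]
      s[lengths(s) > 0L]
    }
    for (r in seq_len(nrow(checks))) {
      mk <- checks$marker[r]
      pos <- checks$position[r]
      cands <- checks$candidates[[r]]
      v <- rep[[mk]][[1]]
      res <- resolve_one(v, pos, cands, member_sets(mk),
                         panel$repeat_unit[match(mk, panel$marker)])
      log[[length(log) + 1L]] <- tibble::tibble(
        marker = mk, position = pos, candidates = list(cands),
        rule = res$rule, chosen = res$chosen)
      if (!is.na(res$chosen)) {
        v[pos] <- res$chosen
        rep[[mk]][[1]] <- v
      } else {
        remaining[[length(remaining) + 1L]] <- checks[r, ]
      }
    }
  }
  rep$checks[[1]] <- if (length(remaining)) dplyr::bind_rows(remaining) else
    checks[0, ]
  log_tbl <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(marker = character(), position = integer(),
                   candidates = list(), rule = character(), chosen = integer())
  attr(rep, "resolution_log") <- log_tbl
  rep
}

resolve_one <- function(values, pos, cands, member_sets, repeat_unit) {
  combos <- lapply(cands, function(cand) {
    v <- values
    v[pos] <- cand
    v
  })
  # R2: more heterogeneous (more distinct alleles)
  het <- vapply(combos, function(v) length(unique(v[!is.na(v)])), numeric(1))
  if (sum(het == max(het)) == 1L) {
    return(list(rule = "R2", chosen = cands[[which.max(het)]]))
  }
  # R3: even differences in units of the repeat motif
  if (!is.na(repeat_unit) && repeat_unit > 0) {
    others <- values[-pos]
    others <- others[!is.na(others)]
    if (length(others)) {
      ok <- vapply(cands, function(cand) {
        all((cand - others) %% repeat_unit == 0)
      }, logical(1))
      if (sum(ok) == 1L) {
        return(list(rule = "R3", chosen = cands[[which(ok)]]))
      }
    }
  }
  # R1: combination observed verbatim in a member (on fully resolved combos)
  if (all(!vapply(combos, anyNA, logical(1)))) {
    counts <- vapply(combos, function(v) {
      key <- sort(unique(v))
      sum(vapply(member_sets, function(s) identical(s, key), logical(1)))
    }, numeric(1))
    if (max(counts) > 0 && sum(counts == max(counts)) == 1L) {
      return(list(rule = "R1", chosen = cands[[which.max(counts)]]))
    }
  }
  list(rule = "unresolved", chosen = NA_integer_)
}

#' Propagate trueness-to-type codes to a group
#'
#' Returns the most desirable code present among the members under the
#' genebank hierarchy 1 over 5 over 2 over 3 over 4 over 0: one true-to-type
#' accession is enough to represent the cultivar as true-to-type.
#' Unassessed members (`NA`) are skipped; a group with no assessed member
#' gets `NA` (with a warning unless `quiet`).
#'
#' @param codes integer vector of member codes (0-5, `NA` = unassessed).
#' @param quiet suppress the all-unassessed warning.
#' @return A single integer code (or `NA`).
#' @examples
#' propagate_trueness(c(4L, 1L, 5L))  # -> 1
#' @export
propagate_trueness <- function(codes, quiet = FALSE) {
  codes <- validate_trueness(codes)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) {
    if (!quiet) warning("no assessed member; trueness undetermined", call. = FALSE)
    return(NA_integer_)
  }
  desirability <- c(`1` = 1L, `5` = 2L, `2` = 3L, `3` = 4L, `4` = 5L, `0` = 6L)
  codes[which.min(desirability[as.character(codes)])]
}

#' Consensus genotypes for every molecular group
#'
#' Runs [majority_fingerprint()] and [resolve_ties()] over each group and
#' stacks the results; ploidy and PUNQ codes (externally assigned metadata)
#' can be merged in by group id.
#'
#' @param profiles an `ssr_profiles` tibble.
#' @param groups an `ssr_groups` tibble (`group_id`, `sample_id`) from
#'   [cluster_profiles()] / [name_groups()].
#' @param panel the [ssr_panel()].
#' @param ploidy,punq optional named vectors keyed by `group_id`.
#' @return An `ssr_representatives` tibble, one row per group, with the
#'   combined tie-resolution log attached as attribute `"resolution_log"`
#'   (extra column `group_id`).
#' @export
consensus_genotypes <- function(profiles, groups, panel = profile_panel(profiles),
                                ploidy = NULL, punq = NULL) {
  stopifnot(all(groups$sample_id %in% profiles$sample_id))
  gids <- unique(groups$group_id)
  reps <- vector("list", length(gids))
  logs <- vector("list", length(gids))
  for (i in seq_along(gids)) {
    gid <- gids[i]
    members <- profiles[profiles$sample_id %in%
                          groups$sample_id[groups$group_id == gid], , drop = FALSE]
    r <- majority_fingerprint(members, panel, group_id = gid)
    r <- resolve_ties(r, members, panel)
    lg <- attr(r, "resolution_log")
    if (nrow(lg)) logs[[i]] <- dplyr::mutate(lg, group_id = gid, .before = 1)
    reps[[i]] <- r
  }
  out <- dplyr::bind_rows(reps)
  if (!is.null(ploidy)) out$ploidy <- as.integer(ploidy[out$group_id])
  if (!is.null(punq)) out$punq <- as.character(punq[out$group_id])
  out <- new_ssr_representatives(out, panel)
  attr(out, "resolution_log") <- dplyr::bind_rows(logs)
  out
}
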