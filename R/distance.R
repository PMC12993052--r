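#' Count common alleles between two allele sets under a bp tolerance
#'
#' Allele calls drift by a base pair between electrophoresis runs, so two
#' fragment lengths are treated as the same allele when they differ by at
#' most `tolerance_bp`. "Common alleles" is the size of a maximum-cardinality
#' matching between the two sets in which allele x may pair with allele y iff
#' |x - y| <= tolerance_bp and each allele is used at most once. Because
#' allele sets are kept sorted and the compatibility relation is an interval
#' on the line, a two-pointer greedy sweep attains the maximum.
#'
#' @param a,b sorted integer AFL vectors (possibly empty = missing).
#' @param tolerance_bp non-negative integer tolerance (default 1).
#' @return Integer matching size.
#' @examples
#' count_common_alleles(c(100L, 104L), c(101L, 105L), tolerance_bp = 1)
#' @export
count_common_alleles <- function(a, b, tolerance_bp = 1L) {
  stopifnot(tolerance_bp >= 0)
  i <- 1L; j <- 1L; n <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    if (abs(a[i] - b[j]) <= tolerance_bp) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  n
}

#' Tolerance-aware Dice-Sorensen distance between two SSR profiles
#'
#' The pairwise distance is
#' \deqn{d = 1 - \frac{2 \sum \mathrm{common\ alleles}}{\sum \mathrm{alleles}_1 + \sum \mathrm{alleles}_2}}
#' with the sums running over the markers amplified in BOTH profiles, and
#' "common" counted by [count_common_alleles()] at `tolerance_bp`. Markers
#' missing in either profile are excluded from numerator and denominator so
#' amplification failure does not inflate the distance between true
#' replicates. When the two profiles share no amplified marker the
#' comparison is undefined and `NA` is returned.
#'
#' @param p,q single-row `ssr_profiles` (or plain one-row tibbles carrying
#'   the panel's marker list-columns).
#' @param panel the [ssr_panel()] both profiles are typed on.
#' @param tolerance_bp bp tolerance for allele identity (default 1).
#' @return Distance in \[0, 1\], or `NA` if no marker is comparable.
#' @export
dice_distance <- function(p, q, panel, tolerance_bp = 1L) {
  a <- lapply(panel$marker, function(mk) p[[mk]][[1]])
  b <- lapply(panel$marker, function(mk) q[[mk]][[1]])
  dice_distance_sets(a, b, tolerance_bp)
}

# core on two lists of allele vectors (one per marker, aligned)
dice_distance_sets <- function(a, b, tolerance_bp) {
  num <- 0L; den <- 0L
  for (k in seq_along(a)) {
    ak <- a[[k]]; bk <- b[[k]]
    if (length(ak) == 0L || length(bk) == 0L) next
    num <- num + count_common_alleles(ak, bk, tolerance_bp)
    den <- den + length(ak) + length(bk)
  }
  if (den == 0L) return(NA_real_)
  1 - 2 * num / den
}

#' All pairwise tolerance-aware Dice-Sorensen distances
#'
#' @param profiles an `ssr_profiles` tibble (>= 2 rows).
#' @param tolerance_bp bp tolerance for allele identity (default 1).
#' @param panel panel; defaults to the one attached to `profiles`.
#' @return An object of class `ssr_dist`: a list with `matrix` (symmetric,
#'   zero diagonal, `NA` where two samples share no amplified marker),
#'   `sample_ids`, `tolerance_bp`, and `incomparable` (tibble of the
#'   no-shared-marker pairs, for QC). [generics::tidy()] returns the pairs in
#'   long form; [ggplot2::autoplot()] draws the distance histogram.
#' @export
pairwise_distances <- function(profiles, tolerance_bp = 1L,
                               panel = profile_panel(profiles)) {
  if (nrow(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  ids <- profiles$sample_id
  n <- length(ids)
  sets <- lapply(seq_len(n), function(i) {
    lapply(panel$marker, function(mk) profiles[[mk]][[i]])
  })
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- dice_distance_sets(sets[[i]], sets[[j]], tolerance_bp)
      m[i, j] <- d; m[j, i] <- d
    }
  }
  nas <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
  incomparable <- tibble::tibble(sample_1 = ids[nas[, 1]], sample_2 = ids[nas[, 2]])
  structure(list(matrix = m, sample_ids = ids, tolerance_bp = tolerance_bp,
                 incomparable = incomparable),
            class = "ssr_dist")
}

#' @export
print.ssr_dist <- function(x, ...) {
  n <- length(x$sample_ids)
  cat("<ssr_dist> ", n, " samples, tolerance ", x$tolerance_bp, " bp; ",
      nrow(x$incomparable), " incomparable pair(s)\n", sep = "")
  invisible(x)
}

#' Cluster samples into molecular groups at a distance cut-off
#'
#' Samples whose fingerprints differ by at most `cutoff` (i.e. share
#' `1 - cutoff` or more identity) are grouped: with `linkage = "single"` the
#' groups are the connected components of the graph joining pairs at
#' distance <= cutoff (the cut-off is inclusive), so identity can chain
#' through intermediates; `linkage = "complete"` instead cuts a
#' complete-linkage dendrogram at `cutoff`, which forbids chaining but
#' requires every pair to be comparable.
#'
#' @param dist an `ssr_dist` from [pairwise_distances()].
#' @param cutoff distance cut-off in \[0, 1\] (default 0.2, i.e. 80-100%
#'   identity groups together).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return List of character vectors of sample ids (a partition of the
#'   samples), ordered by decreasing size then smallest member id.
#' @export
threshold_cluster <- function(dist, cutoff = 0.2, linkage = c("single", "complete")) {
  stopifnot(inherits(dist, "ssr_dist"), cutoff >= 0, cutoff <= 1)
  linkage <- match.arg(linkage)
  m <- dist$matrix
  ids <- dist$sample_ids
  if (linkage == "complete") {
    if (anyNA(m)) stop("complete linkage needs every pair comparable", call. = FALSE)
    hc <- stats::hclust(stats::as.dist(m), method = "complete")
    memb <- stats::cutree(hc, h = cutoff)
    comps <- split(ids, memb)
  } else {
    adj <- !is.na(m) & m <= cutoff
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    comps <- split(ids, memb)
  }
  comps <- unname(lapply(comps, sort))
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L))
  comps[ord]
}

#' Name molecular groups
#'
#' Components are ordered deterministically (descending size, ties by the
#' lexicographically smallest member id) and numbered `prefix` + running
#' number zero-padded to four digits (widening beyond 9999), e.g.
#' `Pyr_0001`.
#'
#' @param components list of non-empty character vectors partitioning the
#'   sample ids (as returned by [threshold_cluster()]).
#' @param prefix group-id prefix (default `"Pyr_"` for *Pyrus*).
#' @return A tibble with columns `group_id`, `sample_id` (one row per
#'   member) of class `ssr_groups`; group-level size is available via
#'   `dplyr::count()`.
#' @export
name_groups <- function(components, prefix = "Pyr_") {
  if (any(lengths(components) == 0L)) stop("empty component", call. = FALSE)
  all_ids <- unlist(components)
  if (anyDuplicated(all_ids)) stop("components are not a partition", call. = FALSE)
  comps <- lapply(components, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L))
  comps <- comps[ord]
  width <- max(4L, nchar(as.character(length(comps))))
  gids <- paste0(prefix, formatC(seq_along(comps), width = width, flag = "0"))
  out <- tibble::tibble(
    group_id = rep(gids, lengths(comps)),
    sample_id = unlist(comps)
  )
  class(out) <- c("ssr_groups", class(out))
  out
}

#' One-call clustering: distances, components, names
#'
#' @inheritParams pairwise_distances
#' @inheritParams threshold_cluster
#' @inheritParams name_groups
#' @return An `ssr_groups` tibble (`group_id`, `sample_id`); the
#'   `ssr_dist` used is attached as attribute `"dist"`.
#' @export
cluster_profiles <- function(profiles, tolerance_bp = 1L, cutoff = 0.2,
                             prefix = "Pyr_", linkage = "single",
                             panel = profile_panel(profiles)) {
  d <- pairwise_distances(profiles, tolerance_bp, panel)
  groups <- name_groups(threshold_cluster(d, cutoff, linkage), prefix)
  attr(groups, "dist") <- d
  groups
}
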