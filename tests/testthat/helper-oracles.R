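# Independent oracles and tiny fixture builders used across the suite.

# brute-force maximum-cardinality matching between two allele lists:
# allele x may pair with allele y iff |x - y| <= tol, each used once.
bf_common <- function(a, b, tol) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  best <- bf_common(a[-1], b, tol)
  for (j in seq_along(b)) {
    if (abs(a[1] - b[j]) <= tol) {
      best <- max(best, 1L + bf_common(a[-1], b[-j], tol))
    }
  }
  best
}

# all strictly increasing allele lists of length 0..4 over an alphabet
all_allele_lists <- function(alphabet, max_len = 4L) {
  out <- list(integer(0))
  for (k in seq_len(min(max_len, length(alphabet)))) {
    combos <- utils::combn(alphabet, k, simplify = FALSE)
    out <- c(out, lapply(combos, as.integer))
  }
  out
}

mini_panel <- function(markers = c("M1", "M2", "M3"), repeat_unit = 2L,
                       grid = NULL) {
  ssr_panel(markers, repeat_unit, grid)
}

# geno: named list sample_id -> named list marker -> integer vector
make_profiles <- function(geno, panel, trueness = NULL, meta_extra = NULL) {
  ids <- names(geno)
  meta <- tibble::tibble(sample_id = ids)
  if (!is.null(trueness)) meta$trueness_code <- trueness
  if (!is.null(meta_extra)) meta <- dplyr::bind_cols(meta, meta_extra)
  alleles <- stats::setNames(lapply(panel$marker, function(mk) {
    lapply(geno, function(g) if (is.null(g[[mk]])) integer(0) else g[[mk]])
  }), panel$marker)
  ssr_profiles(meta, alleles, panel)
}

# naive double-loop distance matrix, independent of pairwise_distances()
naive_distance_matrix <- function(profiles, panel, tol) {
  n <- nrow(profiles)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (mk in panel$marker) {
      a <- profiles[[mk]][[i]]; b <- profiles[[mk]][[j]]
      if (length(a) == 0L || length(b) == 0L) next
      num <- num + bf_common(a, b, tol)
      den <- den + length(a) + length(b)
    }
    m[i, j] <- if (den == 0) NA_real_ else 1 - 2 * num / den
  }
  m
}

# allele-set equality oracle for retraceability: TRUE iff some member has
# identical distinct allele sets to the representative at every marker
retrace_oracle <- function(rep_row, members, panel) {
  rep_sets <- lapply(panel$marker, function(mk) {
    a <- rep_row[[mk]][[1]]
    sort(unique(a[!is.na(a)]))
  })
  any(vapply(seq_len(nrow(members)), function(i) {
    all(vapply(seq_along(panel$marker), function(k) {
      identical(as.integer(members[[panel$marker[k]]][[i]]),
                as.integer(rep_sets[[k]]))
    }, logical(1)))
  }, logical(1)))
}

# the fixed desirability order as a lookup, for exhaustive trueness checks
trueness_oracle <- function(codes) {
  order <- c(1L, 5L, 2L, 3L, 4L, 0L)
  order[min(match(codes, order))]
}
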