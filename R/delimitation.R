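#' ABGD configuration
#'
#' Defaults mirror the public ABGD web server: priors log-spaced on
#' \code{[0.001, 0.1]} over 10 steps, relative gap width \code{X = 1.5}.
#'
#' @param p_min,p_max Lower/upper bounds of the prior intraspecific
#'   divergence, \code{0 < p_min < p_max < 1}.
#' @param steps Number of priors on a log scale (>= 1).
#' @param X Relative gap width multiplier (> 0).
#' @return List of class \code{abgd_config}.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10, X = 1.5) {
  if (!(p_min > 0 && p_min <= p_max && p_max < 1)) {
    stop("require 0 < p_min <= p_max < 1")
  }
  if (steps < 1 || X <= 0) stop("require steps >= 1 and X > 0")
  priors <- if (steps == 1) p_min else
    exp(seq(log(p_min), log(p_max), length.out = steps))
  structure(list(p_min = p_min, p_max = p_max, steps = steps, X = X,
                 priors = priors), class = "abgd_config")
}

new_partition <- function(assignment, method, parameter) {
  # relabel MOTUs contiguously from 1 in order of first appearance
  relab <- match(assignment, unique(assignment))
  names(relab) <- names(assignment)
  structure(list(assignment = relab, n_motus = max(relab),
                 method = method, parameter = parameter),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("<motu_partition> %s: %d samples in %d MOTUs (parameter %.4g)\n",
              x$method, length(x$assignment), x$n_motus, x$parameter))
  invisible(x)
}

# connected components linking pairs with distance <= threshold
link_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (d[i, j] <= threshold && comp[i] != comp[j]) {
        comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# first qualifying gap: between sorted d[i] and d[i+1], with d[i+1] >= prior
# and width > X * running mean of d[1..i]; returns lower edge or NA
find_gap <- function(dsort, prior, X) {
  m <- length(dsort)
  if (m < 2L) return(NA_real_)
  run_mean <- cumsum(dsort) / seq_len(m)
  for (i in seq_len(m - 1L)) {
    if (dsort[i + 1L] < prior) next
    if ((dsort[i + 1L] - dsort[i]) > X * run_mean[i]) return(dsort[i])
  }
  NA_real_
}

abgd_split <- function(d, ids, prior, X) {
  n <- length(ids)
  if (n < 3L) return(list(ids))
  dsort <- sort(d[upper.tri(d)])
  edge <- find_gap(dsort, prior, X)
  if (is.na(edge)) return(list(ids))
  comp <- link_components(d, edge)
  if (max(comp) == 1L) return(list(ids))
  unlist(lapply(seq_len(max(comp)), function(k) {
    sel <- comp == k
    abgd_split(d[sel, sel, drop = FALSE], ids[sel], prior, X)
  }), recursive = FALSE)
}

#' ABGD species delimitation
#'
#' For each prior P the ascending sorted pairwise distances are scanned for
#' the first gap at or above P whose width exceeds \code{X} times the running
#' mean of the distances below it; samples linked at or below the gap's lower
#' edge form MOTUs (connected components), and each MOTU is split recursively
#' until no qualifying gap remains (groups of fewer than 3 samples are not
#' split further). Without any qualifying gap all samples form one MOTU.
#'
#' @param dm A [distance_matrix()] with no inapplicable entries.
#' @param config An [abgd_config()].
#' @return List of \code{motu_partition}, one per prior.
#' @export
abgd_partition <- function(dm, config = abgd_config()) {
  stopifnot(inherits(dm, "dist_matrix"), inherits(config, "abgd_config"))
  d <- dm$distances
  if (anyNA(d)) stop("distance matrix has inapplicable (saturated) entries; ",
                     "use model='p' or drop the affected samples")
  if (length(dm$ids) < 2L) stop("need at least 2 samples")
  lapply(config$priors, function(P) {
    groups <- abgd_split(d, dm$ids, P, config$X)
    assignment <- integer(length(dm$ids))
    names(assignment) <- dm$ids
    for (k in seq_along(groups)) assignment[groups[[k]]] <- k
    new_partition(assignment[dm$ids], "abgd", P)
  })
}

#' Modal ABGD partition across priors
#'
#' Returns the partition whose MOTU count is the most frequent across priors;
#' ties break toward fewer MOTUs.
#'
#' @param partitions Nonempty list of partitions from [abgd_partition()].
#' @return A single \code{motu_partition}.
#' @export
choose_abgd_partition <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  counts <- vapply(partitions, `[[`, integer(1), "n_motus")
  tab <- table(counts)
  best <- min(as.integer(names(tab)[tab == max(tab)]))
  partitions[[which(counts == best)[1]]]
}

#' ASAP-style ranked partitions
#'
#' Single-linkage agglomeration generates one candidate partition per merge
#' interval (from all-singletons down to 2 MOTUs; the trivial one-MOTU
#' partition is not a candidate). Each candidate is scored by the mean of two
#' ranks: the width of the merge-height interval over which the partition is
#' stable, and the separation statistic (mean between-MOTU minus mean
#' within-MOTU distance); larger is better for both. This is a rank-based
#' analogue of the published ASAP score, not its probability model.
#'
#' @param dm A [distance_matrix()] with no inapplicable entries.
#' @return List of \code{motu_partition} ordered best first, each carrying a
#'   \code{score} element; a degenerate all-zero matrix yields a single
#'   flagged candidate.
#' @export
asap_partition <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  d <- dm$distances
  if (anyNA(d)) stop("distance matrix has inapplicable (saturated) entries")
  n <- length(dm$ids)
  if (n < 2L) stop("need at least 2 samples")
  if (all(d[upper.tri(d)] == 0)) {
    part <- new_partition(stats::setNames(rep(1L, n), dm$ids), "asap", 0)
    part$score <- NA_real_
    part$degenerate <- TRUE
    return(list(part))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  h <- hc$height
  m <- length(h)                      # n - 1 merges
  ks <- n - seq_len(m) + 1L           # candidate cluster counts n..2
  # candidate j is the partition before merge j (k = n - j + 1 clusters),
  # stable on the height interval [h[j-1], h[j]) with h[0] = 0
  cand <- lapply(seq_len(m), function(j) {
    assignment <- stats::cutree(hc, k = ks[j])[dm$ids]
    gap <- h[j] - if (j > 1L) h[j - 1L] else 0
    list(assignment = assignment, k = ks[j], gap = gap)
  })
  gaps <- vapply(cand, `[[`, numeric(1), "gap")
  sep <- vapply(cand, function(cc) {
    same <- outer(cc$assignment, cc$assignment, "==")
    intra <- d[upper.tri(d) & same]
    inter <- d[upper.tri(d) & !same]
    # the separation statistic needs both pools: a partition with no
    # within-MOTU pair says nothing about intraspecific variation
    if (!length(intra)) return(-Inf)
    mean(inter) - mean(intra)
  }, numeric(1))
  score <- (rank(gaps) + rank(sep)) / 2
  ord <- order(-score, vapply(cand, `[[`, integer(1), "k"))
  lapply(ord, function(j) {
    part <- new_partition(cand[[j]]$assignment, "asap", cand[[j]]$k)
    part$score <- score[j]
    part
  })
}

#' Compare a MOTU partition with morphological taxonomy
#'
#' A species is counted as a success only on an exact bidirectional match:
#' all of its samples fall into one MOTU and that MOTU holds no other
#' species. The discrimination rate is \code{100 * successes / n_species}.
#'
#' @param partition A \code{motu_partition}.
#' @param taxonomy Taxonomy table covering every partitioned sample.
#' @return One-row data.frame (method, parameter, n_motus, n_species,
#'   n_success, rate).
#' @export
match_partition <- function(partition, taxonomy) {
  stopifnot(inherits(partition, "motu_partition"))
  taxonomy <- validate_taxonomy(taxonomy)
  ids <- names(partition$assignment)
  missing <- setdiff(ids, taxonomy$sample_id)
  if (length(missing)) stop("sample(s) without taxonomy: ",
                            paste(missing, collapse = ", "))
  sp <- taxonomy$species[match(ids, taxonomy$sample_id)]
  species <- unique(sp)
  success <- vapply(species, function(s) {
    motus <- unique(partition$assignment[sp == s])
    length(motus) == 1L &&
      all(sp[partition$assignment == motus] == s)
  }, logical(1))
  data.frame(method = partition$method, parameter = partition$parameter,
             n_motus = partition$n_motus, n_species = length(species),
             n_success = sum(success),
             rate = round(100 * sum(success) / length(species), 2),
             stringsAsFactors = FALSE)
}
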