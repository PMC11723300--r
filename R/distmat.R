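#' Transition/transversion counts for one aligned pair
#'
#' Sites where either sequence carries a gap or ambiguity code are excluded
#' (pairwise deletion). Transitions are A<->G and C<->T; every other mismatch
#' is a transversion.
#'
#' @param seq_a,seq_b Aligned DNA strings of equal length.
#' @return List with \code{P} (transition proportion), \code{Q} (transversion
#'   proportion) and \code{n} (comparable sites).
#' @export
pair_counts <- function(seq_a, seq_b) {
  a <- strsplit(normalize_dna(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(normalize_dna(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  keep <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(keep)
  if (n == 0L) stop("zero comparable sites between the pair")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n = n)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' \eqn{d = -\frac{1}{2}\ln\{(1-2P-Q)\sqrt{1-2Q}\}}. When the log argument is
#' non-positive the pair is saturated and \code{NA} is returned (flagged
#' inapplicable, not an error).
#'
#' @param counts List with elements \code{P} and \code{Q}, as from
#'   [pair_counts()].
#' @return Distance (substitutions/site), or \code{NA} for saturated pairs.
#' @export
k2p_distance <- function(counts) {
  P <- counts$P; Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' p-distance from transition/transversion proportions
#' @param counts List with elements \code{P} and \code{Q}.
#' @return Proportion of differing comparable sites.
#' @export
p_distance <- function(counts) counts$P + counts$Q

# integer-coded alignment: 1..4 for ACGT, NA otherwise
encode_alignment <- function(dataset) {
  m <- seq_matrix(dataset)
  code <- matrix(match(m, DNA_BASES), nrow = nrow(m),
                 dimnames = list(rownames(m), NULL))
  code
}

# distances for one encoded pair; returns c(d, n) with d possibly NA
pair_distance_coded <- function(x, y, model) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n == 0L) return(c(NA_real_, 0))
  x <- x[keep]; y <- y[keep]
  diff <- x != y
  if (model == "p") return(c(sum(diff) / n, n))
  # transitions: A(1)<->G(3), C(2)<->T(4): both odd or both even
  ts <- diff & ((x %% 2L) == (y %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  c(k2p_distance(list(P = P, Q = Q)), n)
}

#' Pairwise distance matrix for an aligned marker dataset
#'
#' Computes p-distance or K2P for every unordered pair with pairwise deletion
#' of gapped/ambiguous sites. K2P pairs whose log argument is non-positive
#' are recorded as \code{NA} (saturated) and counted in
#' \code{n_inapplicable}.
#'
#' @param dataset An aligned [marker_dataset()] with two or more sequences.
#' @param model \code{"p"} or \code{"k2p"}.
#' @return An object of class \code{dist_matrix}: list with \code{ids},
#'   \code{model}, symmetric \code{distances} and \code{n_sites} matrices,
#'   and \code{n_inapplicable}.
#' @export
distance_matrix <- function(dataset, model = c("p", "k2p")) {
  model <- match.arg(model)
  code <- encode_alignment(dataset)
  n <- nrow(code)
  if (n < 2L) stop("distance matrix needs at least 2 sequences")
  ids <- rownames(code)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ns) <- ncol(code)
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      dn <- pair_distance_coded(xi, code[j, ], model)
      if (dn[[2]] == 0) stop("zero comparable sites between ", ids[i],
                             " and ", ids[j])
      d[i, j] <- d[j, i] <- dn[[1]]
      ns[i, j] <- ns[j, i] <- as.integer(dn[[2]])
    }
  }
  structure(list(ids = ids, model = model, distances = d, n_sites = ns,
                 n_inapplicable = sum(is.na(d[upper.tri(d)]))),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, model=%s, %d saturated pair(s)\n",
              length(x$ids), x$model, x$n_inapplicable))
  invisible(x)
}

#' Site-bootstrap standard errors of pairwise distances
#'
#' Alignment columns are resampled with replacement per replicate and the
#' distance recomputed; the SE is the standard deviation of per-replicate
#' distances. Replicates where a pair has zero comparable sites (or a
#' saturated K2P value) are skipped for that pair and counted.
#'
#' @param dataset An aligned [marker_dataset()].
#' @param model \code{"p"} or \code{"k2p"}.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed; same seed gives identical SEs.
#' @return List with symmetric \code{se} matrix and \code{n_used} replicate
#'   counts per pair.
#' @export
bootstrap_se <- function(dataset, model = c("p", "k2p"), replicates = 1000,
                         seed = 1L) {
  model <- match.arg(model)
  stopifnot(replicates >= 1)
  code <- encode_alignment(dataset)
  n <- nrow(code)
  L <- ncol(code)
  ids <- rownames(code)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  acc <- matrix(NA_real_, nrow(pairs), replicates)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- code[, cols, drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      x <- boot[pairs[k, 1], ]; y <- boot[pairs[k, 2], ]
      keep <- !is.na(x) & !is.na(y)
      if (!any(keep)) next
      dn <- pair_distance_coded(x, y, model)
      acc[k, r] <- dn[[1]]
    }
  }
  se <- matrix(0, n, n, dimnames = list(ids, ids))
  used <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    vals <- acc[k, !is.na(acc[k, ])]
    se[i, j] <- se[j, i] <- if (length(vals) >= 2) stats::sd(vals) else NA_real_
    used[i, j] <- used[j, i] <- length(vals)
  }
  list(se = se, n_used = used, model = model, replicates = replicates)
}
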