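#' Validate a pairwise-comparison judgment matrix
#'
#' Judgment matrices follow the Saaty 1-9 scale: positive, reciprocal
#' (\code{m[i,j] = 1/m[j,i]}), unit diagonal, entries in \code{[1/9, 9]}.
#'
#' @param m Square numeric matrix.
#' @return The matrix, invisibly classed \code{judgment_matrix}.
#' @export
judgment_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("judgment matrix must be square")
  if (any(!is.finite(m)) || any(m <= 0)) stop("entries must be positive finite")
  if (any(abs(diag(m) - 1) > 1e-9)) stop("diagonal must be 1")
  if (max(abs(m * t(m) - 1)) > 1e-6) stop("matrix is not reciprocal")
  if (any(m > 9 + 1e-6) || any(m < 1 / 9 - 1e-9)) {
    stop("entries must lie on the Saaty scale [1/9, 9]")
  }
  structure(m, class = c("judgment_matrix", "matrix"))
}

#' Consistent judgment matrix generated by a weight vector
#'
#' \code{m[i,j] = w[i]/w[j]}; by construction perfectly consistent
#' (\code{CR = 0}) and scale-invariant in \code{w}.
#'
#' @param w Positive weight vector with max/min ratio at most 9.
#' @return A [judgment_matrix()].
#' @export
consistent_judgment <- function(w) {
  stopifnot(all(w > 0))
  judgment_matrix(outer(w, w, "/"))
}

# Saaty random consistency index
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)
  if (n <= 9) ri[n] else 1.49
}

#' Criterion weights from a judgment matrix, with consistency check
#'
#' Weights are the normalized principal eigenvector, found by power
#' iteration to relative tolerance 1e-10; the row geometric-mean weights are
#' available as an independent cross-check. The consistency ratio uses
#' Saaty's random index table (\code{CR = CI/RI},
#' \code{CI = (lambda_max - n)/(n - 1)}); \code{CR < 0.1} is acceptable.
#'
#' @param m A [judgment_matrix()] (validated on entry).
#' @param method \code{"eigen"} (principal eigenvector, default) or
#'   \code{"geometric"} (row geometric means).
#' @return List with \code{weights} (sum 1), \code{lambda_max}, \code{CI},
#'   \code{RI}, \code{CR}, \code{acceptable}, \code{method}.
#' @export
derive_weights <- function(m, method = c("eigen", "geometric")) {
  method <- match.arg(method)
  m <- judgment_matrix(m)
  n <- nrow(m)
  if (n == 1L) {
    return(list(weights = 1, lambda_max = 1, CI = 0, RI = 0, CR = 0,
                acceptable = TRUE, method = method))
  }
  if (method == "geometric") {
    w <- exp(rowMeans(log(m)))
    w <- w / sum(w)
  } else {
    w <- rep(1 / n, n)
    for (it in seq_len(10000L)) {
      v <- as.vector(m %*% w)
      v <- v / sum(v)
      if (max(abs(v - w) / pmax(w, 1e-300)) < 1e-10) { w <- v; break }
      w <- v
    }
  }
  lambda <- mean(as.vector(m %*% w) / w)
  CI <- max((lambda - n) / (n - 1), 0)
  RI <- saaty_ri(n)
  CR <- if (RI > 0) CI / RI else 0
  list(weights = w, lambda_max = lambda, CI = CI, RI = RI, CR = CR,
       acceptable = CR < 0.1, method = method)
}

#' Build a criterion scheme
#'
#' A criterion scheme fixes the 13 (or however many) conservation-priority
#' criteria: ids, labels, weights and the ordered score levels each criterion
#' admits.
#'
#' @param criteria data.frame with columns \code{id}, \code{label},
#'   \code{weight}.
#' @param levels data.frame with columns \code{criterion} (an id),
#'   \code{label}, \code{points}.
#' @return Object of class \code{criterion_scheme}.
#' @export
criterion_scheme <- function(criteria, levels) {
  stopifnot(is.data.frame(criteria), is.data.frame(levels))
  need_c <- c("id", "label", "weight"); need_l <- c("criterion", "label", "points")
  if (length(setdiff(need_c, names(criteria)))) stop("criteria need id,label,weight")
  if (length(setdiff(need_l, names(levels)))) stop("levels need criterion,label,points")
  if (any(criteria$weight <= 0)) stop("weights must be positive")
  if (abs(sum(criteria$weight) - 1) > 1e-3) {
    stop("weights must sum to 1 within 1e-3 (got ",
         format(sum(criteria$weight)), ")")
  }
  if (any(levels$points < 1)) stop("level points must be >= 1")
  orphan <- setdiff(levels$criterion, criteria$id)
  if (length(orphan)) stop("levels for unknown criterion: ",
                           paste(orphan, collapse = ", "))
  bare <- setdiff(criteria$id, levels$criterion)
  if (length(bare)) stop("criterion without levels: ",
                         paste(bare, collapse = ", "))
  p_max <- tapply(levels$points, levels$criterion, max)[criteria$id]
  structure(list(criteria = criteria, levels = levels,
                 p_max = stats::setNames(as.numeric(p_max), criteria$id)),
            class = "criterion_scheme")
}

#' Default 13-criterion conservation-priority scheme
#'
#' The scheme shipped with the package: 13 criteria (endangered category,
#' artificial planting, conservation status, threat persistence, population
#' impacts, trade impacts, community status, organism type, endemism,
#' species status, relict status, economic value, hereditary value) with
#' their published weights and score levels.
#'
#' @return A [criterion_scheme()].
#' @export
default_criterion_scheme <- function() {
  crit <- utils::read.csv(system.file("extdata", "ahp_criteria.csv",
                                      package = "barcodeval"),
                          stringsAsFactors = FALSE)
  lev <- utils::read.csv(system.file("extdata", "ahp_levels.csv",
                                     package = "barcodeval"),
                         stringsAsFactors = FALSE)
  criterion_scheme(crit, lev)
}

#' Composite conservation-priority score of one species
#'
#' \eqn{S = \sum_i w_i\, p_i / p_i^{max}} with per-criterion normalization by
#' the criterion's maximum level points (the default declared convention), or
#' \eqn{S = \sum_i w_i\, p_i / 9} with a single global scale.
#'
#' @param points Named numeric vector of per-criterion points (names are
#'   criterion ids); every value must be one of the criterion's declared
#'   levels.
#' @param scheme A [criterion_scheme()].
#' @param normalization \code{"per_criterion_max"} (default) or
#'   \code{"global_nine"}.
#' @return Composite score S.
#' @export
composite_score <- function(points, scheme,
                            normalization = c("per_criterion_max",
                                              "global_nine")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(scheme, "criterion_scheme"))
  ids <- scheme$criteria$id
  missing <- setdiff(ids, names(points))
  if (length(missing)) stop("missing score for criterion: ",
                            paste(missing, collapse = ", "))
  p <- as.numeric(points[ids])
  for (k in seq_along(ids)) {
    lv <- scheme$levels$points[scheme$levels$criterion == ids[k]]
    if (!any(abs(lv - p[k]) < 1e-9)) {
      stop("points ", p[k], " not a declared level of ", ids[k])
    }
  }
  denom <- if (normalization == "per_criterion_max") scheme$p_max[ids] else 9
  sum(scheme$criteria$weight * p / denom)
}

#' Assign the three-level priority class of a composite score
#'
#' Class 1 for \code{S >= 0.60}, class 2 for \code{0.40 <= S < 0.60}, class 3
#' for \code{S < 0.40}. The 0.60 boundary belongs to class 1.
#'
#' @param S Numeric vector of composite scores.
#' @return Integer vector of class labels in \code{{1, 2, 3}}.
#' @export
classify_score <- function(S) {
  ifelse(S >= 0.60, 1L, ifelse(S >= 0.40, 2L, 3L))
}

#' Score and classify a table of species
#'
#' @param score_table data.frame with a \code{species} column, optionally a
#'   \code{family} column, and one column per criterion id.
#' @param scheme A [criterion_scheme()].
#' @inheritParams composite_score
#' @return data.frame of score cards: species, family, score, class.
#' @export
score_species <- function(score_table, scheme,
                          normalization = c("per_criterion_max",
                                            "global_nine")) {
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(score_table), "species" %in% names(score_table))
  ids <- scheme$criteria$id
  missing <- setdiff(ids, names(score_table))
  if (length(missing)) stop("score table lacks criterion column(s): ",
                            paste(missing, collapse = ", "))
  S <- vapply(seq_len(nrow(score_table)), function(i) {
    composite_score(unlist(score_table[i, ids]), scheme, normalization)
  }, numeric(1))
  data.frame(species = score_table$species,
             family = if ("family" %in% names(score_table))
               score_table$family else NA_character_,
             score = round(S, 4), class = classify_score(S),
             stringsAsFactors = FALSE)
}

#' Rank species score cards into priority classes
#'
#' Cards are ordered by descending composite score (ties broken
#' alphabetically by species); class tallies and the family breakdown within
#' class 1 are attached.
#'
#' @param cards data.frame with columns \code{species}, \code{score} and
#'   optionally \code{family}; class labels are (re)derived from the scores.
#' @return List with \code{ranked} (rank, species, family, score, class),
#'   \code{class_tally} (named counts for classes 1-3) and
#'   \code{class1_families} (named family counts within class 1).
#' @export
rank_species <- function(cards) {
  stopifnot(is.data.frame(cards), nrow(cards) >= 1L,
            all(c("species", "score") %in% names(cards)))
  cards$class <- classify_score(cards$score)
  if (!"family" %in% names(cards)) cards$family <- NA_character_
  ord <- order(-cards$score, cards$species)
  ranked <- cards[ord, c("species", "family", "score", "class"), drop = FALSE]
  ranked <- cbind(rank = seq_len(nrow(ranked)), ranked)
  rownames(ranked) <- NULL
  tally <- vapply(1:3, function(k) sum(ranked$class == k), integer(1))
  names(tally) <- paste0("class", 1:3)
  fam1 <- ranked$family[ranked$class == 1L & !is.na(ranked$family)]
  list(ranked = ranked, class_tally = tally,
       class1_families = if (length(fam1)) sort(table(fam1), decreasing = TRUE)
       else table(character(0)))
}
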