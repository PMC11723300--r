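#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] used as plumbing when no externally
#' estimated tree is supplied; on an additive input matrix the tree's path
#' distances reproduce the input exactly.
#'
#' @param dm A [distance_matrix()] with at least 3 samples and no
#'   inapplicable entries.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (length(dm$ids) < 3L) stop("neighbor joining needs at least 3 samples")
  if (anyNA(dm$distances)) {
    bad <- which(is.na(dm$distances) & upper.tri(dm$distances), arr.ind = TRUE)
    stop("inapplicable distance(s) for pair(s): ",
         paste(dm$ids[bad[, 1]], dm$ids[bad[, 2]], sep = "~", collapse = ", "))
  }
  ape::nj(stats::as.dist(dm$distances))
}

# tip-index sets of every internal node, in node-number order
clade_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, as.integer)
}

numeric_support <- function(label) {
  if (is.null(label) || is.na(label) || !nzchar(label)) return(NA_real_)
  suppressWarnings(as.numeric(label))
}

#' Support-thresholded species monophyly on a tree
#'
#' A species with two or more tips is monophyletic when some split of the
#' unrooted tree separates exactly its tips from all others (the verdict is
#' invariant under re-rooting). With an active support threshold the species
#' additionally counts as a supported conspecific cluster only when the
#' split's support exceeds the threshold; splits without a recorded support
#' count as unsupported. Threshold 0 disables support gating. Singleton
#' species are reported but excluded from the headline rate.
#'
#' @param tree An [ape::phylo] tree; numeric internal node labels are read as
#'   support on a 0-100 scale.
#' @param taxonomy Taxonomy table covering every tip.
#' @param support_threshold Support threshold (default 95; strict
#'   inequality).
#' @return Object of class \code{monophyly_report}: per-species data.frame,
#'   headline \code{rate} (percent of multi-tip species forming supported
#'   conspecific clusters) and \code{n_singletons}.
#' @export
species_monophyly <- function(tree, taxonomy, support_threshold = 95) {
  stopifnot(inherits(tree, "phylo"))
  taxonomy <- validate_taxonomy(taxonomy)
  tips <- tree$tip.label
  missing <- setdiff(tips, taxonomy$sample_id)
  if (length(missing)) stop("tip(s) without taxonomy: ",
                            paste(missing, collapse = ", "))
  sp <- taxonomy$species[match(tips, taxonomy$sample_id)]
  ntip <- length(tips)
  clades <- clade_tip_sets(tree)
  labels <- tree$node.label
  species <- unique(sp)
  rows <- lapply(species, function(s) {
    idx <- sort(which(sp == s))
    if (length(idx) == 1L) {
      return(data.frame(species = s, n_tips = 1L, singleton = TRUE,
                        monophyletic = TRUE, support = NA_real_,
                        supported = NA, stringsAsFactors = FALSE))
    }
    mono <- FALSE; support <- NA_real_
    direct <- which(vapply(clades, function(cl)
      length(cl) == length(idx) && all(cl == idx), logical(1)))
    direct <- direct[direct != 1L]  # element 1 is the root clade (all tips)
    if (length(direct)) {
      mono <- TRUE
      support <- numeric_support(labels[direct[1]])
    } else if (length(idx) == ntip) {
      mono <- TRUE  # every tip is this species
    } else if (length(idx) == ntip - 1L) {
      # complement is a single tip: its pendant edge realizes the split
      mono <- TRUE
    } else {
      comp <- sort(setdiff(seq_len(ntip), idx))
      compl_match <- which(vapply(clades, function(cl)
        length(cl) == length(comp) && all(cl == comp), logical(1)))
      compl_match <- compl_match[compl_match != 1L]
      if (length(compl_match)) {
        mono <- TRUE
        support <- numeric_support(labels[compl_match[1]])
      }
    }
    supported <- if (support_threshold <= 0) mono else
      mono && !is.na(support) && support > support_threshold
    data.frame(species = s, n_tips = length(idx), singleton = FALSE,
               monophyletic = mono, support = support,
               supported = supported, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  multi <- per[!per$singleton, , drop = FALSE]
  rate <- if (nrow(multi)) 100 * sum(multi$supported) / nrow(multi) else NA_real_
  structure(list(per_species = per, rate = round(rate, 2),
                 n_singletons = sum(per$singleton),
                 support_threshold = support_threshold),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf(paste0("<monophyly_report> %d species (%d singletons), ",
                     "supported conspecific-cluster rate %.2f%% ",
                     "(threshold %g)\n"),
              nrow(x$per_species), x$n_singletons, x$rate,
              x$support_threshold))
  invisible(x)
}
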