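#' Split a distance matrix into intra- and inter-specific pools
#'
#' Every applicable off-diagonal entry lands in exactly one pool: intra when
#' both samples share a species, inter otherwise. Saturated (\code{NA})
#' entries are excluded and counted.
#'
#' @param dm A [distance_matrix()] result.
#' @param taxonomy Taxonomy table covering every matrix id.
#' @param label Marker or combination name carried on the pools.
#' @return An object of class \code{distance_pools}.
#' @export
pool_distances <- function(dm, taxonomy, label = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  taxonomy <- validate_taxonomy(taxonomy)
  missing <- setdiff(dm$ids, taxonomy$sample_id)
  if (length(missing)) stop("matrix id(s) without taxonomy: ",
                            paste(missing, collapse = ", "))
  sp <- taxonomy$species[match(dm$ids, taxonomy$sample_id)]
  names(sp) <- dm$ids
  n <- length(dm$ids)
  idx <- which(upper.tri(dm$distances), arr.ind = TRUE)
  d <- dm$distances[idx]
  ia <- dm$ids[idx[, 1]]; ib <- dm$ids[idx[, 2]]
  sa <- sp[ia]; sb <- sp[ib]
  ok <- !is.na(d)
  intra_sel <- ok & sa == sb
  inter_sel <- ok & sa != sb
  intra <- data.frame(species = sa[intra_sel], id_a = ia[intra_sel],
                      id_b = ib[intra_sel], distance = d[intra_sel],
                      stringsAsFactors = FALSE, row.names = NULL)
  inter <- data.frame(species_a = pmin(sa[inter_sel], sb[inter_sel]),
                      species_b = pmax(sa[inter_sel], sb[inter_sel]),
                      id_a = ia[inter_sel], id_b = ib[inter_sel],
                      distance = d[inter_sel],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(label = label %||% dm$model, model = dm$model,
                 intra = intra, inter = inter,
                 species = sp, n_inapplicable = sum(!ok)),
            class = "distance_pools")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary statistics for intra/inter distance pools
#'
#' @param pools A [pool_distances()] result.
#' @return One-row data.frame with min/max/mean per pool (NA for empty pools).
#' @export
summarize_pools <- function(pools) {
  stopifnot(inherits(pools, "distance_pools"))
  stat <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    c(min(x), max(x), mean(x))
  }
  si <- stat(pools$intra$distance); se <- stat(pools$inter$distance)
  data.frame(label = pools$label, model = pools$model,
             n_intra = nrow(pools$intra), n_inter = nrow(pools$inter),
             intra_min = si[1], intra_max = si[2], intra_mean = si[3],
             inter_min = se[1], inter_max = se[2], inter_mean = se[3],
             stringsAsFactors = FALSE)
}

#' Per-species barcoding-gap test
#'
#' A species shows a barcoding gap when its maximum intraspecific distance is
#' strictly less than its minimum distance to any other species. Singleton
#' species (one sample) have no intraspecific variation; they are judged on
#' \code{min_inter} alone with \code{max_intra = 0} and flagged.
#'
#' @param pools A [pool_distances()] result covering at least 2 species.
#' @return An object of class \code{gap_report}: per-species data.frame plus
#'   \code{overlap_fraction} (share of species without a gap) and the pooled
#'   summary row.
#' @export
barcode_gap <- function(pools) {
  stopifnot(inherits(pools, "distance_pools"))
  species <- sort(unique(pools$species))
  if (length(species) < 2L) stop("barcoding-gap test needs at least 2 species")
  per <- lapply(species, function(s) {
    own_intra <- pools$intra$distance[pools$intra$species == s]
    own_inter <- pools$inter$distance[pools$inter$species_a == s |
                                      pools$inter$species_b == s]
    singleton <- sum(pools$species == s) == 1L
    max_intra <- if (length(own_intra)) max(own_intra) else 0
    min_inter <- if (length(own_inter)) min(own_inter) else NA_real_
    data.frame(species = s, n_samples = sum(pools$species == s),
               singleton = singleton, max_intra = max_intra,
               min_inter = min_inter,
               gap_present = !is.na(min_inter) && max_intra < min_inter,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(label = pools$label, per_species = per,
                 overlap_fraction = mean(!per$gap_present),
                 pooled = summarize_pools(pools)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %s: %d species, overlap fraction %.3f\n",
              x$label, nrow(x$per_species), x$overlap_fraction))
  invisible(x)
}

#' Histogram counts of distance pools
#'
#' Bins are left-closed right-open, starting at 0, of the given width;
#' counts conserve pool sizes.
#'
#' @param pools A [pool_distances()] result.
#' @param bin_width Positive bin width on the distance scale.
#' @return data.frame with \code{bin_lower}, \code{bin_upper}, \code{intra},
#'   \code{inter} counts; zero rows when both pools are empty.
#' @export
gap_histogram <- function(pools, bin_width = 0.01) {
  stopifnot(inherits(pools, "distance_pools"), bin_width > 0)
  all_d <- c(pools$intra$distance, pools$inter$distance)
  if (!length(all_d)) {
    return(data.frame(bin_lower = numeric(), bin_upper = numeric(),
                      intra = integer(), inter = integer()))
  }
  nbin <- floor(max(all_d) / bin_width) + 1L
  lower <- (seq_len(nbin) - 1L) * bin_width
  count_in <- function(x) {
    if (!length(x)) return(integer(nbin))
    tabulate(pmin(floor(x / bin_width) + 1L, nbin), nbins = nbin)
  }
  data.frame(bin_lower = lower, bin_upper = lower + bin_width,
             intra = count_in(pools$intra$distance),
             inter = count_in(pools$inter$distance))
}

#' Concatenate aligned marker datasets
#'
#' Joins markers sample-wise over the samples present in every requested
#' marker; the combination is named by joining marker names with \code{"+"}.
#' Downstream distances are recomputed on the concatenated alignment rather
#' than averaged per marker.
#'
#' @param datasets List of two or more aligned [marker_dataset()]s.
#' @return A [marker_dataset()] for the combination.
#' @export
concatenate_markers <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  for (ds in datasets) {
    stopifnot(inherits(ds, "marker_dataset"))
    if (!ds$aligned) stop("marker ", ds$marker, " is not aligned")
  }
  ids <- Reduce(intersect, lapply(datasets, function(d) d$records$sample_id))
  if (!length(ids)) stop("no samples shared by all requested markers")
  first <- datasets[[1]]$records
  base <- first[match(ids, first$sample_id), , drop = FALSE]
  seqs <- lapply(datasets, function(d) {
    d$records$sequence[match(ids, d$records$sample_id)]
  })
  base$sequence <- do.call(paste0, seqs)
  combo <- paste(vapply(datasets, `[[`, character(1), "marker"),
                 collapse = "+")
  base$marker <- combo
  rownames(base) <- NULL
  marker_dataset(base, combo, aligned = TRUE)
}
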