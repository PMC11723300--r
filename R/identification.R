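#' Build a reference library from a marker dataset
#'
#' A reference library is a marker dataset whose every record carries full
#' taxonomy; it stands in for a public sequence database so identification
#' runs are reproducible offline.
#'
#' @param dataset A [marker_dataset()].
#' @return Object of class \code{reference_library}.
#' @export
reference_library <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  rec <- dataset$records
  if (!nrow(rec)) stop("reference library must be nonempty")
  incomplete <- !nzchar(rec$species) | !nzchar(rec$genus) | !nzchar(rec$family)
  if (any(incomplete)) stop("library record(s) with incomplete taxonomy: ",
                            paste(rec$sample_id[incomplete], collapse = ", "))
  structure(list(marker = dataset$marker, records = rec),
            class = "reference_library")
}

# percent identity of an end-gap-free global alignment, plus coverage
alignment_identity <- function(query, reference) {
  if (nchar(query) == nchar(reference)) {
    # already co-aligned (equal length): score column-wise directly
    cn <- pair_counts(query, reference)
    matches <- round((1 - cn$P - cn$Q) * cn$n)
    return(c(pi = 100 * matches / cn$n, coverage = 100 * cn$n /
               nchar(gsub("-", "", query, fixed = TRUE))))
  }
  q <- gsub("-", "", query, fixed = TRUE)
  r <- gsub("-", "", reference, fixed = TRUE)
  aln <- Biostrings::pairwiseAlignment(q, r, type = "overlap")
  comparable <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  if (comparable == 0) return(c(pi = 0, coverage = 0))
  c(pi = 100 * Biostrings::nmatch(aln) / comparable,
    coverage = 100 * comparable / nchar(q))
}

#' Best-hit identification of one query against a reference library
#'
#' Every reference is aligned to the query (end-gap-free global alignment;
#' co-aligned equal-length sequences are compared column-wise with pairwise
#' deletion) and scored by percent identity, PI = 100 x matches / comparable
#' aligned positions. The best hit is the highest PI, ties broken by higher
#' coverage then lexicographic reference id; hits below \code{min_identity}
#' are discarded. Verdicts compare the best hit's taxonomy to the query's at
#' species, genus and family rank.
#'
#' @param query One-row record (data.frame row) with sequence and taxonomy.
#' @param library A [reference_library()] sharing the query's marker.
#' @param min_identity Minimum PI (percent) for a hit to survive.
#' @param exclude_self Drop the reference with the query's own sample_id
#'   (leave-one-out; the default evaluation mode).
#' @return One-row data.frame: query id, best-hit id and taxonomy, PI,
#'   coverage, per-rank verdicts, and \code{no_hit} flag.
#' @export
best_hit <- function(query, library, min_identity = 0, exclude_self = TRUE) {
  stopifnot(inherits(library, "reference_library"))
  ref <- library$records
  if (exclude_self) ref <- ref[ref$sample_id != query$sample_id, , drop = FALSE]
  no_hit <- data.frame(query_id = query$sample_id, hit_id = NA_character_,
                       hit_species = NA_character_, pi = NA_real_,
                       coverage = NA_real_, species_match = FALSE,
                       genus_match = FALSE, family_match = FALSE,
                       no_hit = TRUE, stringsAsFactors = FALSE)
  if (!nrow(ref)) return(no_hit)
  scores <- do.call(rbind, lapply(ref$sequence, alignment_identity,
                                  query = query$sequence))
  colnames(scores) <- c("pi", "coverage")
  keep <- scores[, "pi"] >= min_identity
  if (!any(keep)) return(no_hit)
  ref <- ref[keep, , drop = FALSE]
  scores <- scores[keep, , drop = FALSE]
  ord <- order(-scores[, "pi"], -scores[, "coverage"], ref$sample_id)
  b <- ord[1]
  data.frame(query_id = query$sample_id, hit_id = ref$sample_id[b],
             hit_species = ref$species[b],
             pi = round(scores[b, "pi"], 4),
             coverage = round(scores[b, "coverage"], 4),
             species_match = ref$species[b] == query$species,
             genus_match = ref$genus[b] == query$genus,
             family_match = ref$family[b] == query$family,
             no_hit = FALSE, stringsAsFactors = FALSE)
}

#' Identify every query in a dataset against a library
#'
#' @param queries A [marker_dataset()] of query records.
#' @param library A [reference_library()].
#' @inheritParams best_hit
#' @return data.frame of [best_hit()] rows, one per query, with metadata
#'   attributes \code{min_identity} and \code{exclude_self}.
#' @export
identify_queries <- function(queries, library, min_identity = 0,
                             exclude_self = TRUE) {
  stopifnot(inherits(queries, "marker_dataset"))
  if (!nrow(queries$records)) stop("no query records")
  rows <- lapply(seq_len(nrow(queries$records)), function(i) {
    best_hit(queries$records[i, ], library, min_identity, exclude_self)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "min_identity") <- min_identity
  attr(out, "exclude_self") <- exclude_self
  out
}

#' Rank-level identification success rates
#'
#' \code{rate(rank) = 100 * successes(rank) / queries}. By construction of
#' consistent taxonomy the rates are monotone nonincreasing from family to
#' genus to species.
#'
#' @param reports Nonempty data.frame from [identify_queries()].
#' @return One-row data.frame with \code{n_queries} and species/genus/family
#'   rates (percent).
#' @export
success_rates <- function(reports) {
  if (!NROW(reports)) stop("no hit reports to summarize")
  n <- nrow(reports)
  data.frame(n_queries = n,
             species_rate = round(100 * sum(reports$species_match) / n, 2),
             genus_rate = round(100 * sum(reports$genus_match) / n, 2),
             family_rate = round(100 * sum(reports$family_match) / n, 2))
}
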