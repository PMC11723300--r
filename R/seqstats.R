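#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

# character matrix (rows = sequences, cols = alignment columns)
seq_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (!dataset$aligned) stop("dataset is not aligned: ", dataset$marker)
  m <- do.call(rbind, strsplit(dataset$records$sequence, "", fixed = TRUE))
  rownames(m) <- dataset$records$sample_id
  m
}

#' GC content of DNA sequences
#'
#' Percent G+C over the unambiguous bases A, C, G, T only; gaps and IUPAC
#' ambiguity codes are excluded from numerator and denominator.
#'
#' @param sequence Character vector of DNA strings.
#' @return Numeric vector of percentages in \eqn{[0, 100]}.
#' @export
gc_content <- function(sequence) {
  sequence <- normalize_dna(sequence)
  vapply(strsplit(sequence, "", fixed = TRUE), function(ch) {
    ch <- ch[ch %in% DNA_BASES]
    if (!length(ch)) stop("sequence has no unambiguous bases; GC undefined")
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
}

#' Classify alignment columns into conserved / variable sites
#'
#' For every alignment column, rows carrying a gap or ambiguity code are
#' dropped for that column. Columns retaining fewer than two unambiguous
#' bases are excluded from all classes. A retained column is conserved when
#' exactly one state remains, parsimony-informative when at least two states
#' occur each in at least two sequences, and a singleton (non-parsimonious
#' variable) site otherwise.
#'
#' @param dataset An aligned [marker_dataset()] with two or more sequences.
#' @return List with \code{aligned_length}, \code{conserved},
#'   \code{variable}, \code{parsimony_informative}, \code{singleton} and
#'   \code{excluded} counts, plus \code{conserved_pct} / \code{variable_pct}
#'   of the aligned length.
#' @export
site_classes <- function(dataset) {
  m <- seq_matrix(dataset)
  if (nrow(m) < 2L) stop("site classification needs at least 2 sequences")
  L <- ncol(m)
  cls <- apply(m, 2L, function(col) {
    col <- col[col %in% DNA_BASES]
    if (length(col) < 2L) return("excluded")
    tab <- table(col)
    if (length(tab) == 1L) return("conserved")
    if (sum(tab >= 2L) >= 2L) return("informative")
    "singleton"
  })
  counts <- c(conserved = sum(cls == "conserved"),
              parsimony_informative = sum(cls == "informative"),
              singleton = sum(cls == "singleton"),
              excluded = sum(cls == "excluded"))
  variable <- counts[["parsimony_informative"]] + counts[["singleton"]]
  list(aligned_length = L,
       conserved = counts[["conserved"]],
       variable = variable,
       parsimony_informative = counts[["parsimony_informative"]],
       singleton = counts[["singleton"]],
       excluded = counts[["excluded"]],
       conserved_pct = round(100 * counts[["conserved"]] / L, 2),
       variable_pct = round(100 * variable / L, 2))
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise p-distance over all unordered sequence pairs, with pairwise
#' deletion of sites where either sequence carries a gap or ambiguity code.
#'
#' @param dataset An aligned [marker_dataset()] with two or more sequences.
#' @return Nucleotide diversity in \eqn{[0, 1]}.
#' @export
nucleotide_diversity <- function(dataset) {
  dm <- distance_matrix(dataset, model = "p")
  d <- dm$distances[upper.tri(dm$distances)]
  if (anyNA(d)) stop("pair(s) with zero comparable sites; pi undefined")
  mean(d)
}

#' Summarize one marker's sequence characteristics
#'
#' One row with sequence counts, ungapped length range/mean, GC range/mean,
#' aligned length, site-class counts and nucleotide diversity. With a single
#' sequence the alignment-level fields are \code{NA}.
#'
#' @param dataset A [marker_dataset()].
#' @return One-row data.frame.
#' @export
summarize_marker <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  rec <- dataset$records
  if (!nrow(rec)) stop("empty dataset for marker ", dataset$marker)
  ungapped <- nchar(gsub("-", "", rec$sequence, fixed = TRUE))
  gc <- gc_content(rec$sequence)
  row <- data.frame(marker = dataset$marker,
                    n_sequences = nrow(rec),
                    length_min = min(ungapped), length_max = max(ungapped),
                    length_mean = round(mean(ungapped), 2),
                    gc_min = round(min(gc), 2), gc_max = round(max(gc), 2),
                    gc_mean = round(mean(gc), 2),
                    aligned_length = NA_integer_,
                    variable_sites = NA_integer_, variable_pct = NA_real_,
                    parsimony_informative_sites = NA_integer_,
                    singleton_sites = NA_integer_,
                    conserved_sites = NA_integer_, conserved_pct = NA_real_,
                    pi = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(rec) >= 2L && dataset$aligned) {
    sc <- site_classes(dataset)
    row$aligned_length <- sc$aligned_length
    row$variable_sites <- sc$variable
    row$variable_pct <- sc$variable_pct
    row$parsimony_informative_sites <- sc$parsimony_informative
    row$singleton_sites <- sc$singleton
    row$conserved_sites <- sc$conserved
    row$conserved_pct <- sc$conserved_pct
    row$pi <- round(nucleotide_diversity(dataset), 4)
  }
  row
}
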