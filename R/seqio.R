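#' Read a specimen taxonomy table
#'
#' Reads a delimited table (TSV or CSV, sniffed from the header line) with
#' columns \code{sample_id}, \code{species}, \code{genus}, \code{family} and
#' optionally further columns. Taxonomy must be internally consistent: a
#' species name always sits in the same genus, and a genus in the same family.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A data.frame with character columns, one row per specimen.
#' @export
read_taxonomy <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  validate_taxonomy(tab)
}

#' @keywords internal
validate_taxonomy <- function(tab) {
  need <- c("sample_id", "species", "genus", "family")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in need) tab[[col]] <- as.character(tab[[col]])
  if (anyDuplicated(tab$sample_id)) {
    dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
    stop("duplicate sample_id in taxonomy: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tab$sample_id))) stop("empty sample_id in taxonomy")
  # species implies genus implies family
  bad <- nzchar(tab$species) & (!nzchar(tab$genus) | !nzchar(tab$family))
  if (any(bad)) {
    stop("species without genus/family for sample(s): ",
         paste(tab$sample_id[bad], collapse = ", "))
  }
  # nested ranks must be consistent
  sp <- tab[nzchar(tab$species), , drop = FALSE]
  if (nrow(sp)) {
    g <- tapply(sp$genus, sp$species, function(x) length(unique(x)))
    f <- tapply(sp$family, sp$genus, function(x) length(unique(x)))
    if (any(g > 1)) stop("species mapped to >1 genus: ",
                         paste(names(g)[g > 1], collapse = ", "))
    if (any(f > 1)) stop("genus mapped to >1 family: ",
                         paste(names(f)[f > 1], collapse = ", "))
  }
  tab
}

#' Construct a marker dataset
#'
#' A marker dataset binds one marker's sequences to specimen taxonomy. It is
#' the unit every downstream stage consumes.
#'
#' @param records data.frame with columns \code{sample_id}, \code{species},
#'   \code{genus}, \code{family}, \code{marker}, \code{sequence}.
#' @param marker Marker name (e.g. \code{"ITS"}).
#' @param aligned Logical; if \code{NA}, inferred (\code{TRUE} when all
#'   sequences share one length and there is at least one sequence).
#' @return An object of class \code{marker_dataset}.
#' @export
marker_dataset <- function(records, marker, aligned = NA) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "species", "genus", "family", "marker", "sequence")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("records lack column(s): ",
                            paste(missing, collapse = ", "))
  if (nrow(records)) {
    if (anyDuplicated(records$sample_id)) {
      stop("duplicate sample_id within marker ", marker)
    }
    if (any(!nzchar(records$sequence))) stop("empty sequence in marker ", marker)
    records$sequence <- normalize_dna(records$sequence)
    records$marker <- marker
  }
  len <- nchar(records$sequence)
  if (is.na(aligned)) aligned <- nrow(records) > 0L && length(unique(len)) == 1L
  if (isTRUE(aligned) && nrow(records) && length(unique(len)) != 1L) {
    stop("aligned dataset has unequal sequence lengths for marker ", marker)
  }
  structure(list(marker = marker, records = records, aligned = isTRUE(aligned)),
            class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("<marker_dataset> %s: %d sequences, %s\n", x$marker,
              nrow(x$records),
              if (x$aligned) sprintf("aligned (%d columns)",
                                     if (nrow(x$records)) nchar(x$records$sequence[1]) else 0L)
              else "unaligned"))
  invisible(x)
}

# Upper-case, map RNA U to T. Gaps '-' and IUPAC ambiguity codes are kept.
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Read a FASTA file into a marker dataset
#'
#' The first whitespace-delimited token of each header is the sample id and
#' must resolve to a row of the taxonomy table. Sequences are upper-cased and
#' RNA \code{U} is mapped to \code{T}; gaps and IUPAC ambiguity codes pass
#' through.
#'
#' @param path FASTA file path.
#' @param taxonomy Taxonomy table as returned by [read_taxonomy()].
#' @param marker Marker name recorded on every resulting record.
#' @return A [marker_dataset()].
#' @export
read_barcode_fasta <- function(path, taxonomy, marker) {
  taxonomy <- validate_taxonomy(taxonomy)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  unknown <- setdiff(ids, taxonomy$sample_id)
  if (length(unknown)) {
    stop("FASTA sample_id(s) absent from taxonomy: ",
         paste(unknown, collapse = ", "))
  }
  if (!length(ids)) {
    records <- data.frame(sample_id = character(), species = character(),
                          genus = character(), family = character(),
                          marker = character(), sequence = character(),
                          stringsAsFactors = FALSE)
    return(marker_dataset(records, marker, aligned = FALSE))
  }
  idx <- match(ids, taxonomy$sample_id)
  records <- data.frame(sample_id = ids,
                        species = taxonomy$species[idx],
                        genus = taxonomy$genus[idx],
                        family = taxonomy$family[idx],
                        marker = marker,
                        sequence = as.character(set),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  marker_dataset(records, marker)
}

#' Write a marker dataset to FASTA
#'
#' @param dataset A [marker_dataset()].
#' @param path Output FASTA path.
#' @export
write_barcode_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "marker_dataset"))
  lines <- character(0)
  if (nrow(dataset$records)) {
    lines <- as.vector(rbind(paste0(">", dataset$records$sample_id),
                             dataset$records$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Newick tree with optional support labels
#'
#' Internal node labels, when numeric, are interpreted as branch support on a
#' 0-100 scale (the UFBoot convention).
#'
#' @param path Newick file path, or a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse Newick input: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  tr
}

#' Write a results table as TSV
#'
#' Writes a header plus rows, tab-separated; round-trips losslessly for
#' character and numeric columns via [read_result_table()].
#'
#' @param rows data.frame of results.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}
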