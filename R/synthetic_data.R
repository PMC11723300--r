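#' Default per-marker simulation profiles
#'
#' Three profiles shaped like the nuclear ITS and plastid matK/rbcL barcodes:
#' ITS and matK diverge fast with distinct GC targets, rbcL is slow and
#' conserved, so realized mean inter-specific distances order as
#' ITS = matK > rbcL.
#'
#' @return Named list of profiles (\code{length}, \code{gc}, \code{intra},
#'   \code{inter}, \code{tstv}).
#' @export
default_marker_profiles <- function() {
  list(ITS  = list(length = 700L, gc = 0.56, intra = 0.02, inter = 0.12,
                   tstv = 2),
       matK = list(length = 800L, gc = 0.34, intra = 0.02, inter = 0.12,
                   tstv = 2),
       rbcL = list(length = 600L, gc = 0.44, intra = 0.005, inter = 0.05,
                   tstv = 2))
}

#' Simulation configuration
#'
#' Defines the taxonomic shape (families / genera / species / samples), the
#' per-marker divergence profiles and whether a barcoding gap is enforced.
#' With \code{gap_present = TRUE} every marker must satisfy
#' \code{intra < inter}; with \code{gap_present = FALSE} the flora contains
#' a cryptic species pair (shared ancestor, inflated intraspecific
#' divergence on one side) so the intra- and inter-specific distance pools
#' overlap.
#'
#' @param seed Integer RNG seed; every generator is a pure function of
#'   config + seed.
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape.
#' @param samples_per_species Integer vector recycled across species
#'   (1 = singleton species).
#' @param markers Named list of marker profiles, see
#'   [default_marker_profiles()].
#' @param gap_present Enforce intra < inter divergence at generation level.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_families = 3L, genera_per_family = 2L,
                       species_per_genus = 2L,
                       samples_per_species = c(2L, 3L),
                       markers = default_marker_profiles(),
                       gap_present = TRUE) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            all(samples_per_species >= 1), length(markers) >= 1)
  for (nm in names(markers)) {
    p <- markers[[nm]]
    stopifnot(p$length >= 100L, p$gc > 0, p$gc < 1,
              p$intra > 0, p$intra < 1, p$inter > 0, p$inter < 1,
              p$tstv > 0)
    if (gap_present && p$intra >= p$inter) {
      stop("gap_present config requires intra < inter for marker ", nm)
    }
  }
  structure(list(seed = as.integer(seed), n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 samples_per_species = samples_per_species,
                 markers = markers, gap_present = gap_present),
            class = "sim_config")
}

# per-site two-rate substitution: transitions (A<->G, C<->T) favored over
# the two transversion alternatives by the tstv ratio
mutate_seq <- function(seq, rate, tstv) {
  L <- length(seq)
  hit <- which(stats::runif(L) < rate)
  if (!length(hit)) return(seq)
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  is_ts <- stats::runif(length(hit)) < tstv / (tstv + 1)
  for (k in seq_along(hit)) {
    b <- seq[hit[k]]
    seq[hit[k]] <- if (is_ts[k]) partner[[b]] else
      tv[[b]][1L + (stats::runif(1) < 0.5)]
  }
  seq
}

random_root <- function(L, gc) {
  sample(DNA_BASES, L, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate aligned multi-marker barcode data with taxonomy
#'
#' Sequences evolve down the family -> genus -> species ancestor cascade at
#' half the configured inter-specific rate per level, so the closest species
#' pairs (congeners) diverge at about \code{inter}; individuals mutate from
#' their species ancestor at half the intra-specific rate. Generation is
#' columnwise independent (no indels), so datasets come out aligned.
#'
#' @param config A [sim_config()].
#' @return List with \code{markers} (named list of aligned
#'   [marker_dataset()]s), \code{taxonomy} (one row per sample) and
#'   \code{ancestors} (per marker, per species ancestor sequences, used by
#'   [simulate_reference_library()]).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # taxonomy scaffold
  fam <- sprintf("Family%02d", seq_len(config$n_families))
  rows <- list(); sp_meta <- list()
  s <- 0L
  for (f in seq_len(config$n_families)) {
    for (g in seq_len(config$genera_per_family)) {
      genus <- sprintf("Genus%02d_%02d", f, g)
      for (k in seq_len(config$species_per_genus)) {
        s <- s + 1L
        sp_meta[[s]] <- list(species = sprintf("Species%03d", s),
                             genus = genus, family = fam[f],
                             fam_i = f, gen_i = g)
      }
    }
  }
  n_species <- s
  nsamp <- rep_len(config$samples_per_species, n_species)
  taxonomy <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    m <- sp_meta[[i]]
    data.frame(sample_id = sprintf("%s_v%02d", m$species, seq_len(nsamp[i])),
               species = m$species, genus = m$genus, family = m$family,
               stringsAsFactors = FALSE)
  }))
  rownames(taxonomy) <- NULL

  markers <- list(); ancestors <- list()
  for (nm in names(config$markers)) {
    p <- config$markers[[nm]]
    half <- p$inter / 2
    root <- random_root(p$length, p$gc)
    fam_anc <- lapply(seq_len(config$n_families), function(f)
      mutate_seq(root, half, p$tstv))
    gen_anc <- list(); sp_anc <- list()
    for (i in seq_len(n_species)) {
      m <- sp_meta[[i]]
      key <- m$genus
      if (is.null(gen_anc[[key]])) {
        gen_anc[[key]] <- mutate_seq(fam_anc[[m$fam_i]], half, p$tstv)
      }
      sp_anc[[m$species]] <- mutate_seq(gen_anc[[key]], half, p$tstv)
    }
    seqs <- character(nrow(taxonomy))
    sp_intra <- rep(p$intra, n_species)
    if (!config$gap_present && n_species >= 2L) {
      # cryptic pair: two species share their ancestor while the first
      # carries inflated intraspecific divergence, so its intra distances
      # overrun its distances to the sibling species (no barcoding gap)
      sp_anc[[sp_meta[[2L]]$species]] <- sp_anc[[sp_meta[[1L]]$species]]
      sp_intra[1L] <- 3 * p$intra
    }
    for (i in seq_len(n_species)) {
      m <- sp_meta[[i]]
      sel <- taxonomy$species == m$species
      seqs[sel] <- vapply(seq_len(sum(sel)), function(j)
        paste(mutate_seq(sp_anc[[m$species]], sp_intra[i] / 2, p$tstv),
              collapse = ""),
        character(1))
    }
    rec <- cbind(taxonomy, marker = nm, sequence = seqs,
                 stringsAsFactors = FALSE)
    markers[[nm]] <- marker_dataset(rec, nm, aligned = TRUE)
    ancestors[[nm]] <- list(species = sp_anc, profile = p)
  }
  list(markers = markers, taxonomy = taxonomy, ancestors = ancestors,
       config = config)
}

#' Simulate a reference library with decoys
#'
#' Builds an offline stand-in for a public sequence database: for every
#' species, \code{n_conspecific} fresh records mutated from the species
#' ancestor at the intraspecific rate. Congeneric and confamilial decoys are
#' present automatically because every species of the simulated flora is
#' represented. Conspecific records can be withheld for selected species,
#' emulating database gaps that force genus-level identification.
#'
#' @param sim Result of [simulate_sequences()].
#' @param marker Marker name (default: first configured marker).
#' @param n_conspecific Conspecific records per species.
#' @param omit_conspecific Character vector of species whose conspecific
#'   records are withheld.
#' @return List with \code{library} (a [reference_library()]) and
#'   \code{taxonomy} for the reference records.
#' @export
simulate_reference_library <- function(sim, marker = NULL, n_conspecific = 2L,
                                       omit_conspecific = character()) {
  stopifnot(is.list(sim), !is.null(sim$ancestors))
  marker <- marker %||% names(sim$markers)[1]
  anc <- sim$ancestors[[marker]]
  if (is.null(anc)) stop("unknown marker: ", marker)
  p <- anc$profile
  set.seed(sim$config$seed + 1000L)
  tax <- unique(sim$taxonomy[, c("species", "genus", "family")])
  rows <- list()
  for (i in seq_len(nrow(tax))) {
    s <- tax$species[i]
    if (s %in% omit_conspecific) next
    for (k in seq_len(n_conspecific)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("REF_%s_%02d", s, k),
        species = s, genus = tax$genus[i], family = tax$family[i],
        marker = marker,
        sequence = paste(mutate_seq(anc$species[[s]], p$intra / 2, p$tstv),
                         collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("empty reference library (all species omitted)")
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  ds <- marker_dataset(rec, marker, aligned = TRUE)
  list(library = reference_library(ds),
       taxonomy = rec[, c("sample_id", "species", "genus", "family")])
}

#' Simulate per-species criterion scores
#'
#' Draws, for each species and criterion, one of the criterion's declared
#' level points. Sampling weights run from the lowest to the highest level
#' per criterion; by default all levels are equally likely.
#'
#' @param config A [sim_config()] (only the seed and species count are
#'   used) or an integer seed.
#' @param scheme A [criterion_scheme()].
#' @param species Character vector of species names; defaults to the
#'   config's species set.
#' @param level_weights Optional named list (by criterion id) of sampling
#'   weights over that criterion's levels, ordered by increasing points.
#' @return data.frame: species plus one column per criterion id.
#' @export
simulate_ahp_scores <- function(config, scheme, species = NULL,
                                level_weights = NULL) {
  stopifnot(inherits(scheme, "criterion_scheme"))
  if (inherits(config, "sim_config")) {
    seed <- config$seed
    if (is.null(species)) {
      n_sp <- config$n_families * config$genera_per_family *
        config$species_per_genus
      species <- sprintf("Species%03d", seq_len(n_sp))
    }
  } else {
    seed <- as.integer(config)
    if (is.null(species)) stop("species must be given with a bare seed")
  }
  set.seed(seed + 2000L)
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  for (id in scheme$criteria$id) {
    pts <- sort(unique(scheme$levels$points[scheme$levels$criterion == id]))
    w <- level_weights[[id]] %||% rep(1, length(pts))
    if (length(w) != length(pts)) {
      stop("level_weights for ", id, " must have ", length(pts), " entries")
    }
    out[[id]] <- sample(pts, length(species), replace = TRUE, prob = w)
  }
  out
}
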