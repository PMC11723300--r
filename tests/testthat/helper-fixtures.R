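# in-code fixtures shared across test files

# marker_dataset + taxonomy from named sequences and a species map
make_ds <- function(seqs, species, marker = "ITS", aligned = NA) {
  genus <- paste0("G_", sub("_.*$", "", species))
  family <- paste0("F_", sub("_.*$", "", species))
  rec <- data.frame(sample_id = names(seqs), species = species,
                    genus = genus, family = family, marker = marker,
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  ds <- marker_dataset(rec, marker, aligned = aligned)
  list(ds = ds, taxonomy = rec[, c("sample_id", "species", "genus", "family")])
}

# dist_matrix object from a raw symmetric matrix (delimitation toys)
make_dm <- function(m, ids = NULL, model = "p") {
  ids <- ids %||% (rownames(m) %||% paste0("s", seq_len(nrow(m))))
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, model = model, distances = m,
                 n_sites = matrix(100L, nrow(m), ncol(m),
                                  dimnames = dimnames(m)),
                 n_inapplicable = sum(is.na(m[upper.tri(m)]))),
            class = "dist_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distances of points on a line: fully controllable sorted-distance spectrum
dm_from_points <- function(x, ids = paste0("s", seq_along(x))) {
  make_dm(abs(outer(x, x, "-")), ids = ids)
}

# independent brute-force per-site tally (oracle for the distance kernel)
oracle_pair <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  P <- 0; Q <- 0; n <- 0
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(a)) {
    if (!(a[i] %in% bases) || !(b[i] %in% bases)) next
    n <- n + 1
    if (a[i] == b[i]) next
    pair <- sort(c(a[i], b[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
      P <- P + 1
    } else Q <- Q + 1
  }
  list(P = P / n, Q = Q / n, n = n)
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# reciprocal matrix as a bounded perturbation of a consistent one
random_reciprocal <- function(n, noise = 1.5) {
  w <- stats::runif(n, 0.5, 2)
  base <- outer(w, w, "/")
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- base[i, j] * stats::runif(1, 1 / noise, noise)
    v <- min(max(v, 1 / 9), 9)
    m[i, j] <- v; m[j, i] <- 1 / v
  }
  m
}

# acceptance-grade gap configuration: K species with an enforced gap
gap_config <- function(seed, K = 5L, length = 800L, intra = 0.02,
                       inter = 0.10, gap_present = TRUE,
                       samples = c(2L, 3L)) {
  sim_config(seed = seed, n_families = 1L, genera_per_family = 1L,
             species_per_genus = K, samples_per_species = samples,
             markers = list(ITS = list(length = length, gc = 0.5,
                                       intra = intra, inter = inter,
                                       tstv = 2)),
             gap_present = gap_present)
}
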