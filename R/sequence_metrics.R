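#' Barcode compliance configuration
#'
#' Thresholds of the DNA barcode data standard as applied to library
#' membership: a sequence must be longer than `min_length` non-gap bases
#' (strict: 501 bp passes at the 500 bp default) and carry strictly fewer
#' ambiguous bases than `max_ambiguity_fraction` of its length (strict:
#' exactly 1% fails at the 0.01 default). `require_species_name` demands a
#' species-level identification.
#'
#' @param min_length Minimum sequence length in bp (non-gap characters).
#' @param max_ambiguity_fraction Maximum tolerated fraction of non-ACGT,
#'   non-gap characters.
#' @param require_species_name Require a non-empty species name?
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(min_length = 500L, max_ambiguity_fraction = 0.01,
                      require_species_name = TRUE) {
  stopifnot(min_length > 0,
            max_ambiguity_fraction > 0, max_ambiguity_fraction < 1,
            is.logical(require_species_name))
  structure(list(min_length = as.integer(min_length),
                 max_ambiguity_fraction = max_ambiguity_fraction,
                 require_species_name = isTRUE(require_species_name)),
            class = "qc_config")
}

#' Check records against the barcode data standard
#'
#' Total and deterministic: every record gets a verdict, failures carry every
#' applicable reason code among `NO_SEQUENCE`, `TOO_SHORT`, `TOO_AMBIGUOUS`,
#' `NO_SPECIES`. Length is counted over non-gap characters; the ambiguity
#' fraction is (non-ACGT, non-gap characters) / length. An empty sequence
#' reports `NO_SEQUENCE` and `TOO_SHORT` but not `TOO_AMBIGUOUS` (the
#' fraction is undefined at length zero).
#'
#' @param ds A `specimen_df` (or any data.frame with `process_id`,
#'   `sequence`, `species` columns).
#' @param cfg A [qc_config()].
#' @return data.frame(process_id, pass, reasons) where `reasons` is a list
#'   column of character vectors (empty for passes).
#' @export
compliance_check <- function(ds, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  seqs <- ds$sequence
  no_gap <- gsub("-", "", seqs)
  len <- nchar(no_gap)
  n_ambig <- nchar(gsub("[ACGT]", "", no_gap))
  reasons <- vector("list", nrow(ds))
  for (i in seq_len(nrow(ds))) {
    r <- character(0)
    if (len[i] == 0L) r <- c(r, "NO_SEQUENCE")
    if (len[i] <= cfg$min_length) r <- c(r, "TOO_SHORT")
    if (len[i] > 0L && n_ambig[i] / len[i] >= cfg$max_ambiguity_fraction)
      r <- c(r, "TOO_AMBIGUOUS")
    if (cfg$require_species_name && !nzchar(ds$species[i]))
      r <- c(r, "NO_SPECIES")
    reasons[[i]] <- r
  }
  out <- data.frame(process_id = ds$process_id,
                    pass = lengths(reasons) == 0L,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  out
}

# Encode A/C/G/T as 1..4; gaps and ambiguity codes become NA and are
# excluded pairwise from all distance calculations.
.encode_dna <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
}

# Site-pattern counts for two encoded sequences of equal length.
# Transitions are A<->G and C<->T: under the 1..4 encoding those are exactly
# the mismatches with |difference| == 2.
.pair_counts <- function(xa, xb) {
  ok <- !is.na(xa) & !is.na(xb)
  n <- sum(ok)
  if (n == 0L) return(list(n = 0L, ts = 0L, tv = 0L))
  diff <- xa[ok] != xb[ok]
  ts <- sum(diff & abs(xa[ok] - xb[ok]) == 2L)
  list(n = n, ts = ts, tv = sum(diff) - ts)
}

.distance_result <- function(cnt) {
  P <- cnt$ts / cnt$n
  Q <- cnt$tv / cnt$n
  structure(list(comparable_sites = cnt$n, transitions = cnt$ts,
                 transversions = cnt$tv, P = P, Q = Q,
                 p_dist = P + Q, k2p_dist = NA_real_),
            class = "distance_result")
}

.check_pair <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must be pre-aligned to equal length (",
         nchar(a), " vs ", nchar(b), " bp)")
}

#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of differing sites between two equal-length (pre-aligned)
#' sequences under pairwise deletion: any site where either sequence carries
#' a gap or an ambiguity code is excluded from the comparable sites.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return A `"distance_result"`: comparable_sites, transitions,
#'   transversions, P (transition fraction), Q (transversion fraction),
#'   p_dist = P + Q, and k2p_dist (NA here; see [k2p_distance()]).
#' @export
p_distance <- function(a, b) {
  .check_pair(a, b)
  cnt <- .pair_counts(.encode_dna(a), .encode_dna(b))
  if (cnt$n == 0L)
    stop("undefined distance: no comparable (unambiguous) sites")
  .distance_result(cnt)
}

#' Kimura 2-parameter distance
#'
#' K2P-corrected distance d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)) with
#' P and Q the transition and transversion fractions over comparable sites
#' (pairwise deletion, as in [p_distance()]). When the logarithm's argument
#' is non-positive the distance is saturated: `k2p_dist` is set to `NA` and
#' a warning of class `"barcodelib_saturated_distance"` is signalled rather
#' than returning an infinite value.
#'
#' @inheritParams p_distance
#' @return A `"distance_result"` with `k2p_dist` populated.
#' @export
k2p_distance <- function(a, b) {
  res <- p_distance(a, b)
  res$k2p_dist <- .k2p_from_pq(res$P, res$Q)
  if (is.na(res$k2p_dist))
    warning(warningCondition(
      "saturated distance: K2P correction undefined (log domain violation)",
      class = "barcodelib_saturated_distance"))
  res
}

.k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix
#'
#' Symmetric matrix of p or K2P distances over a set of keyed, pre-aligned
#' sequences; diagonal exactly zero. Any pairwise failure (length mismatch,
#' no comparable sites, K2P saturation) is raised as an error naming the
#' offending pair.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param metric `"p"` (uncorrected, default) or `"k2p"`.
#' @return Numeric matrix with the sequence names as dimnames.
#' @export
distance_matrix <- function(seqs, metric = c("p", "k2p")) {
  metric <- match.arg(metric)
  n <- length(seqs)
  if (n == 0L) stop("need at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("sequences must be named")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("sequences must be pre-aligned to equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  enc <- lapply(unname(seqs), .encode_dna)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(m)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- .pair_counts(enc[[i]], enc[[j]])
      if (cnt$n == 0L)
        stop("undefined distance for pair ", ids[i], " / ", ids[j],
             ": no comparable sites")
      d <- if (metric == "p") (cnt$ts + cnt$tv) / cnt$n
           else .k2p_from_pq(cnt$ts / cnt$n, cnt$tv / cnt$n)
      if (is.na(d))
        stop("saturated distance for pair ", ids[i], " / ", ids[j])
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Per-species intraspecific divergence summaries
#'
#' For each species, distance statistics over all n*(n-1)/2 within-species
#' specimen pairs: mean, standard error (sample SD of the pairwise distances
#' divided by sqrt(number of pairs) — pairs treated as observations, their
#' non-independence acknowledged), minimum and maximum. Species with a
#' single specimen have zero pairs and undefined (NA) statistics.
#'
#' @param species_to_seqs Named list: canonical species name -> named
#'   character vector of that species' aligned sequences.
#' @param metric `"p"` or `"k2p"`.
#' @return data.frame(species, n_specimens, n_pairs, mean, se, min, max).
#' @export
intraspecific_stats <- function(species_to_seqs, metric = c("k2p", "p")) {
  metric <- match.arg(metric)
  rows <- lapply(names(species_to_seqs), function(sp) {
    seqs <- species_to_seqs[[sp]]
    n <- length(seqs)
    if (n < 2L)
      return(data.frame(species = sp, n_specimens = n, n_pairs = 0L,
                        mean = NA_real_, se = NA_real_, min = NA_real_,
                        max = NA_real_, stringsAsFactors = FALSE))
    dm <- distance_matrix(seqs, metric = metric)
    d <- dm[lower.tri(dm)]
    data.frame(species = sp, n_specimens = n, n_pairs = length(d),
               mean = mean(d),
               se = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0,
               min = min(d), max = max(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(species = character(0), n_specimens = integer(0),
                      n_pairs = integer(0), mean = numeric(0), se = numeric(0),
                      min = numeric(0), max = numeric(0))
  out
}

#' Flag potential cryptic species by mean intraspecific divergence
#'
#' Species whose mean within-species divergence strictly exceeds the
#' threshold (default 2%) may represent cryptic species complexes. Species
#' with undefined means (single specimens) are never flagged.
#'
#' @param summaries Output of [intraspecific_stats()].
#' @param threshold Divergence fraction; strictly-greater comparison.
#' @return Character vector of species, ordered by decreasing mean.
#' @export
flag_high_divergence <- function(summaries, threshold = 0.02) {
  hit <- summaries[!is.na(summaries$mean) & summaries$mean > threshold, ]
  hit$species[order(hit$mean, decreasing = TRUE)]
}
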