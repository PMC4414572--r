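# Name pools for synthetic taxa. Genus/epithet stems are chosen so that any
# two epithets assigned to the same genus are several edits apart: planted
# one-edit misspellings then resolve to their own species only.
.genus_pool <- c(
  "Lygaeodes", "Aphidura", "Cicadulina", "Miriphaga", "Corixella",
  "Psyllomorpha", "Delphacodes", "Tingidella", "Nabicula", "Pentatomina",
  "Cercopidia", "Membracina", "Aleyrodina", "Coccidula", "Saldulopsis",
  "Gerrimorpha", "Reduviolus", "Berytinopsis", "Piesmodes", "Anthocorella"
)
.epithet_pool <- c(
  "lineolaris", "quadratus", "septentrionalis", "borealis", "fuscipennis",
  "marginatus", "punctulatus", "viridescens", "canadensis", "obscurellus",
  "rubromaculatus", "pallidicornis", "nigrofasciatus", "longirostris",
  "brevicollis", "flavomarginatus", "albonotatus", "griseipes",
  "sulcifrons", "tibialis", "ventralis", "humeralis", "costalis",
  "apicalis", "basalis", "dorsalis", "lateralis", "frontalis",
  "carinatus", "spinifer", "granulosus", "velutinus", "pruinosus",
  "maculipennis", "angustatus", "dilatatus", "depressus", "elevatus",
  "confluens", "interruptus"
)
.old_genus_pool <- c(
  "Palaeocoris", "Archinabis", "Protolygus", "Eocicadula", "Priscaphis",
  "Veterocorixa", "Antiquella", "Fossorina"
)

#' Configuration for the synthetic barcode dataset generator
#'
#' Defines the statistical structure the audit assumes of real COI-5P data:
#' several species with low intraspecific and clearly higher interspecific
#' divergence, transition-biased substitutions, plus planted curation
#' artifacts (unidentified specimens, synonyms, misspellings, non-compliant
#' sequences, species deliberately sharing a haplotype cluster).
#'
#' @param n_species Number of species.
#' @param specimens_per_species Inclusive range `c(lo, hi)` sampled per
#'   species.
#' @param seq_length Barcode length in bp (default 658, full COI-5P).
#' @param intra_divergence Target intraspecific p-distance.
#' @param inter_divergence Guaranteed minimum interspecific p-distance; must
#'   exceed `2 * intra_divergence`.
#' @param kappa Transition/transversion rate ratio (default 3, a typical
#'   mitochondrial bias).
#' @param fraction_unidentified Fraction of specimens stripped of their
#'   species name.
#' @param n_synonym_pairs Species relabelled with a junior synonym (and the
#'   synonym table entry to resolve it).
#' @param n_misspellings Species relabelled with a one-edit epithet typo.
#' @param n_noncompliant Records made QC-failing (alternately truncated
#'   below 500 bp and salted with >1% Ns).
#' @param sharing_groups List of integer vectors (species indices) forced to
#'   share one haplotype cluster (producing discordant bins).
#' @param seed RNG seed; same config + seed gives identical output.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_species = 20L,
                              specimens_per_species = c(3L, 8L),
                              seq_length = 658L,
                              intra_divergence = 0.005,
                              inter_divergence = 0.06,
                              kappa = 3,
                              fraction_unidentified = 0.1,
                              n_synonym_pairs = 2L,
                              n_misspellings = 2L,
                              n_noncompliant = 3L,
                              sharing_groups = list(),
                              seed = 1L) {
  stopifnot(n_species >= 1, seq_length > 0, kappa > 0,
            length(specimens_per_species) == 2,
            specimens_per_species[1] >= 1,
            specimens_per_species[2] >= specimens_per_species[1],
            intra_divergence >= 0, intra_divergence <= 1,
            inter_divergence > 0, inter_divergence <= 1,
            fraction_unidentified >= 0, fraction_unidentified < 1)
  if (inter_divergence <= 2 * intra_divergence)
    stop("inter_divergence must exceed 2 * intra_divergence ",
         "for cluster recovery to be well-posed")
  if (n_species > length(.epithet_pool))
    stop("n_species capped at ", length(.epithet_pool),
         " by the name pool")
  sharing_groups <- lapply(sharing_groups, as.integer)
  for (g in sharing_groups)
    stopifnot(length(g) >= 2, all(g >= 1), all(g <= n_species))
  if (anyDuplicated(unlist(sharing_groups)))
    stop("sharing_groups must be disjoint")
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = as.integer(specimens_per_species),
                 seq_length = as.integer(seq_length),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 kappa = kappa,
                 fraction_unidentified = fraction_unidentified,
                 n_synonym_pairs = as.integer(n_synonym_pairs),
                 n_misspellings = as.integer(n_misspellings),
                 n_noncompliant = as.integer(n_noncompliant),
                 sharing_groups = sharing_groups,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Transition-biased substitution: A<->G, C<->T with probability
# kappa/(kappa+2), else one of the two transversions.
.mutate_base <- function(base, kappa) {
  bases <- c("A", "C", "G", "T")
  ti <- c(A = "G", C = "T", G = "A", T = "C")
  if (stats::runif(1) < kappa / (kappa + 2)) ti[[base]]
  else sample(setdiff(bases, c(base, ti[[base]])), 1L)
}

#' Simulate aligned COI-like sequences with known cluster truth
#'
#' Each haplotype cluster (one per species, except species forced together
#' by `sharing_groups`) derives from a shared root sequence by substitutions
#' at a cluster-specific disjoint block of `ceil(inter_divergence * L / 2)`
#' sites, which guarantees every between-cluster p-distance is at least
#' `inter_divergence`. Specimens then accumulate
#' `round(intra_divergence / 2 * L)` substitutions at sites outside all
#' blocks (transition-biased, no indels), bounding within-cluster
#' p-distances by twice that count. Realized extremes are measured and
#' returned, not assumed.
#'
#' @param cfg A [simulation_config()].
#' @return list: `sequences` (named char vector, process-ID keyed), `truth`
#'   (data.frame process_id, species, cluster), `species_names`,
#'   `cluster_of` (species -> cluster id), `realized` (max_intra_p,
#'   min_inter_p).
#' @export
simulate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  n_sp <- cfg$n_species
  # species -> cluster (sharing groups collapse onto one cluster)
  cluster_of <- seq_len(n_sp)
  for (g in cfg$sharing_groups) cluster_of[g] <- min(g)
  cluster_ids <- unique(cluster_of)
  m <- ceiling(cfg$inter_divergence * L / 2)
  if (length(cluster_ids) * m > L)
    stop("unattainable divergence constraints: ", length(cluster_ids),
         " clusters x ", m, " block sites exceed sequence length ", L)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  blocks <- split(seq_len(length(cluster_ids) * m),
                  rep(seq_along(cluster_ids), each = m))
  names(blocks) <- cluster_ids
  ancestors <- lapply(seq_along(cluster_ids), function(i) {
    anc <- root
    for (pos in blocks[[i]]) anc[pos] <- .mutate_base(anc[pos], cfg$kappa)
    anc
  })
  names(ancestors) <- cluster_ids
  free_sites <- setdiff(seq_len(L), unlist(blocks))
  n_mut <- max(1L, round(cfg$intra_divergence / 2 * L))
  if (length(free_sites) < n_mut)
    stop("unattainable divergence constraints: no free sites left for ",
         "intraspecific variation")
  genus_idx <- rep(seq_len(ceiling(n_sp / 2)), each = 2)[seq_len(n_sp)]
  species_names <- paste(.genus_pool[genus_idx], .epithet_pool[seq_len(n_sp)])
  n_per <- sample(seq(cfg$specimens_per_species[1],
                      cfg$specimens_per_species[2]),
                  n_sp, replace = TRUE)
  seqs <- character(0)
  truth_sp <- character(0)
  truth_cl <- integer(0)
  for (s in seq_len(n_sp)) {
    anc <- ancestors[[as.character(cluster_of[s])]]
    for (k in seq_len(n_per[s])) {
      x <- anc
      for (pos in sample(free_sites, n_mut))
        x[pos] <- .mutate_base(x[pos], cfg$kappa)
      seqs <- c(seqs, paste(x, collapse = ""))
      truth_sp <- c(truth_sp, species_names[s])
      truth_cl <- c(truth_cl, cluster_of[s])
    }
  }
  ids <- sprintf("SIM%05d", seq_along(seqs))
  names(seqs) <- ids
  dm <- distance_matrix(seqs, metric = "p")
  same <- outer(truth_cl, truth_cl, "==")
  lower <- lower.tri(dm)
  realized <- list(
    max_intra_p = if (any(same & lower)) max(dm[same & lower]) else NA_real_,
    min_inter_p = if (any(!same & lower)) min(dm[!same & lower]) else NA_real_
  )
  list(sequences = seqs,
       truth = data.frame(process_id = ids, species = truth_sp,
                          cluster = truth_cl, stringsAsFactors = FALSE),
       species_names = species_names,
       cluster_of = stats::setNames(cluster_of, species_names),
       realized = realized)
}

# One-edit typo in the epithet: substitute an interior character.
.misspell <- function(name) {
  parts <- strsplit(name, " ")[[1]]
  ep <- strsplit(parts[2], "")[[1]]
  pos <- max(2L, length(ep) - 2L)
  ep[pos] <- setdiff(letters, ep[pos])[1]
  paste(parts[1], paste(ep, collapse = ""))
}

#' Plant curation artifacts into a clean simulated dataset
#'
#' Relabels records and degrades sequences per the configuration:
#' misspelled epithets (edit distance 1), junior-synonym names (with the
#' synonym-table entries that resolve them), emptied species names, sub-500
#' bp truncations and >1% N injections. Artifact species are chosen from
#' those not listed in `protect` (the pipeline protects sharing-group
#' species so each planted fact maps to exactly one downstream signal). The
#' returned ledger records every planted fact with its expected downstream
#' status.
#'
#' @param ds A clean `specimen_df` with true names.
#' @param cfg A [simulation_config()].
#' @param protect Species names exempt from relabelling artifacts.
#' @return list(dataset, synonyms, ledger).
#' @export
inject_artifacts <- function(ds, cfg, protect = character(0)) {
  species <- unique(ds$species)
  eligible <- setdiff(species, protect)
  need <- cfg$n_misspellings + cfg$n_synonym_pairs
  if (length(eligible) < need + 1L)
    stop("not enough species (", length(eligible),
         ") to plant ", need, " name artifacts")
  miss_sp <- eligible[seq_len(cfg$n_misspellings)]
  syn_sp <- eligible[cfg$n_misspellings + seq_len(cfg$n_synonym_pairs)]
  plain_sp <- setdiff(eligible, c(miss_sp, syn_sp))

  ledger <- list()
  # misspellings: every record of the species carries the typo
  planted_miss <- vapply(miss_sp, .misspell, "")
  for (i in seq_along(miss_sp))
    ds$species[ds$species == miss_sp[i]] <- planted_miss[i]
  ledger$misspellings <- data.frame(true_name = miss_sp,
                                    planted_name = unname(planted_miss),
                                    stringsAsFactors = FALSE)
  # synonyms: records carry an old combination; the synonym table anchors it
  planted_syn <- paste(.old_genus_pool[seq_along(syn_sp)],
                       vapply(strsplit(syn_sp, " "), `[`, "", 2))
  for (i in seq_along(syn_sp))
    ds$species[ds$species == syn_sp[i]] <- planted_syn[i]
  synonyms <- data.frame(variant_name = planted_syn, accepted_name = syn_sp,
                         kind = rep("synonym", length(syn_sp)),
                         stringsAsFactors = FALSE)
  ledger$synonyms <- data.frame(true_name = syn_sp,
                                planted_name = planted_syn,
                                stringsAsFactors = FALSE)
  # unidentified specimens: only among untouched species, never the last
  # named specimen of a species
  unid_pool <- which(ds$species %in% plain_sp)
  keep_named <- !duplicated(ds$species)   # first record of each species
  unid_pool <- setdiff(unid_pool, which(keep_named))
  n_unid <- min(round(cfg$fraction_unidentified * nrow(ds)),
                length(unid_pool))
  unid <- if (n_unid > 0) sort(sample(unid_pool, n_unid)) else integer(0)
  ds$species[unid] <- ""
  ds$identification_method[unid] <- "unknown"
  ds$identified_by[unid] <- ""
  ledger$unidentified_ids <- ds$process_id[unid]
  # non-compliant sequences: alternately truncated and N-salted, drawn from
  # named, untouched records
  qc_pool <- setdiff(which(ds$species %in% plain_sp), unid)
  n_bad <- min(cfg$n_noncompliant, length(qc_pool))
  bad <- if (n_bad > 0) sort(sample(qc_pool, n_bad)) else integer(0)
  short_ids <- character(0)
  ambig_ids <- character(0)
  for (k in seq_along(bad)) {
    i <- bad[k]
    s <- strsplit(ds$sequence[i], "")[[1]]
    if (k %% 2L == 1L) {
      keep_len <- min(450L, length(s))
      ds$sequence[i] <- paste(s[seq_len(keep_len)], collapse = "")
      short_ids <- c(short_ids, ds$process_id[i])
    } else {
      n_n <- ceiling(0.02 * length(s))
      s[sample(length(s), n_n)] <- "N"
      ds$sequence[i] <- paste(s, collapse = "")
      ambig_ids <- c(ambig_ids, ds$process_id[i])
    }
  }
  ledger$short_ids <- short_ids
  ledger$ambiguous_ids <- ambig_ids
  list(dataset = ds, synonyms = synonyms, ledger = ledger)
}

#' Simulate a full BOLD-style dataset with planted truth
#'
#' End-to-end generator: sequences with known cluster structure
#' ([simulate_sequences()]), a BOLD-style specimen table, a matching
#' taxonomic checklist (true names only, genera grouped into families and
#' families into the four hemipteran suborders), a synonym table for the
#' planted synonyms, and a truth ledger recording every planted artifact
#' with the stage expected to catch it.
#'
#' @param cfg A [simulation_config()].
#' @return list of class `"simulated_dataset"`: `dataset` (a
#'   `specimen_df`), `checklist`, `synonyms`, `truth`, `ledger`, `realized`,
#'   `sequences`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  sim <- simulate_sequences(cfg)
  n_sp <- cfg$n_species
  genus_idx <- rep(seq_len(ceiling(n_sp / 2)), each = 2)[seq_len(n_sp)]
  genera <- .genus_pool[genus_idx]
  fam_idx <- (genus_idx - 1L) %/% 3L + 1L
  families <- paste0(c("Miridae", "Aphididae", "Cicadellidae", "Corixidae",
                       "Delphacidae", "Tingidae", "Nabidae")[
                         (fam_idx - 1L) %% 7L + 1L])
  suborders <- c("Heteroptera", "Sternorrhyncha", "Clypeorrhyncha",
                 "Heteroptera", "Archaeorrhyncha", "Heteroptera",
                 "Heteroptera")[(fam_idx - 1L) %% 7L + 1L]
  checklist <- data.frame(
    suborder = suborders, family = families, genus = genera,
    species_epithet = vapply(strsplit(sim$species_names, " "), `[`, "", 2),
    canonical_name = sim$species_names,
    author = sprintf("(Author, %d)", 1850 + seq_len(n_sp)),
    stringsAsFactors = FALSE
  )
  sp_row <- match(sim$truth$species, checklist$canonical_name)
  identifiers <- c("M. D. Schwartz", "C. Bartlett", "J. N. Zahniser",
                   "E. Maw", "G. G. E. Scudder")
  n <- nrow(sim$truth)
  ds <- data.frame(
    process_id = sim$truth$process_id,
    sample_id = sprintf("BIOUG%05d", seq_len(n)),
    institution = sample(c("CNC", "BIO", "RBCM"), n, replace = TRUE),
    phylum = "Arthropoda", class = "Insecta", order = "Hemiptera",
    suborder = checklist$suborder[sp_row],
    family = checklist$family[sp_row],
    genus = checklist$genus[sp_row],
    species = sim$truth$species,
    identified_by = sample(identifiers, n, replace = TRUE),
    identification_method = "user",
    bin_label = "",
    country = "Canada",
    collection_year = sample(1990:2013, n, replace = TRUE),
    primer_pair = sample(c("LepF1_LepR1", "LCO1490_HCO2198", "MLepF1_LepR1"),
                         n, replace = TRUE),
    sequence = unname(sim$sequences),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("specimen_df", "data.frame")
  attr(ds, "provenance") <- sprintf("synthetic (seed %d)", cfg$seed)
  sharing_species <- sim$species_names[unlist(cfg$sharing_groups)]
  art <- inject_artifacts(ds, cfg, protect = sharing_species)
  ledger <- art$ledger
  ledger$sharing_groups <- lapply(cfg$sharing_groups,
                                  function(g) sim$species_names[g])
  ledger$n_clusters_true <- length(unique(sim$truth$cluster))
  ledger$realized <- sim$realized
  structure(list(dataset = art$dataset, checklist = checklist,
                 synonyms = art$synonyms, truth = sim$truth,
                 ledger = ledger, realized = sim$realized,
                 sequences = sim$sequences),
            class = "simulated_dataset")
}
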