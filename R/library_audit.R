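# Bin labels for a dataset: either a computed "bin_partition", a named
# character vector (process_id -> bin), or the name of a column in ds.
# Records without a label get "" (unplaced).
.bin_labels_for <- function(bins, ds) {
  if (inherits(bins, "bin_partition")) {
    lab <- bins$assignment[ds$process_id]
    lab[is.na(lab)] <- ""
  } else if (is.character(bins) && length(bins) == 1L && bins %in% names(ds)) {
    lab <- ds[[bins]]
  } else if (is.character(bins) && !is.null(names(bins))) {
    lab <- bins[ds$process_id]
    lab[is.na(lab)] <- ""
  } else stop("bins must be a bin_partition, a named vector, or a column name")
  stats::setNames(as.character(lab), ds$process_id)
}

# Species-level names used by the audit: accepted (post-reconciliation)
# names when annotate_dataset() has run, raw names otherwise — so synonym
# pairs collapse before concordance is judged.
.audit_names <- function(ds) {
  if (!is.null(ds$accepted_name)) {
    nm <- ds$accepted_name
    nm[is.na(nm)] <- ""
    nm
  } else normalize_name(ds$species)
}

#' Per-BIN concordance classification
#'
#' A BIN whose named members carry exactly one species name is `CONCORDANT`;
#' two or more names make it `DISCORDANT`; no species-level names at all
#' make it `UNNAMED`. Unnamed members never create discordance. Species are
#' counted by accepted (post-reconciliation) name when the dataset has been
#' annotated, so synonyms collapse first.
#'
#' @param bins A `"bin_partition"`, a named process_id -> bin vector, or the
#'   name of a column of `ds` (e.g. `"bin_label"`).
#' @param ds A `specimen_df`.
#' @return data.frame(bin_id, n_specimens, n_species, species_names
#'   (list column), status, singleton), one row per bin, ordered by first
#'   appearance in the dataset.
#' @export
bin_concordance <- function(bins, ds) {
  lab <- .bin_labels_for(bins, ds)
  nm <- .audit_names(ds)
  keep <- nzchar(lab)
  bin_ids <- unique(lab[keep])
  rows <- lapply(bin_ids, function(b) {
    members <- which(lab == b)
    named <- sort(unique(nm[members][nzchar(nm[members])]))
    k <- length(named)
    data.frame(bin_id = b, n_specimens = length(members), n_species = k,
               status = if (k == 0L) "UNNAMED"
                        else if (k == 1L) "CONCORDANT" else "DISCORDANT",
               singleton = length(members) == 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(bin_id = character(0), n_specimens = integer(0),
                      n_species = integer(0), status = character(0),
                      singleton = logical(0))
  out$species_names <- lapply(bin_ids, function(b) {
    members <- which(lab == b)
    sort(unique(nm[members][nzchar(nm[members])]))
  })
  out
}

#' Per-species identifiability status
#'
#' Three-way partition of the named species in a dataset: `IDENTIFIABLE`
#' (all of the species' bins are concordant — a query hitting one of them
#' returns a single name), `SHARING` (at least one of its bins is
#' discordant: the species shares barcodes), `UNPLACED` (no specimen of the
#' species carries a bin). `sharing_partners` lists the species co-occurring
#' in its discordant bins.
#'
#' @param concordance Output of [bin_concordance()].
#' @param ds The same `specimen_df`.
#' @param bins The same bin source passed to [bin_concordance()].
#' @return data.frame(species, n_specimens, n_bins, status,
#'   sharing_partners (list column)).
#' @export
species_status <- function(concordance, ds, bins = "bin_label") {
  lab <- .bin_labels_for(bins, ds)
  nm <- .audit_names(ds)
  species <- sort(unique(nm[nzchar(nm)]))
  status_of <- stats::setNames(concordance$status, concordance$bin_id)
  names_of <- stats::setNames(concordance$species_names, concordance$bin_id)
  rows <- lapply(species, function(sp) {
    members <- which(nm == sp)
    sp_bins <- unique(lab[members][nzchar(lab[members])])
    if (length(sp_bins) == 0L) {
      st <- "UNPLACED"
      partners <- character(0)
    } else if (any(status_of[sp_bins] == "DISCORDANT")) {
      st <- "SHARING"
      partners <- setdiff(sort(unique(unlist(
        names_of[sp_bins[status_of[sp_bins] == "DISCORDANT"]]))), sp)
    } else {
      st <- "IDENTIFIABLE"
      partners <- character(0)
    }
    data.frame(species = sp, n_specimens = length(members),
               n_bins = length(sp_bins), status = st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(species = character(0), n_specimens = integer(0),
                      n_bins = integer(0), status = character(0))
  out$sharing_partners <- lapply(seq_len(nrow(out)), function(i) {
    sp <- out$species[i]
    if (out$status[i] != "SHARING") return(character(0))
    members <- which(nm == sp)
    sp_bins <- unique(lab[members][nzchar(lab[members])])
    setdiff(sort(unique(unlist(
      names_of[sp_bins[status_of[sp_bins] == "DISCORDANT"]]))), sp)
  })
  out
}

#' Bins with no named members (possible new species records)
#'
#' `UNNAMED` bins hold specimens not identified to species anywhere in the
#' bin; restricted to a country of interest they are candidates for new
#' national species records.
#'
#' @inheritParams species_status
#' @param country_filter If non-empty, keep only bins with at least one
#'   record from this country.
#' @return Character vector of bin ids.
#' @export
unnamed_bins <- function(concordance, ds, bins = "bin_label",
                         country_filter = "") {
  lab <- .bin_labels_for(bins, ds)
  out <- concordance$bin_id[concordance$status == "UNNAMED"]
  if (nzchar(country_filter)) {
    keep <- vapply(out, function(b)
      any(ds$country[lab == b] == country_filter), NA)
    out <- out[keep]
  }
  out
}

#' Assemble the reference library
#'
#' A record enters the library iff it passes QC, its name resolves to the
#' checklist (`MATCHED`, `SYNONYM` or `SPELLING_VARIANT`), and it has a bin
#' assignment. Every excluded record carries the full list of reasons (QC
#' codes plus `NAME_UNRESOLVED`, `NO_BIN`). Rebuilding from the library's
#' own records changes nothing (idempotence).
#'
#' @param ds A `specimen_df`.
#' @param checklist data.frame from [read_checklist()].
#' @param synonyms Optional data.frame from [read_synonyms()].
#' @param qc A [qc_config()].
#' @param bins Bin source (see [bin_concordance()]).
#' @return list of class `"library_build"`: `records` (the library subset,
#'   annotated), `excluded` (data.frame process_id + reasons list column),
#'   `annotated` (the full annotated dataset), `checklist_coverage`
#'   (per-family species counts, see [family_coverage()]).
#' @export
build_library <- function(ds, checklist, synonyms = NULL, qc = qc_config(),
                          bins = "bin_label") {
  ann <- annotate_dataset(ds, checklist, synonyms)
  ds <- ann$dataset
  qc_res <- compliance_check(ds, qc)
  lab <- .bin_labels_for(bins, ds)
  ok_name <- ds$resolution_status %in%
    c("MATCHED", "SYNONYM", "SPELLING_VARIANT")
  reasons <- lapply(seq_len(nrow(ds)), function(i) {
    r <- qc_res$reasons[[i]]
    if (!ok_name[i]) r <- c(r, "NAME_UNRESOLVED")
    if (!nzchar(lab[i])) r <- c(r, "NO_BIN")
    r
  })
  include <- lengths(reasons) == 0L
  lib <- ds[include, , drop = FALSE]
  rownames(lib) <- NULL
  excluded <- data.frame(process_id = ds$process_id[!include],
                         stringsAsFactors = FALSE)
  excluded$reasons <- reasons[!include]
  build <- list(records = lib, excluded = excluded, annotated = ds,
                qc = qc, bins = bins)
  class(build) <- "library_build"
  build$checklist_coverage <- family_coverage(build, checklist)
  build
}

#' @export
print.library_build <- function(x, ...) {
  cat("library_build: ", nrow(x$records), " library records, ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Per-family barcode coverage of the checklist
#'
#' For each checklist family: how many checklist species there are, how many
#' have at least one library barcode, and the proportion covered. Families
#' are grouped by suborder, then sorted by decreasing proportion.
#'
#' @param build A `"library_build"`.
#' @param checklist data.frame from [read_checklist()].
#' @return data.frame(suborder, family, checklist_species, barcoded_species,
#'   proportion).
#' @export
family_coverage <- function(build, checklist) {
  lib_species <- unique(.audit_names(build$records))
  fams <- unique(checklist[, c("suborder", "family")])
  rows <- lapply(seq_len(nrow(fams)), function(i) {
    sp <- checklist$canonical_name[checklist$family == fams$family[i] &
                                     checklist$suborder == fams$suborder[i]]
    got <- sum(sp %in% lib_species)
    data.frame(suborder = fams$suborder[i], family = fams$family[i],
               checklist_species = length(sp), barcoded_species = got,
               proportion = got / length(sp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$suborder, -out$proportion, out$family), , drop = FALSE]
}

# Suborder of each record, following the checklist of its accepted species;
# records whose own family disagrees with the checklist's, or whose higher
# taxonomy cannot be anchored, go to "Not.assigned".
.record_suborder <- function(ds, checklist) {
  nm <- .audit_names(ds)
  idx <- match(nm, checklist$canonical_name)
  sub <- checklist$suborder[idx]
  fam_ok <- is.na(idx) | ds$family == "" |
    ds$family == checklist$family[idx]
  sub[!fam_ok] <- "Not.assigned"
  # unnamed records: trust their own suborder field when it is one the
  # checklist knows, otherwise Not.assigned
  known <- unique(checklist$suborder)
  own <- ifelse(ds$suborder %in% known, ds$suborder, "Not.assigned")
  ifelse(is.na(sub), own, sub)
}

#' Suborder-level roll-up of the data release and library
#'
#' One row per suborder plus a totals row: distinct families, genera and
#' species in the library and in the full data release, library and total
#' BIN counts, unnamed BINs, species flagged over the divergence threshold,
#' specimen counts, and species sharing barcodes. Species are counted by
#' accepted name. Records whose higher taxonomy conflicts with the checklist
#' are bucketed under `Not.assigned`.
#'
#' @param build A `"library_build"`.
#' @param ds The full data-release `specimen_df` (annotated or not).
#' @param checklist data.frame from [read_checklist()].
#' @param bins Bin source over the full release (see [bin_concordance()]).
#' @param divergent_species Character vector from [flag_high_divergence()].
#' @return data.frame with one row per suborder and a `Totals` row whose
#'   countable columns equal the column sums.
#' @export
suborder_summary <- function(build, ds, checklist, bins = "bin_label",
                             divergent_species = character(0)) {
  if (is.null(ds$accepted_name))
    ds <- build$annotated[match(ds$process_id, build$annotated$process_id), ,
                          drop = FALSE]
  lib <- build$records
  rel_sub <- .record_suborder(ds, checklist)
  lib_sub <- .record_suborder(lib, checklist)
  lab <- .bin_labels_for(bins, ds)
  lib_lab <- .bin_labels_for(bins, lib)
  conc <- bin_concordance(bins, ds)
  # a bin belongs to the suborder of its first member
  bin_sub <- tapply(rel_sub[nzchar(lab)], lab[nzchar(lab)],
                    function(x) x[1])
  lib_status <- species_status(bin_concordance(bins, lib), lib, bins)
  sp_sub <- function(records, subv) {
    nm <- .audit_names(records)
    keep <- nzchar(nm)
    tapply(subv[keep], nm[keep], function(x) x[1])
  }
  lib_sp_sub <- sp_sub(lib, lib_sub)
  subs <- sort(unique(c(rel_sub, lib_sub)))
  subs <- c(setdiff(subs, "Not.assigned"),
            intersect("Not.assigned", subs))
  count_distinct <- function(v, keep) length(unique(v[keep & nzchar(v)]))
  rows <- lapply(subs, function(s) {
    in_rel <- rel_sub == s
    in_lib <- lib_sub == s
    rel_nm <- .audit_names(ds)
    lib_nm <- .audit_names(lib)
    s_bins <- names(bin_sub)[bin_sub == s]
    unnamed <- sum(conc$status[match(s_bins, conc$bin_id)] == "UNNAMED")
    sharing_sp <- lib_status$species[lib_status$status == "SHARING"]
    data.frame(
      suborder = s,
      lib_families = count_distinct(lib$family, in_lib),
      release_families = count_distinct(ds$family, in_rel),
      lib_genera = count_distinct(lib$genus, in_lib),
      release_genera = count_distinct(ds$genus, in_rel),
      lib_species = count_distinct(lib_nm, in_lib),
      release_species = count_distinct(rel_nm, in_rel),
      lib_bins = length(unique(lib_lab[in_lib & nzchar(lib_lab)])),
      total_bins = length(s_bins),
      unnamed_bins = unnamed,
      high_divergence_species =
        sum(names(lib_sp_sub)[lib_sp_sub == s] %in% divergent_species),
      lib_specimens = sum(in_lib),
      release_specimens = sum(in_rel),
      sharing_species =
        sum(names(lib_sp_sub)[lib_sp_sub == s] %in% sharing_sp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  totals <- out[1, , drop = FALSE]
  totals$suborder <- "Totals"
  for (col in names(out)[-1]) totals[[col]] <- sum(out[[col]])
  rbind(out, totals)
}

#' Concordance histogram data (species x specimens per BIN, by family)
#'
#' Tabular form of the 3-D concordance view: for each named bin in scope,
#' its (modal) family, its number of species and its number of specimens;
#' plus marginal counts of bins holding 1, 2, and 3-or-more species.
#' Optionally restricted to given families and/or to specimens identified by
#' named specialists (`identification_method == "user"` and, when a
#' whitelist is given, `identified_by` in it).
#'
#' @inheritParams species_status
#' @param family_filter Character vector of families (empty = all).
#' @param identifier_whitelist Optional character vector of identifier names;
#'   implies restriction to user-identified records.
#' @return list(triples = data.frame(family, bin_id, n_species_in_bin,
#'   n_specimens_in_bin), counts = c(one, two, three_plus)).
#' @export
concordance_histogram <- function(concordance, ds, bins = "bin_label",
                                  family_filter = character(0),
                                  identifier_whitelist = NULL) {
  keep <- rep(TRUE, nrow(ds))
  if (!is.null(identifier_whitelist))
    keep <- ds$identification_method == "user" &
      ds$identified_by %in% identifier_whitelist
  sub <- ds[keep, , drop = FALSE]
  conc <- bin_concordance(bins, sub)
  lab <- .bin_labels_for(bins, sub)
  fam_of <- tapply(sub$family[nzchar(lab)], lab[nzchar(lab)], function(x) {
    x <- x[nzchar(x)]
    if (!length(x)) "" else names(sort(table(x), decreasing = TRUE))[1]
  })
  named <- conc[conc$status != "UNNAMED", , drop = FALSE]
  named$family <- as.character(fam_of[named$bin_id])
  if (length(family_filter))
    named <- named[named$family %in% family_filter, , drop = FALSE]
  triples <- data.frame(family = named$family, bin_id = named$bin_id,
                        n_species_in_bin = named$n_species,
                        n_specimens_in_bin = named$n_specimens,
                        stringsAsFactors = FALSE)
  counts <- c(one = sum(named$n_species == 1L),
              two = sum(named$n_species == 2L),
              three_plus = sum(named$n_species >= 3L))
  list(triples = triples, counts = counts)
}

#' Amplification success by family and primer pair
#'
#' For every family x primer-pair combination attempted: the number of
#' records, the number with a recovered (non-empty) sequence, and the
#' success proportion. Records without primer metadata are excluded and
#' their count reported in the `n_no_primer` attribute.
#'
#' @param ds A `specimen_df`.
#' @return data.frame(family, primer_pair, attempts, successes, proportion)
#'   with attribute `n_no_primer`.
#' @export
primer_success_matrix <- function(ds) {
  has <- nzchar(ds$primer_pair)
  sub <- ds[has, , drop = FALSE]
  if (nrow(sub)) {
    key <- paste(sub$family, sub$primer_pair, sep = "\r")
    att <- table(key)
    succ <- tapply(nzchar(sub$sequence), key, sum)
    parts <- strsplit(names(att), "\r", fixed = TRUE)
    out <- data.frame(
      family = vapply(parts, `[`, "", 1),
      primer_pair = vapply(parts, `[`, "", 2),
      attempts = as.integer(att),
      successes = as.integer(succ[names(att)]),
      stringsAsFactors = FALSE
    )
    out$proportion <- out$successes / out$attempts
    out <- out[order(out$family, out$primer_pair), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(family = character(0), primer_pair = character(0),
                      attempts = integer(0), successes = integer(0),
                      proportion = numeric(0))
  }
  attr(out, "n_no_primer") <- sum(!has)
  out
}
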