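# Canonical specimen fields, in output order. Missing metadata is the empty
# string (collection_year: NA); sequences are uppercased with terminal gaps
# stripped on read.
.canonical_fields <- c(
  "process_id", "sample_id", "institution",
  "phylum", "class", "order", "suborder", "family", "genus", "species",
  "identified_by", "identification_method", "bin_label",
  "country", "collection_year", "primer_pair", "sequence"
)

#' Default column aliases for BOLD-style specimen tables
#'
#' BOLD export headers have drifted over the years ("processid" vs
#' "Process ID", "nucleotides" vs "nuc", ...). Each canonical field maps to
#' the header spellings accepted for it; matching is case-insensitive and
#' ignores punctuation/whitespace. Extend or replace the list to adapt the
#' reader to another dialect.
#'
#' @return Named list: canonical field name -> character vector of accepted
#'   header spellings.
#' @export
default_field_aliases <- function() {
  list(
    process_id = c("process_id", "processid", "process id"),
    sample_id = c("sample_id", "sampleid", "sample id"),
    institution = c("institution", "institution_storing", "inst"),
    phylum = c("phylum", "phylum_name"),
    class = c("class", "class_name"),
    order = c("order", "order_name"),
    suborder = c("suborder", "suborder_name"),
    family = c("family", "family_name"),
    genus = c("genus", "genus_name"),
    species = c("species", "species_name"),
    identified_by = c("identified_by", "identifier", "identifier_name"),
    identification_method = c("identification_method", "id_method"),
    bin_label = c("bin_label", "bin_uri", "bin.uri", "bin"),
    country = c("country", "country_name"),
    collection_year = c("collection_year", "collectionyear", "year"),
    primer_pair = c("primer_pair", "primers", "seq_primers"),
    sequence = c("sequence", "nucleotides", "nuc")
  )
}

.squash_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.normalize_sequence <- function(s) {
  s <- toupper(trimws(s))
  s <- sub("^-+", "", s)
  sub("-+$", "", s)
}

.normalize_id_method <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("user", length(x))
  out[x == "" | is.na(x)] <- "unknown"
  out[grepl("instit", x)] <- "institutional"
  out[grepl("engine|bin", x)] <- "id_engine"
  out[x %in% c("user", "institutional", "id_engine", "unknown")] <-
    x[x %in% c("user", "institutional", "id_engine", "unknown")]
  out
}

#' Read a BOLD-style specimen table
#'
#' Parses a delimited specimen table (one row per specimen) into a typed
#' dataset: canonical columns first (see [default_field_aliases()]), any
#' unmapped input columns preserved verbatim after them. Sequences are
#' uppercased and terminal gaps stripped; missing metadata becomes `""`.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param aliases Alias table, as from [default_field_aliases()].
#' @param provenance Free-text source label (e.g. a dataset DOI); stored as
#'   the `"provenance"` attribute.
#' @return A `data.frame` with class `"specimen_df"`; one row per input row,
#'   input order preserved.
#' @export
read_specimen_table <- function(path, dialect = c("tsv", "csv"),
                                aliases = default_field_aliases(),
                                provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("specimen table not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = character(0), fileEncoding = "UTF-8")
  as_specimen_df(raw, aliases = aliases, provenance = provenance)
}

#' Coerce a raw data.frame into a typed specimen dataset
#'
#' @param raw A data.frame of character columns with BOLD-style headers.
#' @inheritParams read_specimen_table
#' @return A `specimen_df` (see [read_specimen_table()]).
#' @export
as_specimen_df <- function(raw, aliases = default_field_aliases(),
                           provenance = "") {
  squashed <- .squash_header(names(raw))
  ds <- data.frame(matrix("", nrow(raw), length(.canonical_fields)),
                   stringsAsFactors = FALSE)
  names(ds) <- .canonical_fields
  mapped <- character(0)
  for (field in .canonical_fields) {
    hit <- which(squashed %in% .squash_header(aliases[[field]]))
    if (length(hit)) {
      ds[[field]] <- trimws(as.character(raw[[hit[1]]]))
      ds[[field]][is.na(ds[[field]])] <- ""
      mapped <- c(mapped, names(raw)[hit[1]])
    }
  }
  if (!any(.squash_header(names(raw)) %in% .squash_header(aliases$process_id)))
    stop("no process-ID column found (accepted: ",
         paste(aliases$process_id, collapse = ", "), ")")
  dup <- unique(ds$process_id[duplicated(ds$process_id)])
  if (length(dup))
    stop("duplicate process_id(s): ", paste(dup, collapse = ", "))
  if (any(ds$process_id == ""))
    stop("empty process_id in row(s): ",
         paste(which(ds$process_id == ""), collapse = ", "))
  ds$sequence <- .normalize_sequence(ds$sequence)
  bad <- grepl("[^ACGTURYSWKMBDHVN-]", ds$sequence)
  if (any(bad))
    stop("non-IUPAC characters in sequence for: ",
         paste(ds$process_id[bad], collapse = ", "))
  ds$identification_method <- .normalize_id_method(ds$identification_method)
  ds$collection_year <- suppressWarnings(as.integer(ds$collection_year))
  extra <- setdiff(names(raw), mapped)
  for (nm in extra) ds[[nm]] <- raw[[nm]]
  attr(ds, "provenance") <- provenance
  class(ds) <- c("specimen_df", "data.frame")
  ds
}

#' Write a specimen dataset back to delimited text
#'
#' Inverse of [read_specimen_table()]: writes canonical columns (and any
#' preserved extras) as UTF-8 delimited text, tab-separated by default.
#'
#' @param ds A `specimen_df`.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_specimen_table <- function(ds, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(ds)
  out$collection_year[is.na(out$collection_year)] <- ""
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxonomic checklist
#'
#' The checklist is the fixed nomenclatural baseline: one row per accepted
#' species with its higher ranks. Requires columns (by alias) for suborder,
#' family, genus and the species epithet; an `author` column is optional.
#' `canonical_name` is built as "Genus epithet". Rows lacking genus or
#' epithet are dropped with a warning naming their line numbers; duplicated
#' canonical names are deduplicated (first kept) with a warning.
#'
#' @param path Path to a delimited checklist file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return data.frame with columns suborder, family, genus, species_epithet,
#'   canonical_name, author; file order preserved.
#' @export
read_checklist <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("checklist not found: ", path)
  raw <- utils::read.table(path, sep = if (dialect == "csv") "," else "\t",
                           header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character(0), quote = "\"",
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    warning("empty checklist: ", path)
    return(data.frame(suborder = character(0), family = character(0),
                      genus = character(0), species_epithet = character(0),
                      canonical_name = character(0), author = character(0),
                      stringsAsFactors = FALSE))
  }
  squashed <- .squash_header(names(raw))
  pick <- function(cands) {
    hit <- which(squashed %in% cands)
    if (length(hit)) trimws(raw[[hit[1]]]) else rep("", nrow(raw))
  }
  chk <- data.frame(
    suborder = pick(c("suborder", "subordername")),
    family = pick(c("family", "familyname")),
    genus = pick(c("genus", "genusname")),
    species_epithet = pick(c("speciesepithet", "species", "epithet")),
    author = pick(c("author", "authority")),
    stringsAsFactors = FALSE
  )
  if (all(chk$genus == "") || all(chk$species_epithet == ""))
    stop("checklist must have suborder, family, genus and species columns")
  bad <- chk$genus == "" | chk$species_epithet == ""
  if (any(bad)) {
    warning("dropping ", sum(bad), " checklist row(s) lacking genus or ",
            "epithet at line(s): ", paste(which(bad) + 1L, collapse = ", "))
    chk <- chk[!bad, , drop = FALSE]
  }
  chk$canonical_name <- paste(chk$genus, chk$species_epithet)
  dup <- duplicated(chk$canonical_name)
  if (any(dup)) {
    warning("deduplicated ", sum(dup), " repeated checklist name(s): ",
            paste(unique(chk$canonical_name[dup]), collapse = ", "))
    chk <- chk[!dup, , drop = FALSE]
  }
  rownames(chk) <- NULL
  chk[, c("suborder", "family", "genus", "species_epithet",
          "canonical_name", "author")]
}

#' Read a synonym table
#'
#' Maps variant names to accepted checklist names. `kind` is one of
#' `synonym` (a published junior synonym), `spelling` (a known orthographic
#' variant) or `post_checklist` (a species described or reported after the
#' checklist's cutoff; needs no checklist anchor).
#'
#' @param path Path to a delimited file with columns variant_name,
#'   accepted_name, kind.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return data.frame(variant_name, accepted_name, kind).
#' @export
read_synonyms <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, sep = if (dialect == "csv") "," else "\t",
                           header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character(0), quote = "\"",
                           fileEncoding = "UTF-8")
  squashed <- .squash_header(names(raw))
  need <- c("variantname", "acceptedname", "kind")
  if (!all(need %in% squashed))
    stop("synonym table needs columns variant_name, accepted_name, kind")
  syn <- data.frame(
    variant_name = trimws(raw[[which(squashed == "variantname")[1]]]),
    accepted_name = trimws(raw[[which(squashed == "acceptedname")[1]]]),
    kind = trimws(raw[[which(squashed == "kind")[1]]]),
    stringsAsFactors = FALSE
  )
  ok <- c("synonym", "spelling", "post_checklist")
  if (any(!syn$kind %in% ok))
    stop("unknown synonym kind(s): ",
         paste(unique(setdiff(syn$kind, ok)), collapse = ", "))
  syn
}

#' Read and write FASTA keyed by process ID
#'
#' Headers are bare process IDs. Sequences are uppercased on read.
#' `write_fasta` then `read_fasta` is the identity on valid input.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector (process_id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  ids <- names(seqs)
  bad <- which(is.na(ids) | ids == "" | grepl("\\s", ids))
  if (length(bad))
    stop("malformed FASTA header at record(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line width for wrapping sequence text.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
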