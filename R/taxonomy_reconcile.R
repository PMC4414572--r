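# Epithet placeholders that mean "not identified to species".
.placeholder_epithets <- c("sp", "spp", "cf", "nr", "aff", "sp.nov")

#' Normalize a scientific name to a canonical binomial
#'
#' Trims and collapses whitespace, removes parentheticals (subgenus
#' insertions and parenthesized authorships alike), strips trailing
#' author/year strings (tokens starting with a capital or containing
#' digits/punctuation after the epithet), capitalizes the genus and
#' lowercases the epithet. Trinomials are truncated to the binomial.
#' Genus-only names and placeholder epithets ("sp.", "cf." ...) normalize to
#' the empty string (not identified to species).
#'
#' @param raw Character vector of names.
#' @return Character vector of "Genus epithet" binomials (or `""`).
#' @export
normalize_name <- function(raw) {
  vapply(raw, function(x) {
    if (is.na(x)) return("")
    x <- gsub("\\([^)]*\\)", " ", x)
    x <- gsub("\\s+", " ", trimws(x))
    if (x == "") return("")
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    genus <- toks[1]
    if (grepl("[^A-Za-z-]", genus)) return("")
    genus <- paste0(toupper(substring(genus, 1, 1)),
                    tolower(substring(genus, 2)))
    # first subsequent token that looks like an epithet (letters only, not
    # an authority, which starts uppercase or carries digits/commas); a
    # miscased capitalized token directly after the genus is taken as the
    # epithet, since authorities follow an epithet
    epithet <- ""
    first <- TRUE
    for (tok in toks[-1]) {
      if (grepl("^[a-z-]+\\.?$", tok)) {
        epithet <- sub("\\.$", "", tok)
        break
      }
      if (first && grepl("^[A-Z][a-z-]+$", tok)) {
        epithet <- tolower(tok)
        break
      }
      first <- FALSE
      if (grepl("^[A-Z]", tok) || grepl("[0-9,]", tok)) break
    }
    if (epithet == "" || epithet %in% .placeholder_epithets) return("")
    paste(genus, epithet)
  }, "", USE.NAMES = FALSE)
}

# Latin gender-suffix swap on an otherwise exact stem: -us/-a/-um, -is/-e.
.gender_swap <- function(a, b) {
  strip <- function(x, sufs) {
    for (s in sufs) if (endsWith(x, s))
      return(substring(x, 1, nchar(x) - nchar(s)))
    NULL
  }
  g1 <- c("us", "a", "um")
  g2 <- c("is", "e")
  for (sufs in list(g1, g2)) {
    sa <- strip(a, sufs)
    sb <- strip(b, sufs)
    if (!is.null(sa) && !is.null(sb) && nzchar(sa) && sa == sb) return(TRUE)
  }
  FALSE
}

#' Resolve one specimen name against the checklist
#'
#' Resolution order: empty name -> `UNIDENTIFIED`; exact checklist match ->
#' `MATCHED`; synonym-table hit -> `SYNONYM` / `SPELLING_VARIANT` /
#' `POST_CHECKLIST` per its kind; same-genus spelling match (Levenshtein
#' distance <= 2 on the epithet, or a Latin gender-suffix swap on an exact
#' stem) -> `SPELLING_VARIANT`; otherwise `TENTATIVE_NEW`. Name changes in
#' generic combination (same epithet under a different genus) are never
#' auto-resolved; they stay `TENTATIVE_NEW` with a same-epithet hint in the
#' evidence for human review.
#'
#' @param name Raw species name.
#' @param checklist data.frame from [read_checklist()].
#' @param synonyms Optional data.frame from [read_synonyms()].
#' @param max_edit_distance Spelling tolerance on the epithet (default 2).
#' @return list(input_name, status, accepted_name, evidence).
#' @export
resolve_name <- function(name, checklist, synonyms = NULL,
                         max_edit_distance = 2L) {
  res <- function(status, accepted = "", evidence = "")
    list(input_name = name, status = status, accepted_name = accepted,
         evidence = evidence)
  norm <- normalize_name(name)
  if (norm == "") return(res("UNIDENTIFIED"))
  if (norm %in% checklist$canonical_name)
    return(res("MATCHED", norm, "exact checklist match"))
  if (!is.null(synonyms) && nrow(synonyms)) {
    hit <- which(normalize_name(synonyms$variant_name) == norm)
    if (length(hit)) {
      hit <- hit[1]
      kind <- synonyms$kind[hit]
      accepted <- normalize_name(synonyms$accepted_name[hit])
      status <- c(synonym = "SYNONYM", spelling = "SPELLING_VARIANT",
                  post_checklist = "POST_CHECKLIST")[[kind]]
      if (kind != "post_checklist" &&
          !accepted %in% checklist$canonical_name)
        stop("synonym table maps '", name, "' to '", accepted,
             "' which is not in the checklist")
      return(res(status, accepted, paste0("synonym table (kind=", kind, ")")))
    }
  }
  parts <- strsplit(norm, " ", fixed = TRUE)[[1]]
  genus <- parts[1]
  epithet <- parts[2]
  congeners <- checklist[checklist$genus == genus, , drop = FALSE]
  if (nrow(congeners)) {
    dists <- as.integer(utils::adist(epithet, congeners$species_epithet))
    swap <- vapply(congeners$species_epithet, .gender_swap, NA, a = epithet)
    ok <- dists <= max_edit_distance & dists > 0L
    ok <- ok | swap
    if (any(ok)) {
      best <- which(ok)[order(dists[ok])][1]
      return(res("SPELLING_VARIANT", congeners$canonical_name[best],
                 paste0("edit distance ", dists[best], " to '",
                        congeners$canonical_name[best], "'")))
    }
  }
  same_ep <- checklist$canonical_name[checklist$species_epithet == epithet]
  ev <- if (length(same_ep))
    paste0("same epithet as ", paste(same_ep, collapse = ", "),
           " (possible change of combination; manual review)")
  else "no checklist or synonym match"
  res("TENTATIVE_NEW", "", ev)
}

#' Annotate a dataset with name resolutions
#'
#' Resolves every distinct species name once (resolution is a pure function
#' of name, checklist and synonym table) and adds `resolution_status` and
#' `accepted_name` columns to the dataset. Status counts are at the species
#' level — distinct normalized input names, the empty name counting once as
#' `UNIDENTIFIED` when present — so the counts sum to the number of distinct
#' names.
#'
#' @param ds A `specimen_df`.
#' @inheritParams resolve_name
#' @return list(dataset = annotated `specimen_df`,
#'   counts = named integer vector over all six statuses,
#'   resolutions = one data.frame row per distinct input name).
#' @export
annotate_dataset <- function(ds, checklist, synonyms = NULL,
                             max_edit_distance = 2L) {
  norm <- normalize_name(ds$species)
  uniq <- unique(norm)
  resolved <- lapply(uniq, resolve_name, checklist = checklist,
                     synonyms = synonyms,
                     max_edit_distance = max_edit_distance)
  tab <- data.frame(
    input_name = uniq,
    status = vapply(resolved, `[[`, "", "status"),
    accepted_name = vapply(resolved, `[[`, "", "accepted_name"),
    evidence = vapply(resolved, `[[`, "", "evidence"),
    stringsAsFactors = FALSE
  )
  idx <- match(norm, tab$input_name)
  ds$resolution_status <- tab$status[idx]
  ds$accepted_name <- tab$accepted_name[idx]
  statuses <- c("MATCHED", "SYNONYM", "SPELLING_VARIANT", "POST_CHECKLIST",
                "TENTATIVE_NEW", "UNIDENTIFIED")
  counts <- stats::setNames(integer(length(statuses)), statuses)
  got <- table(tab$status)
  counts[names(got)] <- as.integer(got)
  list(dataset = ds, counts = counts, resolutions = tab)
}
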