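# Brute-force oracles and small fixture builders, independent of the
# package's implementation paths.

# character-by-character p-distance with pairwise deletion
bf_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

# connected components of the thresholded graph by breadth-first search
bf_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(d[v, ] <= threshold & comp == 0L)
      nb <- setdiff(nb, v)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# pair-by-pair Rand index
bf_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  tot <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1L
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1L
  }
  agree / tot
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate k positions of a sequence (guaranteed different base)
mutate_seq <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  paste(x, collapse = "")
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

small_checklist <- function() {
  data.frame(
    suborder = c("Heteroptera", "Heteroptera", "Clypeorrhyncha"),
    family = c("Miridae", "Miridae", "Cicadellidae"),
    genus = c("Lygus", "Tropidosteptes", "Macrosteles"),
    species_epithet = c("lineolaris", "cardinalis", "quadrilineatus"),
    canonical_name = c("Lygus lineolaris", "Tropidosteptes cardinalis",
                       "Macrosteles quadrilineatus"),
    author = c("(Palisot, 1818)", "(Uhler, 1878)", "(Forbes, 1885)"),
    stringsAsFactors = FALSE
  )
}

# minimal specimen_df builder
make_ds <- function(process_id, species, sequence = NULL,
                    bin_label = "", country = "Canada", family = "",
                    primer_pair = "", identified_by = "",
                    identification_method = "user") {
  n <- length(process_id)
  if (is.null(sequence)) sequence <- rep("", n)
  ds <- data.frame(
    process_id = process_id, sample_id = process_id, institution = "",
    phylum = "Arthropoda", class = "Insecta", order = "Hemiptera",
    suborder = "", family = family, genus = "", species = species,
    identified_by = identified_by,
    identification_method = identification_method,
    bin_label = bin_label, country = country,
    collection_year = NA_integer_, primer_pair = primer_pair,
    sequence = sequence, stringsAsFactors = FALSE
  )
  class(ds) <- c("specimen_df", "data.frame")
  ds
}
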