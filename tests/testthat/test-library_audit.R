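# shared fixture: two named concordant bins, one discordant, one unnamed,
# one species never sequenced (unplaced)
audit_fixture <- function() {
  ds <- make_ds(
    paste0("P", 1:10),
    c("Aus bus", "Aus bus", "Aus bus",          # B1 concordant
      "Cus dus", "",                            # B2 concordant (named rule)
      "Eus fus", "Gus hus",                     # B3 discordant
      "", "",                                   # B4 unnamed
      "Ius jus"),                               # no bin -> unplaced
    bin_label = c("B1", "B1", "B1", "B2", "B2", "B3", "B3", "B4", "B4", ""),
    country = c(rep("Canada", 8), "United States", "Canada"),
    family = c(rep("Famae", 5), rep("Fambe", 4), "Famce")
  )
  ds
}

test_that("bin concordance classifies by named members only", {
  ds <- audit_fixture()
  conc <- bin_concordance("bin_label", ds)
  st <- setNames(conc$status, conc$bin_id)
  expect_equal(unname(st[c("B1", "B2", "B3", "B4")]),
               c("CONCORDANT", "CONCORDANT", "DISCORDANT", "UNNAMED"))
  expect_equal(conc$n_species[conc$bin_id == "B3"], 2L)
  expect_false(conc$singleton[conc$bin_id == "B1"])
  # status partition covers all bins
  expect_equal(sum(conc$status %in%
                     c("CONCORDANT", "DISCORDANT", "UNNAMED")), nrow(conc))
})

test_that("species status partitions library species three ways", {
  ds <- audit_fixture()
  conc <- bin_concordance("bin_label", ds)
  st <- species_status(conc, ds, "bin_label")
  got <- setNames(st$status, st$species)
  expect_equal(unname(got[c("Aus bus", "Cus dus", "Eus fus", "Gus hus",
                            "Ius jus")]),
               c("IDENTIFIABLE", "IDENTIFIABLE", "SHARING", "SHARING",
                 "UNPLACED"))
  expect_equal(st$sharing_partners[[which(st$species == "Eus fus")]],
               "Gus hus")
  # identity: IDENTIFIABLE + SHARING + UNPLACED = total species
  expect_equal(sum(table(st$status)), nrow(st))
  # species spanning two concordant bins stays identifiable
  ds2 <- make_ds(paste0("Q", 1:4), rep("Aus bus", 4),
                 bin_label = c("C1", "C1", "C2", "C2"))
  st2 <- species_status(bin_concordance("bin_label", ds2), ds2, "bin_label")
  expect_equal(st2$status, "IDENTIFIABLE")
  expect_equal(st2$n_bins, 2L)
})

test_that("unnamed bins are listed with optional country restriction", {
  ds <- audit_fixture()
  conc <- bin_concordance("bin_label", ds)
  expect_equal(unnamed_bins(conc, ds, "bin_label"), "B4")
  # B4 has one US and one... P8 is Canada, P9 US -> included for Canada
  expect_equal(unnamed_bins(conc, ds, "bin_label", "Canada"), "B4")
  expect_equal(unnamed_bins(conc, ds, "bin_label", "Mexico"), character(0))
  # a bin with any named member is never a candidate
  expect_false("B2" %in% unnamed_bins(conc, ds, "bin_label"))
})

test_that("library assembly includes exactly QC-passing, resolvable, binned records", {
  chk <- data.frame(
    suborder = "Heteroptera", family = "Miridae",
    genus = c("Aus", "Cus", "Eus"),
    species_epithet = c("bus", "dus", "fus"),
    canonical_name = c("Aus bus", "Cus dus", "Eus fus"),
    author = "", stringsAsFactors = FALSE)
  full <- strrep("ACGT", 160)   # 640 bp clean
  ds <- make_ds(
    paste0("R", 1:8),
    c("Aus bus", "Aus bus", "Cus dus", "Eus fus",
      "Unknown thing", "", "Aus bus", "Cus dus"),
    sequence = c(full, full, full, full, full, full,
                 strrep("ACGT", 100),                       # 400 bp: short
                 paste0(strrep("N", 20), strrep("A", 620))),# >1% N
    bin_label = c("B1", "B1", "B2", "B3", "B4", "B4", "B1", ""))
  build <- build_library(ds, chk, NULL, qc_config(), bins = "bin_label")
  expect_equal(build$records$process_id, c("R1", "R2", "R3", "R4"))
  ex <- setNames(build$excluded$reasons, build$excluded$process_id)
  expect_equal(ex[["R5"]], "NAME_UNRESOLVED")
  expect_true(all(c("NO_SPECIES", "NAME_UNRESOLVED") %in% ex[["R6"]]))
  expect_equal(ex[["R7"]], "TOO_SHORT")
  expect_true(all(c("TOO_AMBIGUOUS", "NO_BIN") %in% ex[["R8"]]))
  # excluded + included = input
  expect_equal(nrow(build$records) + nrow(build$excluded), nrow(ds))
  # idempotence: rebuilding from the library changes nothing
  again <- build_library(build$records, chk, NULL, qc_config(),
                         bins = "bin_label")
  expect_equal(again$records$process_id, build$records$process_id)
  expect_equal(nrow(again$excluded), 0L)
  # empty dataset -> empty build
  empty <- build_library(ds[0, ], chk, NULL, qc_config(), "bin_label")
  expect_equal(nrow(empty$records), 0L)
})

test_that("family coverage reports checklist proportions in order", {
  chk <- data.frame(
    suborder = rep("Heteroptera", 4),
    family = c("Mirid", "Mirid", "Nabid", "Tingid"),
    genus = c("Aus", "Cus", "Eus", "Gus"),
    species_epithet = c("bus", "dus", "fus", "hus"),
    canonical_name = c("Aus bus", "Cus dus", "Eus fus", "Gus hus"),
    author = "", stringsAsFactors = FALSE)
  full <- strrep("ACGT", 160)
  ds <- make_ds(c("F1", "F2"), c("Aus bus", "Eus fus"),
                sequence = c(full, full), bin_label = c("B1", "B2"))
  build <- build_library(ds, chk, NULL, qc_config(), "bin_label")
  cov <- build$checklist_coverage
  expect_equal(cov$proportion[cov$family == "Nabid"], 1.0)
  expect_equal(cov$proportion[cov$family == "Mirid"], 0.5)
  expect_equal(cov$proportion[cov$family == "Tingid"], 0.0)
  # sorted by proportion descending within suborder
  expect_equal(cov$family, c("Nabid", "Mirid", "Tingid"))
})

test_that("concordance histogram marginals sum to named bins in scope", {
  ds <- audit_fixture()
  conc <- bin_concordance("bin_label", ds)
  h <- concordance_histogram(conc, ds, "bin_label")
  expect_equal(sum(h$counts), 3L)  # B1, B2, B3 named
  expect_equal(unname(h$counts), c(2L, 1L, 0L))
  # one bin with 3 species
  ds3 <- make_ds(paste0("T", 1:3), c("Aa bb", "Cc dd", "Ee ff"),
                 bin_label = "Z1", family = "Famae")
  h3 <- concordance_histogram(bin_concordance("bin_label", ds3), ds3,
                              "bin_label")
  expect_equal(unname(h3$counts["three_plus"]), 1L)
  # family filter restricts the triples
  hf <- concordance_histogram(conc, ds, "bin_label",
                              family_filter = "Fambe")
  expect_equal(hf$triples$bin_id, "B3")
})

test_that("primer success proportions count recovered sequences per attempt", {
  ds <- make_ds(paste0("M", 1:12), "Aus bus",
                sequence = c(rep("ACGT", 7), rep("", 3), "ACGT", "ACGT"),
                family = c(rep("Miridae", 10), "Nabidae", "Nabidae"),
                primer_pair = c(rep("LepF1_LepR1", 10), "LCO_HCO", ""))
  m <- primer_success_matrix(ds)
  mir <- m[m$family == "Miridae" & m$primer_pair == "LepF1_LepR1", ]
  expect_equal(mir$attempts, 10L)
  expect_equal(mir$successes, 7L)
  expect_equal(mir$proportion, 0.7)
  nab <- m[m$family == "Nabidae", ]
  expect_equal(nab$proportion, 1.0)
  expect_equal(attr(m, "n_no_primer"), 1L)
  expect_true(all(m$proportion >= 0 & m$proportion <= 1))
})

test_that("suborder roll-up totals equal column sums and catch taxonomy conflicts", {
  chk <- data.frame(
    suborder = c("Heteroptera", "Heteroptera", "Sternorrhyncha"),
    family = c("Miridae", "Miridae", "Aphididae"),
    genus = c("Aus", "Cus", "Eus"),
    species_epithet = c("bus", "dus", "fus"),
    canonical_name = c("Aus bus", "Cus dus", "Eus fus"),
    author = "", stringsAsFactors = FALSE)
  full <- strrep("ACGT", 160)
  ds <- make_ds(
    paste0("S", 1:6),
    c("Aus bus", "Aus bus", "Cus dus", "Eus fus", "Eus fus", "Aus bus"),
    sequence = rep(full, 6),
    bin_label = c("B1", "B1", "B2", "B3", "B3", "B4"),
    family = c("Miridae", "Miridae", "Miridae", "Aphididae", "Aphididae",
               "Wrongidae"))  # S6: family conflicts with the checklist
  build <- build_library(ds, chk, NULL, qc_config(), "bin_label")
  tab <- suborder_summary(build, ds, chk, bins = "bin_label")
  expect_equal(tab$suborder,
               c("Heteroptera", "Sternorrhyncha", "Not.assigned", "Totals"))
  tot <- tab[tab$suborder == "Totals", ]
  body <- tab[tab$suborder != "Totals", ]
  for (col in setdiff(names(tab), "suborder"))
    expect_equal(tot[[col]], sum(body[[col]]), info = col)
  expect_equal(body$release_specimens, c(3L, 2L, 1L))
  expect_equal(body$lib_species, c(2L, 1L, 1L))
  # single-suborder dataset: totals equal that row
  ds1 <- ds[ds$family == "Miridae" & ds$species != "Eus fus", ]
  build1 <- build_library(ds1, chk, NULL, qc_config(), "bin_label")
  tab1 <- suborder_summary(build1, ds1, chk, bins = "bin_label")
  expect_equal(nrow(tab1), 2L)
  expect_equal(unlist(tab1[1, -1]), unlist(tab1[2, -1]),
               ignore_attr = TRUE)
})
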