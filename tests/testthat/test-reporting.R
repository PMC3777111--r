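# hand-built kinome object for report-shape tests
toy_kinome <- function() {
  calls <- data.frame(
    query_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    category = c("ePK", "ePK", "aPK", "twilight", "subthreshold",
                 "non_candidate"),
    group = c("CMGC", "", "Atypical", "", "", ""),
    family = c("CDK", "", "RIO", "", "", ""),
    subfamily = c("CDC2", "", "", "", "", ""),
    depth = c(3L, 0L, 2L, 0L, 0L, 0L),
    unclassified_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    tk_flag = FALSE,
    hmm_score = c(120, -80, 15, -100, -150, -200),
    motif_score = c(0.9, 0.5, 0.2, 0.6, 0.1, 0.05),
    best_blast_evalue = c(1e-60, 1e-4, 1e-45, NA, NA, NA),
    product_name = c("CMGC CDK CDC2 protein kinase",
                     "serine/threonine protein kinase",
                     "Atypical RIO protein kinase",
                     "protein kinase subdomain-containing protein",
                     "subthreshold", ""),
    stringsAsFactors = FALSE)
  structure(list(calls = calls, params = default_params(),
                 proteome_size = 120L),
            class = "kin_kinome")
}

test_that("the draft table has one row per protein with the documented columns", {
  tab <- draft_table(toy_kinome())
  expect_equal(nrow(tab), 6L)
  expect_equal(names(tab),
               c("id", "category", "group", "family", "subfamily", "depth",
                 "unclassified_flag", "tk_flag", "hmm_score", "motif_score",
                 "best_blast_evalue", "product_name"))
  expect_equal(tab$depth[tab$id == "p1"], 3L)
  # unclassified kinase: empty label fields, flag set in its own column
  p2 <- tab[tab$id == "p2", ]
  expect_equal(p2$group, "")
  expect_equal(p2$depth, 0L)
  expect_true(p2$unclassified_flag)
  expect_equal(tab$product_name[tab$id == "p4"],
               "protein kinase subdomain-containing protein")
})

test_that("the summary counts kinases, reports coverage and lists missing core kinases", {
  db <- toy_db()
  s <- summarize_kinome(toy_kinome(), db, core_species = c("hs", "dm", "ce"))
  expect_equal(s$total, 3L)                        # ePK + ePK + aPK
  expect_equal(s$unclassified, 1L)
  expect_equal(sum(s$per_group) + s$unclassified, s$total)
  expect_equal(s$percent_of_proteome, 100 * 3 / 120)
  # the core here is CMGC/CDK/CDC2 and TK/Src/SrcA; only the former called
  expect_true("TK/Src/SrcA" %in% s$missing_core)
  expect_false("CMGC/CDK/CDC2" %in% s$missing_core)
})

test_that("a kinome of 10 in a proteome of 200 is 5 percent", {
  k <- toy_kinome()
  k$calls <- k$calls[rep(1, 10), ]
  k$calls$query_id <- paste0("p", 1:10)
  k$proteome_size <- 200L
  s <- summarize_kinome(k, toy_db(), core_species = "hs")
  expect_equal(s$total, 10L)
  expect_equal(s$percent_of_proteome, 5.0)
})

test_that("phylogenetic profiles count classified kinases with consistent sums", {
  db <- toy_db()
  k <- toy_kinome()
  prof2 <- phylo_profile(k, db, depth = 2)
  # new-kinome column: p1 (CMGC/CDK) and p3 (Atypical/RIO); p2 unclassified
  expect_equal(sum(prof2[, "new"]), 2L)
  expect_equal(prof2["CMGC/CDK", "new"], 1L)
  # per-species column sums equal that species' depth>=2 entry count
  for (sp in db$species) {
    expect_equal(sum(prof2[, sp]),
                 sum(db$entries$species == sp & db$entries$depth >= 2))
  }
  # depth-1 aggregation preserves counts of deeper rows
  prof1 <- phylo_profile(k, db, depth = 1)
  expect_equal(sum(prof1[, "new"]), 2L)
  expect_gte(sum(prof1[, "hs"]), sum(prof2[, "hs"]))

  # empty kinome -> all-zero new column
  k0 <- k
  k0$calls <- k0$calls[0, ]
  prof0 <- phylo_profile(k0, db, depth = 1)
  expect_equal(sum(prof0[, "new"]), 0L)
})

test_that("parameter files round-trip, override and reject junk keys", {
  p <- default_params(n_consistent_hits = 5L, metazoan_mode = TRUE)
  path <- withr::local_tempfile(fileext = ".used")
  write_params(p, path)
  back <- read_params(path)
  expect_equal(unclass(back), unclass(p))

  # file overriding a single key keeps defaults for the rest (with notice)
  single <- withr::local_tempfile()
  writeLines("n_consistent_hits=5", single)
  expect_message(p2 <- read_params(single), "using defaults")
  expect_equal(p2$n_consistent_hits, 5L)
  expect_equal(p2$hmm_score_identification, -66)

  junk <- withr::local_tempfile()
  writeLines("no_such_cutoff=3", junk)
  expect_error(read_params(junk), "no_such_cutoff")

  badval <- withr::local_tempfile()
  writeLines("hmm_score_identification=abc", badval)
  expect_error(read_params(badval), "unparsable")
})

test_that("report files are reproduced byte-identically on re-run", {
  db <- toy_db()
  k <- toy_kinome()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_outputs(k, db, d1, core_species = "hs")
  write_outputs(k, db, d2, core_species = "hs")
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_setequal(list.files(d1),
                  c("draft_kinome.tsv", "summary.txt", "phylo_profile.tsv",
                    "product_names.tsv", "params.used"))
  # round-trip of the draft table preserves the calls
  back <- read_draft_table(file.path(d1, "draft_kinome.tsv"))
  expect_equal(back$calls$query_id, k$calls$query_id)
  expect_equal(back$calls$depth, k$calls$depth)
  expect_equal(back$calls$group, k$calls$group)
})
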