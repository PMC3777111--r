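test_that("the generator is a pure function of its spec", {
  spec <- fixture_spec(seed = 19, n_typical = 4L, n_unusual = 1L,
                       n_species_specific = 1L, n_apk = 1L, n_twilight = 1L,
                       n_non_kinase = 10L)
  r1 <- make_reference(spec)
  r2 <- make_reference(spec)
  expect_identical(r1$db$entries, r2$db$entries)
  expect_identical(r1$alignment$seqs, r2$alignment$seqs)
  p1 <- make_proteome(spec, r1)
  p2 <- make_proteome(spec, r2)
  expect_identical(p1$proteome, p2$proteome)
  expect_identical(p1$truth, p2$truth)

  # a different seed changes the sequences
  r3 <- make_reference(fixture_spec(seed = 20))
  expect_false(identical(r1$db$entries$sequence[1],
                         r3$db$entries$sequence[1]))
})

test_that("the reference hierarchy has the right shape and labels", {
  spec <- fixture_spec(seed = 19)
  ref <- make_reference(spec)
  e <- ref$db$entries
  typical <- e[e$depth == 3L, ]
  n_subfam <- spec$n_groups * spec$families_per_group *
    spec$subfamilies_per_family
  labels <- unique(paste(typical$group, typical$family, typical$subfamily,
                         sep = "/"))
  expect_equal(length(labels), n_subfam)
  expect_equal(nrow(typical), n_subfam * spec$members_per_subfamily)
  expect_equal(length(ref$db$species), spec$members_per_subfamily)
  # ePK entries are domain-length; aPK entries are full-length proteins
  expect_true(all(nchar(typical$sequence) == spec$domain_length))
  apk <- e[e$kinase_class == "aPK", ]
  expect_true(all(nchar(apk$sequence) > spec$domain_length))
  # unclassified entries retained
  expect_true(any(e$depth == 0L))
})

test_that("subfamily members are mutually closer than members of different groups", {
  ref <- make_reference(fixture_spec(seed = 19))
  e <- ref$db$entries[ref$db$entries$depth == 3L, ]
  identity <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  set.seed(4)
  subfams <- split(e$sequence, paste(e$group, e$family, e$subfamily))
  within <- replicate(50, {
    s <- sample(subfams, 1)[[1]]
    pair <- sample(s, 2)
    identity(pair[1], pair[2])
  })
  groups <- split(e$sequence, e$group)
  across <- replicate(50, {
    g <- sample(names(groups), 2)
    identity(sample(groups[[g[1]]], 1), sample(groups[[g[2]]], 1))
  })
  expect_gt(min(within), max(across))
})

test_that("the proteome and truth table are consistent and correctly labelled", {
  fx <- small_fixture()
  spec <- fx$internals$spec
  expect_identical(fx$truth$protein_id, names(fx$proteome))
  counts <- table(fx$truth$category)
  expect_equal(unname(counts["typical"]), spec$n_typical)
  expect_equal(unname(counts["unusual"]), spec$n_unusual)
  expect_equal(unname(counts["apk"]), spec$n_apk)
  expect_equal(unname(counts["non_kinase"]), spec$n_non_kinase)
  expect_equal(sum(fx$truth$is_kinase),
               spec$n_typical + spec$n_unusual + spec$n_species_specific +
                 spec$n_apk)
  # planted typical kinases carry their template's full label
  typ <- fx$truth[fx$truth$category == "typical", ]
  ref_labels <- with(fx$db$entries[fx$db$entries$depth == 3L, ],
                     unique(paste(group, family, subfamily, sep = "/")))
  expect_true(all(typ$label %in% ref_labels))
  # non-kinases and twilight sequences are not kinases in truth
  expect_true(all(!fx$truth$is_kinase[fx$truth$category %in%
                                        c("non_kinase", "twilight")]))
  # species-specific plants are flagged and labelled at group depth
  ss <- fx$truth[fx$truth$category == "species_specific", ]
  if (nrow(ss)) {
    expect_true(all(ss$species_specific))
    expect_true(all(!grepl("/", ss$label)))
  }
})

test_that("planted non-kinase motif scores fall stochastically below kinase motif scores", {
  fx <- small_fixture()
  motif <- fx$scores$motif_table
  cat_of <- fx$truth$category[match(motif$query_id, fx$truth$protein_id)]
  kin <- motif$value[cat_of %in% c("typical", "unusual", "species_specific")]
  nk <- motif$value[cat_of == "non_kinase"]
  w <- stats::wilcox.test(nk, kin, alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 1e-5)
  expect_lt(max(nk), min(kin))
})

test_that("degenerate and inconsistent specs are rejected", {
  expect_error(fixture_spec(n_groups = 0L), "n_groups")
  expect_error(fixture_spec(within_subfamily_divergence = 0.3,
                            within_family_divergence = 0.2),
               "strictly increasing")
  expect_error(fixture_spec(n_typical = -1L), "counts")
})

test_that("make_fixture writes a complete, reloadable file set", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 23, n_typical = 4L, n_unusual = 1L,
                       n_species_specific = 0L, n_apk = 1L, n_twilight = 1L,
                       n_non_kinase = 8L)
  fx <- make_fixture(spec, dir = dir)
  expect_setequal(list.files(dir),
                  c("refdb.fasta", "refdb.tsv", "alignment.fasta",
                    "proteome.fasta", "truth.tsv", "params.used"))
  db <- load_reference(file.path(dir, "refdb.fasta"),
                       file.path(dir, "refdb.tsv"))
  expect_identical(db$entries$id, fx$db$entries$id)
  aln <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(aln$seqs, fx$alignment$seqs)
  truth <- read_truth(file.path(dir, "truth.tsv"))
  expect_identical(truth$protein_id, fx$truth$protein_id)
  expect_equal(truth$is_kinase, fx$truth$is_kinase)
  params <- read_params(file.path(dir, "params.used"))
  expect_equal(params$hmm_score_identification,
               fx$params$hmm_score_identification)
})
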