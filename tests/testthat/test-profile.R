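test_that("profile column scores equal hand-computed log-odds", {
  aln <- as_alignment(c(r1 = "DAK", r2 = "DAR", r3 = "DCK"))
  prof <- build_profile(aln, pseudocount = 1)
  bg <- 1 / 20
  lo <- function(count) log2(((count + 1 * bg) / (3 + 1)) / bg)
  expect_equal(unname(prof$scores[1, "D"]), lo(3))
  expect_equal(unname(prof$scores[2, "A"]), lo(2))
  expect_equal(unname(prof$scores[2, "C"]), lo(1))
  expect_equal(unname(prof$scores[2, "W"]), lo(0))
  expect_equal(unname(prof$scores[3, "K"]), lo(2))
  # sign properties: consensus residue positive, unseen residue negative
  expect_gt(prof$scores[1, "D"], 0)
  expect_lt(prof$scores[1, "W"], 0)
})

test_that("identical rows give a profile whose max-scoring residues spell the row", {
  aln <- as_alignment(c(a = "MKWD", b = "MKWD", c = "MKWD"))
  prof <- build_profile(aln)
  expect_equal(prof$consensus, "MKWD")
})

test_that("columns with more than 50% gaps are dropped", {
  aln <- as_alignment(c(a = "M-KD", b = "M-K-", c = "MAK-"))
  prof <- build_profile(aln)
  # col2 has 2/3 gaps (dropped); col4 has 2/3 gaps (dropped)
  expect_equal(prof$columns, c(1L, 3L))
  expect_equal(prof$n_columns, 2L)
  expect_error(build_profile(as_alignment(c(a = "-", b = "-"))),
               "no match columns")
})

test_that("the profile consensus scores as the sum of per-column maxima with identity map", {
  set.seed(5)
  rows <- replicate(4, random_protein(12))
  names(rows) <- paste0("r", 1:4)
  prof <- build_profile(as_alignment(rows))
  hit <- score_sequence(prof, prof$consensus)
  expect_equal(hit$bit_score, sum(apply(prof$scores, 1, max)))
  expect_equal(hit$column_map, seq_len(prof$n_columns))
})

test_that("native profile scores match the brute-force DP oracle on random instances", {
  set.seed(101)
  for (trial in 1:250) {
    ncol <- sample(2:10, 1)
    nres <- sample(2:10, 1)
    S <- matrix(rnorm(ncol * 20, sd = 3), ncol, 20,
                dimnames = list(NULL, aa_alphabet()))
    q <- sample(0:20, nres, replace = TRUE)
    open <- runif(1, 1, 12)
    ext <- runif(1, 0.2, open)
    got <- kinclass:::.profile_sw_cpp(S, q, open, ext)$score
    want <- oracle_profile_score(S, q, open, ext)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("profile E-values scale with database size and separate kinases from noise", {
  fx <- small_fixture()
  prof <- fx$scores$profile$scores
  profile <- fx$scores$profile
  seq1 <- profile$consensus
  h1 <- score_sequence(profile, seq1, db_size = 100)
  h2 <- score_sequence(profile, seq1, db_size = 200)
  expect_equal(h1$bit_score, h2$bit_score)
  expect_equal(h2$e_value, 2 * h1$e_value)

  # a consensus-derived sequence outranks 100 random sequences by E-value
  set.seed(6)
  rand_e <- replicate(100, {
    score_sequence(profile, random_protein(nchar(seq1)), db_size = 100)$e_value
  })
  expect_true(all(h1$e_value < rand_e / 1e6))
})

test_that("HMMER3 tabular output parses with the best-domain rule and score scaling", {
  tbl <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "#                                     --- full sequence ---- ...",
    "p1 - model - 1e-30 100.5 0.1 1e-29 99.0 0.1 1 1 0 0 1 1 1 desc",
    "p2 - model - 2e-10  40.0 0.0 2e-10 40.0 0.0 1 1 0 0 1 1 1 desc",
    "p3 - model - 5.0     5.0 0.0 5.0    5.0 0.0 1 1 0 0 1 1 1 desc"),
    tbl)
  hits <- parse_hmmer(tbl)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$bit_score[hits$query_id == "p1"], 100.5)
  expect_equal(hits$e_value[hits$query_id == "p2"], 2e-10)

  # affine score scale (2, -10): raw 5 -> 0
  scaled <- parse_hmmer(tbl, score_scale = c(2, -10))
  expect_equal(scaled$bit_score[scaled$query_id == "p3"], 0)

  # domtblout: two domains for one protein -> single hit, better domain kept
  dom <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c(
    "# domtblout",
    paste("p1 - 500 model - 120 1e-40 90.0 0.1 1 2 1e-38 1e-35 60.0 0.1",
          "5 100 10 110 8 112 0.9 desc"),
    paste("p1 - 500 model - 120 1e-40 90.0 0.1 2 2 1e-20 1e-18 35.0 0.1",
          "200 300 210 310 205 315 0.8 desc")),
    dom)
  dh <- parse_hmmer(dom)
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$bit_score, 60.0)
  expect_equal(dh$e_value, 1e-40)
})

test_that("classic HMMER2 text output parses", {
  h2 <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "hmmsearch - search a sequence db with a profile HMM",
    "",
    "Scores for complete sequences (score includes all domains):",
    "Sequence Description                 Score    E-value  N",
    "-------- -----------                 -----    ------- ---",
    "kin1     putative kinase             -66.5      0.051   1",
    "kin2     another                     210.3    1.2e-60   2",
    "",
    "Parsed for domains:"), h2)
  hits <- parse_hmmer(h2)
  expect_equal(sort(hits$query_id), c("kin1", "kin2"))
  expect_equal(hits$bit_score[hits$query_id == "kin1"], -66.5)
  expect_equal(hits$e_value[hits$query_id == "kin2"], 1.2e-60)
})
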