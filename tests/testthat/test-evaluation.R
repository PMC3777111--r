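make_truth <- function(ids, is_kinase, label, ss = FALSE) {
  data.frame(protein_id = ids, is_kinase = is_kinase, label = label,
             species_specific = ss, stringsAsFactors = FALSE)
}

make_calls <- function(ids, category, label) {
  parts <- lapply(label, function(l) {
    if (l == "") character(0) else strsplit(l, "/", fixed = TRUE)[[1]]
  })
  data.frame(
    query_id = ids, category = category,
    group = vapply(parts, function(p) if (length(p) >= 1) p[1] else "", ""),
    family = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
    subfamily = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    depth = lengths(parts),
    stringsAsFactors = FALSE)
}

test_that("partial and full levels score shallow, wrong and agreeing calls as specified", {
  # reference at subfamily depth, call correct to family: partial TP, full FN
  truth <- make_truth("p1", TRUE, "CMGC/CDK/CDC2")
  calls <- make_calls("p1", "ePK", "CMGC/CDK")
  cp <- confusion_counts(truth, calls, "partial")
  cf <- confusion_counts(truth, calls, "full")
  expect_equal(c(cp$TP, cp$FP, cp$FN), c(1L, 0L, 0L))
  expect_equal(c(cf$TP, cf$FP, cf$FN), c(0L, 0L, 1L))

  # wrong subfamily negates the correct group/family: FP at both levels
  calls <- make_calls("p1", "ePK", "CMGC/CDK/PCTAIRE")
  expect_equal(confusion_counts(truth, calls, "partial")$FP, 1L)
  expect_equal(confusion_counts(truth, calls, "full")$FP, 1L)

  # agreement on "unclassified kinase" is a true negative for partial
  truth <- make_truth("p1", TRUE, "")
  calls <- make_calls("p1", "ePK", "")
  cp <- confusion_counts(truth, calls, "partial")
  expect_equal(c(cp$TN, cp$TP, cp$FP, cp$FN), c(1L, 0L, 0L, 0L))

  # no classification for a classified reference kinase: FN for partial
  truth <- make_truth("p1", TRUE, "CMGC/CDK")
  calls <- make_calls("p1", "ePK", "")
  expect_equal(confusion_counts(truth, calls, "partial")$FN, 1L)

  # family-depth reference: exact family match is a full TP, a deeper
  # subfamily assertion is FP
  truth <- make_truth("p1", TRUE, "CMGC/CDK")
  expect_equal(confusion_counts(truth, make_calls("p1", "ePK", "CMGC/CDK"),
                                "full")$TP, 1L)
  expect_equal(confusion_counts(truth,
                                make_calls("p1", "ePK", "CMGC/CDK/CDC2"),
                                "full")$FP, 1L)
})

test_that("identification counts satisfy TP + FN = P and flag extra calls", {
  truth <- make_truth(c("p1", "p2", "p3"), c(TRUE, TRUE, FALSE),
                      c("CMGC", "", ""))
  calls <- make_calls(c("p1", "p3", "p9"), c("ePK", "ePK", "aPK"),
                      c("CMGC", "", ""))
  cid <- confusion_counts(truth, calls, "identification")
  expect_equal(cid$P, 2L)
  expect_equal(cid$TP + cid$FN, cid$P)
  expect_equal(cid$TP, 1L)
  expect_equal(cid$FN, 1L)       # p2 not called
  expect_equal(cid$FP, 2L)       # p3 wrongly called + unknown p9
  expect_equal(attr(cid, "extra_calls"), "p9")
})

test_that("species-specific exclusion removes those entries from P and the counts", {
  truth <- make_truth(c("p1", "p2"), c(TRUE, TRUE), c("CMGC/CDK", "G1"),
                      ss = c(FALSE, TRUE))
  calls <- make_calls(c("p1", "p2"), c("ePK", "ePK"), c("CMGC/CDK", "G9"))
  full_all <- confusion_counts(truth, calls, "full")
  full_cons <- confusion_counts(truth, calls, "full",
                                exclude_species_specific = TRUE)
  expect_equal(full_all$P, 2L)
  expect_equal(full_all$FP, 1L)
  expect_equal(full_cons$P, 1L)
  expect_equal(full_cons$FP, 0L)
  expect_equal(full_cons$TP, 1L)
})

test_that("metric formulas match hand arithmetic and the stated conventions", {
  m <- confusion_metrics(list(TP = 1L, FP = 0L, FN = 0L, TN = 0L, P = 1L))
  expect_equal(c(m$TPR, m$PPV, m$F), c(1, 1, 1))

  m <- confusion_metrics(list(TP = 0L, FP = 1L, FN = 0L, TN = 0L, P = 1L))
  expect_equal(m$PPV, 0)
  expect_equal(m$FDR, 1)

  m <- confusion_metrics(list(TP = 3L, FP = 1L, FN = 3L, TN = 0L, P = 6L))
  expect_equal(m$TPR, 0.5)
  expect_equal(m$PPV, 0.75)
  expect_equal(m$F, 0.6)
  expect_equal(m$FDR, 1 - m$PPV)

  # no positive calls: PPV convention 1, FDR 0
  m <- confusion_metrics(list(TP = 0L, FP = 0L, FN = 2L, TN = 5L, P = 2L))
  expect_equal(m$PPV, 1)
  expect_equal(m$FDR, 0)
})

test_that("macro averaging is the unweighted mean and is identity for one species", {
  one <- list(list(TPR = 0.5, PPV = 0.25, FDR = 0.75, F = 1 / 3))
  expect_equal(unclass(macro_average(one))[c("TPR", "PPV")],
               list(TPR = 0.5, PPV = 0.25))
  two <- c(one, list(list(TPR = 1, PPV = 0.75, FDR = 0.25, F = 0.9)))
  expect_equal(macro_average(two)$TPR, 0.75)
  expect_equal(macro_average(two)$PPV, 0.5)
  expect_error(macro_average(list()), "empty")
})

test_that("confusion counts agree with a per-sequence recount oracle on random data", {
  set.seed(33)
  vocab <- c("A/a/x", "A/a/y", "A/b", "B/c", "B/c/z", "C", "")
  for (trial in 1:40) {
    n <- sample(5:40, 1)
    ids <- paste0("p", seq_len(n))
    truth <- make_truth(ids,
                        sample(c(TRUE, FALSE), n, replace = TRUE),
                        sample(vocab, n, replace = TRUE),
                        ss = sample(c(TRUE, FALSE), n, replace = TRUE,
                                    prob = c(0.2, 0.8)))
    truth$label[!truth$is_kinase] <- ""
    m <- sample(n)[seq_len(sample(n, 1))]
    calls <- make_calls(ids[m],
                        sample(c("ePK", "unusual_ePK", "aPK", "twilight",
                                 "subthreshold", "non_candidate"),
                               length(m), replace = TRUE),
                        sample(vocab, length(m), replace = TRUE))
    # non-kinome categories carry no classification
    nk <- !calls$category %in% c("ePK", "unusual_ePK", "aPK")
    calls[nk, c("group", "family", "subfamily")] <- ""
    calls$depth[nk] <- 0L

    for (level in c("identification", "partial", "full")) {
      for (excl in c(FALSE, TRUE)) {
        got <- confusion_counts(truth, calls, level, excl)
        want <- oracle_confusion(truth, calls, level, excl)
        expect_equal(got$TP, want$TP, label = paste(level, excl, "TP"))
        expect_equal(got$FP, want$FP, label = paste(level, excl, "FP"))
        expect_equal(got$FN, want$FN, label = paste(level, excl, "FN"))
        expect_equal(got$TN, want$TN, label = paste(level, excl, "TN"))
        expect_equal(got$P, want$P, label = paste(level, excl, "P"))
      }
    }
    # full-level TP never exceeds partial-level TP
    expect_lte(confusion_counts(truth, calls, "full")$TP,
               confusion_counts(truth, calls, "partial")$TP)
    # identification satisfies TP + FN = P
    cid <- confusion_counts(truth, calls, "identification")
    expect_equal(cid$TP + cid$FN, cid$P)
  }
})

test_that("roc_sweep with a single value equals direct evaluation and rejects bad names", {
  fx <- small_fixture()
  sw <- roc_sweep(fx$scores, fx$truth, "n_consistent_hits", 3L, "full",
                  fx$params)
  k <- call_kinome(fx$scores, fx$params)
  m <- confusion_metrics(confusion_counts(fx$truth, k, "full"))
  expect_equal(sw$TPR, m$TPR)
  expect_equal(sw$FDR, m$FDR)
  expect_error(roc_sweep(fx$scores, fx$truth, "bogus", 1), "unknown parameter")
})

test_that("truth tables read from TSV with logical coercion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tis_kinase\tlabel\tspecies_specific\tcategory",
               "p1\tTRUE\tCMGC/CDK\tFALSE\ttypical",
               "p2\tFALSE\t\tFALSE\tnon_kinase"), path)
  truth <- read_truth(path)
  expect_equal(truth$is_kinase, c(TRUE, FALSE))
  expect_equal(truth$label, c("CMGC/CDK", ""))
  expect_equal(truth$category, c("typical", "non_kinase"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb", bad)
  expect_error(read_truth(bad), "must have columns")
})
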