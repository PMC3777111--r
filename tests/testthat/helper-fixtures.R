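# Shared fixtures, built once per test run and memoised.

# small end-to-end fixture: quick enough for per-module tests
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(fixture_spec(
        seed = 11, n_typical = 8L, n_unusual = 2L, n_species_specific = 1L,
        n_apk = 2L, n_twilight = 2L, n_non_kinase = 30L))
    }
    cache
  }
})

# the default 250-protein study fixture used by the acceptance checks
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(fixture_spec(seed = 1))
    cache
  }
})

# fixture with deliberate subfamily ambiguity: shallow subfamilies (two
# members each) plus plants sitting at family consensus positions
ambiguity_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(fixture_spec(
        seed = 7, subfamilies_per_family = 2L, members_per_subfamily = 2L,
        n_typical = 6L, n_family_level = 24L, n_unusual = 0L,
        n_species_specific = 0L, n_apk = 0L, n_twilight = 0L,
        n_non_kinase = 30L))
    }
    cache
  }
})

# hand-built reference database with a known vocabulary, for rule tests
toy_db <- function() {
  entries <- data.frame(
    id = c("cdc2_hs", "cdc2_dm", "cdc2_ce", "pctaire_hs",
           "agc1_hs", "camk1_hs", "src_hs", "src_dm", "src_ce",
           "rio1_hs", "uncl_hs"),
    species = c("hs", "dm", "ce", "hs", "hs", "hs", "hs", "dm", "ce",
                "hs", "hs"),
    group = c("CMGC", "CMGC", "CMGC", "CMGC", "AGC", "CAMK", "TK", "TK",
              "TK", "Atypical", ""),
    family = c("CDK", "CDK", "CDK", "CDK", "PKA", "CAMK1", "Src", "Src",
               "Src", "RIO", ""),
    subfamily = c("CDC2", "CDC2", "CDC2", "PCTAIRE", "", "", "SrcA",
                  "SrcA", "SrcA", "", ""),
    kinase_class = c(rep("ePK", 9), "aPK", "ePK"),
    sequence = replicate(11, random_protein(40)),
    stringsAsFactors = FALSE)
  entries$depth <- (entries$group != "") + (entries$family != "") +
    (entries$subfamily != "")
  kinclass:::new_refdb(entries)
}

# ranked-hit data.frame builder for consensus tests
toy_hits <- function(reference_ids, e_values) {
  data.frame(query_id = "q", reference_id = reference_ids,
             raw_score = NA_real_,
             bit_score = -log2(e_values),
             e_value = e_values, rank = seq_along(reference_ids),
             stringsAsFactors = FALSE)
}
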