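scheme <- default_scheme()
cxxc2 <- parse_motif("CxxC-CxxC")

test_that("pattern parsing enforces the element grammar", {
  p <- parse_motif("CxxC-CxxxxC", "uS4")
  expect_length(p$element1, 4)
  expect_length(p$element2, 6)
  expect_equal(p$n_constrained, 4)
  q <- parse_motif("Cxx[CDE]-CxxC")
  expect_equal(q$element1[[4]], c("C", "D", "E"))
  expect_error(parse_motif("xCxC-CxxC"), "constrained")
  expect_error(parse_motif("CxxC"), "two")
})

test_that("match_pattern finds the leftmost in-order non-overlapping pair", {
  expect_null(match_pattern("MKVRPSV", cxxc2))
  expect_equal(match_pattern("MCAKCGGGGCRRCA", cxxc2), c(2, 10))
  # second element would overlap the first: no match
  expect_null(match_pattern("CAKCRRC", cxxc2))
  # zero-length spacer allowed: elements back to back
  expect_equal(match_pattern("CAACCBBC", cxxc2), c(1, 5))
  expect_null(match_pattern("", cxxc2))
})

test_that("ambiguity codes satisfy wildcards but never constrained positions", {
  expect_equal(match_pattern("CXXCCXXC", cxxc2), c(1, 5))
  expect_null(match_pattern("XAAXCAAC", cxxc2))  # X is not a Cys
  h <- parse_motif("CxxC-CxxH")
  expect_equal(match_pattern("MCBZCAACAAH", h), c(2, 8))
})

test_that("match_pattern agrees with the brute-force placement oracle", {
  set.seed(101)
  seqs <- random_aa(10000)
  pats <- list(cxxc2, parse_motif("CxxC-CxxH"), parse_motif("CxxC-CxxxxC"),
               parse_motif("CxxC-CxxD"))
  for (p in pats) {
    got <- lapply(seqs, match_pattern, pattern = p)
    want <- lapply(seqs, bf_match, pattern = p)
    expect_identical(got, want, label = p$pattern_string)
  }
})

test_that("mutating a constrained residue to A never creates a new match", {
  set.seed(202)
  seqs <- random_aa(400, max_len = 40)
  for (s in seqs) {
    m <- match_pattern(s, cxxc2)
    if (is.null(m)) {
      # no match: mutating any C to A keeps it matchless
      pos <- which(strsplit(s, "")[[1]] == "C")
      for (i in pos) {
        substr(s, i, i) <- "A"
        expect_null(match_pattern(s, cxxc2))
      }
    } else {
      # destroy every matched constrained residue: match may move or die,
      # but each single mutation never matches at the mutated position
      for (i in c(m[1], m[1] + 3, m[2], m[2] + 3)) {
        s2 <- s
        substr(s2, i, i) <- "A"
        m2 <- match_pattern(s2, cxxc2)
        if (!is.null(m2)) expect_false(i %in% c(m2[1], m2[1] + 3,
                                                m2[2], m2[2] + 3))
      }
    }
  }
})

test_that("isoform calls follow the all/none/mixed rule", {
  cplus <- "MCAKCGGGGCRRCA"
  cminus <- "MKVRPSVGGGGAKL"
  one <- classify_protein_isoform(
    mk_records("r1", "sp1", "bL32", cplus), scheme)
  expect_equal(one$call, "only_cplus")
  mixed <- classify_protein_isoform(
    mk_records(c("r1", "r2"), "sp1", "bL32", c(cplus, cminus)), scheme)
  expect_equal(mixed$call, "both")
  expect_equal(mixed$n_sequences, 2)
  none <- classify_protein_isoform(
    mk_records(paste0("r", 1:3), "sp1", "bL32", rep(cminus, 3)), scheme)
  expect_equal(none$call, "only_cminus")
  expect_error(classify_protein_isoform(
    mk_records("r", "s", "bL32", "M")[0, ], scheme), "zero")
})

test_that("species C+ count treats 'both' as C+ and reports missing proteins", {
  all9 <- data.frame(species_id = "sp1", protein = METAL_PROTEINS,
                     call = "only_cplus", n_sequences = 1)
  expect_equal(as.integer(species_cplus_count(all9, scheme)), 9)
  one <- data.frame(species_id = "sp1",
                    protein = METAL_PROTEINS,
                    call = c("both", rep("only_cminus", 8)),
                    n_sequences = 1)
  expect_equal(as.integer(species_cplus_count(one, scheme)), 1)
  expect_warning(n <- species_cplus_count(all9[0, ], scheme), "no sequence data")
  expect_equal(as.integer(n), 0)
  expect_length(attr(n, "missing_proteins"), 9)
  expect_error(species_cplus_count(rbind(all9, all9[1, ]), scheme),
               "duplicate")
})

test_that("bL33 typing tests CCCC, then CCCD, then CCCE", {
  expect_equal(classify_bl33_variant("MCAKCGGGGCRRCA"), "CCCC")
  expect_equal(classify_bl33_variant("MCAKCGGGGCRRDA"), "CCCD")
  expect_equal(classify_bl33_variant("MCAKCGGGGCRREA"), "CCCE")
  expect_equal(classify_bl33_variant("MAAAA"), "none")
  # CCCC wins whenever present, regardless of additional D/E matches
  both <- "MCAKCGCRRDGCRRCA"   # contains CxxC-CxxD and CxxC-CxxC
  expect_equal(classify_bl33_variant(both), "CCCC")
})

test_that("coordinating residues sum to 36 over the scheme and 8 for bL36+bL32", {
  expect_equal(coordinating_residue_count(scheme), 36L)
  expect_equal(coordinating_residue_count(scheme, c("bL36", "bL32")), 8L)
  expect_equal(coordinating_residue_count(scheme, character(0)), 0L)
  expect_error(coordinating_residue_count(scheme, "uL99"), "unknown")
})

test_that("the packaged scheme annotates eight zinc proteins and one Fe-S", {
  expect_setequal(names(scheme$patterns), METAL_PROTEINS)
  expect_equal(sum(scheme$metal == "zinc"), 8)
  expect_equal(unname(scheme$metal["uS4"]), "iron_sulfur")
  expect_named(scheme$patterns$bL33, c("CCCC", "CCCD", "CCCE"))
})
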