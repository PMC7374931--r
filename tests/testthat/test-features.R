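test_that("glycosylation sequons are counted by overlapping regex scan", {
  # "NASNGT": N-A-S at 1 and N-G-T at 4
  prot <- protein_topology("P1", "NASNGT",
                           data.frame(start = 1, end = 6,
                                      kind = "non_cytoplasmic"))
  f <- extract_features(prot)
  expect_equal(unname(f["non_cytoplasmic.n_glyc_sequons"]), 2)

  # N-P-S is not a sequon; overlapping N-N-S / N-S-T both are
  prot2 <- protein_topology("P2", "NPSANNST",
                            data.frame(start = 1, end = 8,
                                       kind = "non_cytoplasmic"))
  expect_equal(unname(extract_features(prot2)["non_cytoplasmic.n_glyc_sequons"]),
               2)

  # sequons are only counted in the non-cytoplasmic domain
  prot3 <- protein_topology("P3", "NASNGT",
                            data.frame(start = 1, end = 6,
                                       kind = "cytoplasmic"))
  expect_equal(unname(extract_features(prot3)["non_cytoplasmic.n_glyc_sequons"]),
               0)
})

test_that("absent domains yield all-zero features", {
  prot <- protein_topology("P1", "MKLVFF",
                           data.frame(start = 1, end = 6,
                                      kind = "transmembrane"))
  f <- extract_features(prot)
  sp <- f[startsWith(names(f), "signal_peptide.")]
  expect_true(all(sp == 0))
  expect_equal(unname(f["transmembrane.n_residues"]), 6)
})

test_that("degenerate composition gives frequency 1 for one residue", {
  prot <- protein_topology("P1", "AAAAAA",
                           data.frame(start = 1, end = 6,
                                      kind = "transmembrane"))
  f <- extract_features(prot)
  expect_equal(unname(f["transmembrane.freq_A"]), 1)
  other <- f[startsWith(names(f), "transmembrane.freq_")]
  expect_equal(sum(other), 1)
})

test_that("residues pool across same-kind segments; frequencies sum to 1", {
  prot <- protein_topology(
    "P1", "AAAACCCCGGGG",
    data.frame(start = c(1, 9), end = c(4, 12),
               kind = c("cytoplasmic", "cytoplasmic")))
  f <- extract_features(prot)
  expect_equal(unname(f["cytoplasmic.n_segments"]), 2)
  expect_equal(unname(f["cytoplasmic.n_residues"]), 8)
  expect_equal(unname(f["cytoplasmic.mean_segment_length"]), 4)
  expect_equal(unname(f["cytoplasmic.freq_A"]), 0.5)
  expect_equal(unname(f["cytoplasmic.freq_G"]), 0.5)
  freqs <- f[startsWith(names(f), "cytoplasmic.freq_")]
  expect_equal(sum(freqs), 1)
})

test_that("invalid topologies and residues are rejected", {
  expect_error(protein_topology("P1", "ACDB",
                                data.frame(start = 1, end = 4,
                                           kind = "cytoplasmic")),
               "alphabet")
  expect_error(protein_topology("P1", "ACDE",
                                data.frame(start = c(1, 3), end = c(3, 4),
                                           kind = "cytoplasmic")),
               "overlap")
  expect_error(protein_topology("P1", "ACDE",
                                data.frame(start = 1, end = 9,
                                           kind = "cytoplasmic")),
               "coordinates")
  # X is tolerated and carries no frequency mass
  f <- extract_features(protein_topology(
    "P1", "AXXA", data.frame(start = 1, end = 4, kind = "cytoplasmic")))
  expect_equal(unname(f["cytoplasmic.freq_A"]), 1)
  expect_equal(unname(f["cytoplasmic.n_residues"]), 4)
})

test_that("FASTA + topology round-trip preserves features", {
  spec <- fixture_spec(seed = 21)
  ids <- sprintf("Q%02d", 1:4)
  fx <- make_sequence_fixture(spec, ids, positive_ids = ids[1:2])
  fa <- tempfile(fileext = ".fasta"); topo <- tempfile(fileext = ".tsv")
  write_sequence_fixture(fx$proteins, fa, topo)
  back <- read_topologies(fa, topo)
  expect_setequal(names(back), ids)
  expect_equal(feature_matrix(back)[ids, ],
               feature_matrix(fx$proteins)[ids, ])
})
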