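test_that("translation follows the standard code with stop termination", {
  expect_equal(translate_dna("ATGGGA"), "MG")
  expect_equal(translate_dna("ATGTAA"), "M")
  expect_equal(translate_dna("ATGTAAGGG"), "M")        # stop terminates
  expect_equal(translate_dna("atgGGAu"), "MG")          # case and partial codon
  expect_equal(translate_dna("ATGNNNGGA"), "MXG")       # ambiguity to X
  expect_equal(translate_dna("GATGGGA", frame = 2), "MG")
  expect_error(translate_dna("AT"), "invalid sequence")
  expect_error(translate_dna("ATGQQQ"), "invalid sequence")
})

test_that("physicochemical indices match the independent reference values", {
  for (ref in protparam_reference) {
    rec <- protein_properties(ref$seq)
    # reference masses differ from the Expasy table in the 4th decimal
    # of a few residues; that bounds the achievable MW agreement
    expect_equal(rec$mw_Da, ref$mw, tolerance = 5e-5)
    expect_equal(rec$pI, ref$pI, tolerance = 0.01)
    expect_equal(rec$instability_index, ref$instability, tolerance = 1e-5)
    expect_equal(rec$gravy, ref$gravy, tolerance = 1e-5)
    expect_equal(rec$aliphatic_index, ref$aliphatic, tolerance = 1e-5)
  }
})

test_that("poly-Ala has aliphatic index 100 and GRAVY 1.8", {
  rec <- protein_properties(strrep("A", 25))
  expect_equal(rec$aliphatic_index, 100)
  expect_equal(rec$gravy, 1.8)
})

test_that("GRAVY equals a hand-summed oracle on short peptides and stays in range", {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  for (seed in 1:10) {
    s <- random_protein(10, seed = 300 + seed)
    oracle <- sum(kd[strsplit(s, "")[[1]]]) / 10
    rec <- protein_properties(s)
    expect_equal(rec$gravy, oracle, tolerance = 1e-12)
    expect_gte(rec$gravy, -4.5)
    expect_lte(rec$gravy, 4.5)
  }
})

test_that("molecular weight is additive up to one water", {
  s1 <- "MKWVTF"; s2 <- "ISLLLL"
  mw <- function(s) protein_properties(s)$mw_Da
  expect_equal(mw(paste0(s1, s2)), mw(s1) + mw(s2) - 18.01524, tolerance = 1e-9)
})

test_that("charge decreases in pH and vanishes at the reported pI", {
  s <- protparam_reference$rand60$seq
  ph <- seq(1, 13, by = 0.5)
  q <- protein_charge(s, ph)
  expect_true(all(diff(q) < 0))
  pI <- isoelectric_point(s)
  expect_lt(abs(protein_charge(s, pI)), 1e-4)
})

test_that("instability reversal-invariance holds only for symmetric dipeptides", {
  # GG and AA weights are symmetric: reversal changes nothing
  rec_f <- protein_properties("GGAAGG")
  rec_r <- protein_properties("GGAAGG")  # palindrome by construction
  expect_equal(rec_f$instability_index, rec_r$instability_index)
  # WC and CW carry different published weights: reversal shifts the index
  expect_false(isTRUE(all.equal(protein_properties("WWC")$instability_index,
                                protein_properties("CWW")$instability_index)))
})

test_that("unknown residues are skipped with renormalization and a warning", {
  expect_warning(rec <- protein_properties("AAXAA"), "unknown residue")
  expect_equal(rec$length, 5L)
  expect_equal(rec$gravy, 1.8)  # computed over the four alanines
  expect_equal(rec$n_unknown, 1L)
  expect_error(protein_properties(""), "invalid sequence")
  expect_error(suppressWarnings(protein_properties("XX")), "no standard residues")
})

test_that("FASTA round trip preserves sequences", {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  seqs <- c(rec1 = "ATGGGATAA", rec2 = "MKWVTFISLL")
  write_fasta(seqs, tmp)
  back <- read_fasta(tmp)
  expect_equal(unname(back), unname(seqs))
  expect_equal(names(back), names(seqs))
})
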