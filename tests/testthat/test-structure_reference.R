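test_that("classic DSSP parsing recovers fixture content and skips breaks", {
  path <- withr::local_tempfile(fileext = ".dssp")
  write_dssp_fixture(dssp_helix_fixture(), path)
  res <- parse_dssp(path)
  expect_identical(nrow(res), 12L)
  expect_identical(sum(res$ss_code == "H"), 10L)
  expect_identical(res$aa, dssp_helix_fixture()$aa)
  # header only -> empty table
  empty <- parse_dssp(c("junk", "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"))
  expect_identical(nrow(empty), 0L)
  # one '!' chain break among 6 residues is excluded
  brk <- data.frame(aa = c("A", "K", "V", "!", "L", "E", "G"),
                    ss_code = c("H", "H", "H", " ", " ", " ", " "),
                    stringsAsFactors = FALSE)
  expect_identical(nrow(parse_dssp(write_dssp_fixture(brk))), 6L)
  # missing header and short lines raise informative errors
  expect_error(parse_dssp(c("no", "header", "here")), "format error")
  lines <- write_dssp_fixture(dssp_helix_fixture())
  lines[4L] <- substr(lines[4L], 1L, 15L)
  expect_error(parse_dssp(lines), "line 2")
})

test_that("structure fractions follow the 100 - H - E rule", {
  path <- withr::local_tempfile(fileext = ".dssp")
  write_dssp_fixture(dssp_helix_fixture(), path)
  p <- compute_fractions(parse_dssp(path))
  expect_equal(p[["H"]], 100 * 10 / 12)
  expect_equal(p[["E"]], 0)
  expect_equal(p[["H"]] + p[["E"]] + p[["Others"]], 100, tolerance = 1e-9)
  # all-helix protein
  allh <- data.frame(aa = rep("A", 10L), ss_code = rep("H", 10L))
  pa <- compute_fractions(parse_dssp(write_dssp_fixture(allh)))
  expect_equal(unname(pa[c("H", "E", "Others")]), c(100, 0, 0))
  # highly helical protein: 73% H, 0% E leaves 27% Others
  myo <- data.frame(aa = rep("A", 100L),
                    ss_code = c(rep("H", 73L), rep(" ", 27L)))
  pm <- compute_fractions(parse_dssp(write_dssp_fixture(myo)))
  expect_equal(unname(pm[c("H", "E", "Others")]), c(73, 0, 27))
  # fully irregular protein: 0/0/100
  met <- data.frame(aa = rep("A", 60L), ss_code = rep(" ", 60L))
  pz <- compute_fractions(parse_dssp(write_dssp_fixture(met)))
  expect_equal(unname(pz[c("H", "E", "Others")]), c(0, 0, 100))
  expect_error(compute_fractions(parse_dssp(write_dssp_fixture(
    data.frame(aa = character(), ss_code = character())))), "empty")
})

test_that("helix amputation splits ordered and disordered helix", {
  # one 10-residue helix in a 10-residue protein: 6 ordered, 4 tips
  one <- data.frame(aa = rep("A", 10L), ss_code = rep("H", 10L))
  s1 <- ordered_helix_split(parse_dssp(write_dssp_fixture(one)))
  expect_equal(unname(s1), c(60, 40))
  # a 4-residue helix is all tips
  short <- data.frame(aa = rep("A", 10L),
                      ss_code = c(rep("H", 4L), rep(" ", 6L)))
  s2 <- ordered_helix_split(parse_dssp(write_dssp_fixture(short)))
  expect_equal(unname(s2), c(0, 40))
  # helices of length 6 and 5 in 20 residues: (2 + 1)/20 ordered
  two <- data.frame(aa = rep("A", 20L),
                    ss_code = c(rep("H", 6L), rep(" ", 3L), rep("H", 5L),
                                rep(" ", 6L)))
  s3 <- ordered_helix_split(parse_dssp(write_dssp_fixture(two)))
  expect_equal(s3[["ordered_H"]], 15)
  # splits always recompose to H
  p <- compute_fractions(parse_dssp(write_dssp_fixture(two)))
  expect_equal(p[["ordered_H"]] + p[["disordered_H"]], p[["H"]],
               tolerance = 1e-9)
})

test_that("sheet sense split follows the ladder-case convention", {
  anti <- parse_dssp(write_dssp_fixture(dssp_hairpin_fixture("antiparallel")))
  sa <- sheet_sense_split(anti)
  expect_equal(sa[["E_antiparallel"]], 80)
  expect_equal(sa[["E_parallel"]], 0)
  par <- parse_dssp(write_dssp_fixture(dssp_hairpin_fixture("parallel")))
  sp <- sheet_sense_split(par)
  expect_equal(sp[["E_parallel"]], 80)
  expect_equal(sp[["E_antiparallel"]], 0)
  # no sheet at all
  none <- parse_dssp(write_dssp_fixture(dssp_helix_fixture()))
  expect_equal(unname(sheet_sense_split(none)), c(0, 0))
  # E residue without ladder info: warned, counted antiparallel
  orphan <- data.frame(aa = rep("A", 5L),
                       ss_code = c("E", "E", " ", " ", " "),
                       ladder = c("", "", "", "", ""))
  expect_warning(so <- sheet_sense_split(parse_dssp(write_dssp_fixture(orphan))),
                 "antiparallel")
  expect_equal(so[["E_antiparallel"]], 40)
  # and the profile invariant E_par + E_anti = E holds
  pf <- compute_fractions(anti)
  expect_equal(pf[["E_parallel"]] + pf[["E_antiparallel"]], pf[["E"]],
               tolerance = 1e-9)
})

test_that("amino-acid composition matches hand counts on real sequences", {
  glucagon <- "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT"
  cg <- aa_composition(glucagon)
  expect_equal(round(cg[["Q"]], 2), 10.34)  # 3 of 29
  expect_equal(round(cg[["R"]], 2), 6.90)   # 2 of 29
  ubiquitin <- paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQL",
                      "EDGRTLSDYNIQKESTLHLVLRLRGG")
  expect_equal(round(aa_composition(ubiquitin)[["Q"]], 2), 7.89)  # 6 of 76
  expect_equal(unname(aa_composition("AAAAAAAAAA")[["A"]]), 100)
  expect_equal(sum(cg), 100, tolerance = 1e-9)
  expect_error(aa_composition("ACDEFGX"), "unknown amino-acid")
})

test_that("structure profiles reject inconsistent fractions", {
  expect_error(structure_profile(H = 60, E = 30, Others = 20), "equal 100")
  expect_error(structure_profile(H = 60, E = 40, ordered_H = 30,
                                 disordered_H = 20), "ordered_H")
  expect_error(structure_profile(H = -5, E = 50, Others = 55), "0, 100")
  p <- structure_profile(H = 40, E = 25, ordered_H = 25,
                         E_antiparallel = 20, E_parallel = 5)
  expect_equal(p[["Others"]], 35)
})

test_that("fraction reports and FASTA reading round-trip", {
  profs <- list(
    p1 = structure_profile(H = 73, E = 0),
    p2 = structure_profile(H = 0, E = 0)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fraction_report(profs, path)
  back <- utils::read.delim(path)
  expect_identical(back$protein_id, c("p1", "p2"))
  expect_equal(back$Others, c(27, 100))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqA test", "HSQGTF", "TSDY", ">seqB", "MQIF"), fa)
  seqs <- read_fasta_sequences(fa)
  expect_identical(unname(seqs["seqA test"]), "HSQGTFTSDY")
  expect_identical(unname(seqs["seqB"]), "MQIF")
})
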