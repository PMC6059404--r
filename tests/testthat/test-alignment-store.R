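# Loading, validation, filtering and position lookup of the aligned
# sequence universe.

write_fixture_files <- function(dir, seqs, labels, md_lines) {
  fa <- file.path(dir, "f.fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), fa)
  pm <- file.path(dir, "f_positions.tsv")
  writeLines(c("column\tlabel",
               sprintf("%d\t%s", seq_along(labels) - 1L, labels)), pm)
  md <- file.path(dir, "f_metadata.tsv")
  writeLines(md_lines, md)
  c(fasta = fa, posmap = pm, metadata = md)
}

four_seq_files <- function(dir) {
  seqs <- c(R1_HUMAN = "NDRIVPWYAC", R2_HUMAN = "NDRIVPWYAC",
            R3_BOVIN = "NDRVVPWYAC", R4_DANRE = "NDRLVPWFAC")
  labels <- c("1.50", "2.50", "3.50", "3.51", "3.52",
              "5.50", "6.44", "6.50", "7.50", "8.50")
  md <- c("entry_name\tgpcr_class\ttaxon_group\tolfactory\tscheme:fredriksson",
          "R1_HUMAN\tA\thuman\tFALSE\talpha/amine",
          "R2_HUMAN\tA\thuman\tFALSE\talpha/amine",
          "R3_BOVIN\tA\tmammal\tFALSE\tbeta/npy",
          "R4_DANRE\tA\tvertebrate\tFALSE\tbeta/npy")
  write_fixture_files(dir, seqs, labels, md)
}

test_that("a written fixture loads back with the right shape", {
  dir <- withr::local_tempdir()
  paths <- four_seq_files(dir)
  aln <- read_alignment(paths["fasta"], paths["posmap"], paths["metadata"])
  expect_s3_class(aln, "gpcr_alignment")
  expect_equal(n_sequences(aln), 4L)
  expect_equal(ncol(aln$matrix), 10L)
  expect_equal(aln$position_map$label[3L], "3.50")
})

test_that("load rejects ragged alignments, bad symbols and name mismatches", {
  dir <- withr::local_tempdir()
  paths <- four_seq_files(dir)

  bad_fa <- file.path(dir, "ragged.fasta")
  writeLines(c(">R1_HUMAN", "NDRIVPWYAC", ">R2_HUMAN", "NDRIVPWYA"), bad_fa)
  md2 <- file.path(dir, "md2.tsv")
  writeLines(c("entry_name\tgpcr_class\ttaxon_group\tolfactory",
               "R1_HUMAN\tA\thuman\tFALSE", "R2_HUMAN\tA\thuman\tFALSE"), md2)
  expect_error(read_alignment(bad_fa, paths["posmap"], md2),
               class = "gpcr_shape_error")

  j_fa <- file.path(dir, "badchar.fasta")
  writeLines(c(">R1_HUMAN", "NDRIVPWYAJ"), j_fa)
  md1 <- file.path(dir, "md1.tsv")
  writeLines(c("entry_name\tgpcr_class\ttaxon_group\tolfactory",
               "R1_HUMAN\tA\thuman\tFALSE"), md1)
  expect_error(read_alignment(j_fa, paths["posmap"], md1),
               class = "gpcr_alphabet_error")

  # ambiguity codes are rejected too, not treated as gaps
  expect_error(gpcr_alignment(c(R1_HUMAN = "NDRIVPWYAB"),
                              labels = paste0("1.", 50:59)),
               class = "gpcr_alphabet_error")

  expect_error(read_alignment(paths["fasta"], paths["posmap"], md1),
               class = "gpcr_consistency_error")
})

test_that("load -> write -> load round-trips bit-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  aln <- default_fixture(seed = 7, dir = dir1)
  p1 <- file.path(dir1, c("fixture.fasta", "fixture_positions.tsv",
                          "fixture_metadata.tsv"))
  reread <- read_alignment(p1[1], p1[2], p1[3])
  write_alignment(reread, dir2, "fixture")
  p2 <- file.path(dir2, c("fixture.fasta", "fixture_positions.tsv",
                          "fixture_metadata.tsv"))
  for (k in 1:3) {
    expect_identical(readBin(p1[k], "raw", file.size(p1[k])),
                     readBin(p2[k], "raw", file.size(p2[k])))
  }
})

test_that("taxonomic sets are cumulative and selection is idempotent", {
  dir <- withr::local_tempdir()
  paths <- four_seq_files(dir)
  aln <- read_alignment(paths["fasta"], paths["posmap"], paths["metadata"])

  expect_equal(n_sequences(select_receptors(aln, taxon = "Human")), 2L)
  expect_equal(n_sequences(select_receptors(aln, taxon = "Mammals")), 3L)
  expect_equal(n_sequences(select_receptors(aln, taxon = "Vertebrates")), 4L)

  sizes <- vapply(c("Human", "Mammals", "Vertebrates", "Eukaryotes", "All"),
                  function(tx) n_sequences(select_receptors(aln, taxon = tx)),
                  integer(1L))
  expect_true(all(diff(sizes) >= 0L))

  sel <- select_receptors(aln, scheme = "fredriksson", path = "alpha")
  expect_equal(n_sequences(sel), 2L)
  sel2 <- select_receptors(sel, scheme = "fredriksson", path = "alpha")
  expect_identical(sel$sequences, sel2$sequences)

  expect_error(select_receptors(aln, gpcr_class = "C"),
               class = "gpcr_empty_selection")
})

test_that("path prefixes match whole components and olfactory is opt-in", {
  md <- meta_with_scheme(sprintf("R%d_HUMAN", 1:4), "A", "human",
                         c(FALSE, FALSE, TRUE, FALSE),
                         c("alpha/amine", "alpha", "alpha/olfactory", "alphax"))
  aln <- aln_from_cols(list(c("I", "I", "V", "L")), labels = "3.40",
                       metadata = md)
  sel <- select_receptors(aln, scheme = "fredriksson", path = "alpha")
  expect_setequal(names(sel$sequences), c("R1_HUMAN", "R2_HUMAN"))
  sel_olf <- select_receptors(aln, scheme = "fredriksson", path = "alpha",
                              include_olfactory = TRUE)
  expect_equal(n_sequences(sel_olf), 3L)
})

test_that("generic labels translate to columns in specification order", {
  labels <- c("1.50", "2.50", "3.50", "3.51", "3.52",
              "5.50", "6.44", "6.50", "7.50", "8.50")
  aln <- aln_from_cols(rep(list(rep("A", 2L)), 10L), labels = labels)

  expect_equal(columns_for(aln, "3.50"), 3L)
  expect_equal(columns_for(aln, "3.50-3.52"), c(3L, 4L, 5L))
  # non-consecutive positions keep the order as written
  expect_equal(columns_for(aln, "6.44,3.50,5.50"), c(7L, 3L, 6L))
  expect_error(columns_for(aln, "4.50"), class = "gpcr_position_error")
  expect_error(columns_for(aln, "3.50-5.50"), class = "gpcr_range_error")
  # range endpoints must themselves be mapped
  expect_error(columns_for(aln, "3.50-3.54"), class = "gpcr_position_error")
})

test_that("position specifications round-trip through format()", {
  for (txt in c("3.50", "3.50-3.54", "3.40,5.50,6.44", "1.50-1.52,8.50")) {
    expect_equal(format(parse_positions(txt)), txt)
    expect_equal(parse_positions(format(parse_positions(txt))),
                 parse_positions(txt))
  }
})
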