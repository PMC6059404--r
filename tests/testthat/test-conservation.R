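# Frequency tables, scaled Shannon entropy, percent occurrence,
# consensus, and category-level comparisons.

test_that("frequency tables count gap-free residues and tuples", {
  aln <- aln_from_cols(list(c("I", "I", "V", "V")), labels = "3.40")
  ft <- frequency_table(aln, "3.40")
  expect_equal(attr(ft, "n_effective"), 4L)
  expect_equal(ft$count[order(ft$tuple)], c(2L, 2L))
  expect_equal(ft$prob, c(0.5, 0.5))

  aln2 <- aln_from_cols(list(c("I", "I", "-", "V")), labels = "3.40")
  ft2 <- frequency_table(aln2, "3.40")
  expect_equal(attr(ft2, "n_effective"), 3L)
  expect_equal(ft2$prob[ft2$tuple == "I"], 2 / 3)

  aln3 <- aln_from_cols(list(c("A", "A", "V"), c("L", "L", "F")),
                        labels = c("3.40", "6.44"))
  ft3 <- frequency_table(aln3, "3.40,6.44")
  expect_setequal(ft3$tuple, c("AL", "VF"))
  expect_equal(ft3$count[ft3$tuple == "AL"], 2L)

  all_gap <- aln_from_cols(list(c("-", "-"), c("A", "A")),
                           labels = c("1.50", "1.51"))
  expect_error(frequency_table(all_gap, "1.50"),
               class = "gpcr_empty_denominator")
})

test_that("entropy hits its closed-form limits", {
  cons <- aln_from_cols(list(rep("R", 5L)), labels = "3.50")
  expect_equal(shannon_entropy(cons, "3.50")$H, 0)

  unif <- aln_from_cols(list(AAS), labels = "3.50")
  e <- shannon_entropy(unif, "3.50")
  expect_equal(e$H, 1.0)
  expect_equal(e$b, 20)

  half <- aln_from_cols(list(c("I", "I", "V", "V")), labels = "3.40")
  expect_equal(shannon_entropy(half, "3.40")$H, log(2) / log(20),
               tolerance = 1e-12)
})

test_that("joint entropy scales by base 20^n", {
  # all 400 dipeptides exactly once -> uniform over the full alphabet
  grid <- expand.grid(a = AAS, b = AAS, stringsAsFactors = FALSE)
  aln <- aln_from_cols(list(grid$a, grid$b), labels = c("1.50", "1.51"))
  e <- shannon_entropy(aln, "1.50-1.51")
  expect_equal(e$b, 400)
  expect_equal(e$H, 1.0)

  # two perfectly covarying uniform columns: 20 joint symbols out of 400
  aln2 <- aln_from_cols(list(AAS, AAS), labels = c("1.50", "1.51"))
  expect_equal(shannon_entropy(aln2, "1.50-1.51")$H, log(20) / log(400))
})

test_that("merging two residues' counts never increases entropy", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(3:8, 1L)
    counts <- as.numeric(rmultinom(1L, 60L, rep(1, k)))
    counts <- counts[counts > 0]
    residues <- sample(AAS, length(counts))
    col <- rep(residues, times = counts)
    H_full <- shannon_entropy(aln_from_cols(list(col), labels = "2.50"),
                              "2.50")$H
    # merge the first residue into the second
    col_merged <- ifelse(col == residues[1L], residues[2L], col)
    H_merged <- shannon_entropy(aln_from_cols(list(col_merged),
                                              labels = "2.50"), "2.50")$H
    expect_lte(H_merged, H_full + 1e-12)
  }
})

test_that("percent occurrence uses gap-free denominators and lists matches", {
  aln <- aln_from_cols(list(c("I", "I", "V", "V")), labels = "3.40")
  occ <- percent_occurrence(aln, "3.40", "I")
  expect_equal(occ$percent, 50)
  expect_setequal(occ$receptors, c("SEQ001_HUMAN", "SEQ002_HUMAN"))

  apolar <- percent_occurrence(
    aln_from_cols(list(c("I", "V", "T", "S")), labels = "3.40"), "3.40", "~")
  expect_equal(apolar$percent, 50)

  none <- percent_occurrence(aln, "3.40", "W")
  expect_equal(none$percent, 0)
  expect_length(none$receptors, 0L)

  gappy <- aln_from_cols(list(c("I", "I", "-", "V")), labels = "3.40")
  expect_equal(percent_occurrence(gappy, "3.40", "I")$percent, 100 * 2 / 3)

  set.seed(31)
  aln_r <- random_aln(10L, 2L)
  expect_equal(percent_occurrence(aln_r, "1.50,1.51", "XX")$percent, 100)
})

test_that("consensus picks the modal residue with lexicographic ties", {
  aln <- aln_from_cols(list(c("I", "I", "V"),
                            c("V", "I", "-"),
                            c("-", "-", "-")),
                       labels = c("1.50", "1.51", "1.52"))
  cons <- consensus_sequence(aln)
  expect_equal(cons$residue, c("I", "I", "-"))
  expect_equal(cons$freq, c(2 / 3, 1 / 2, 0))
  expect_equal(cons$tie, c(FALSE, TRUE, FALSE))
})

test_that("level comparisons match direct per-category recomputation", {
  aln <- default_fixture(seed = 3)
  lv <- compare_levels(aln, "3.40", "I", gpcr_class = "A", taxon = "Human",
                       scheme = "fredriksson", path = "alpha")
  expect_true("beta" %in% lv$category[lv$level == "same"])
  expect_false("alpha" %in% lv$category[lv$level == "same"])
  expect_setequal(lv$category[lv$level == "sub"],
                  c("alpha/amine", "alpha/opsin"))

  for (r in seq_len(nrow(lv))) {
    if (is.na(lv$percent[r])) next
    sel <- select_receptors(aln, gpcr_class = "A", taxon = "Human",
                            scheme = "fredriksson", path = lv$category[r])
    direct <- percent_occurrence(sel, "3.40", "I")
    expect_equal(lv$percent[r], direct$percent)
    expect_equal(lv$n_effective[r], direct$n_effective)
  }
})

test_that("child-category match counts add up to the parent's", {
  aln <- default_fixture(seed = 3)
  parent <- percent_occurrence(
    select_receptors(aln, gpcr_class = "C", taxon = "All"), "3.40", "@")
  lv <- compare_levels(aln, "3.40", "@", gpcr_class = "C", taxon = "All",
                       scheme = "fredriksson", path = "glutamate")
  kids <- lv[lv$level == "sub", ]
  expect_gt(nrow(kids), 1L)
  expect_equal(sum(kids$n_match), parent$n_match)
  expect_equal(sum(kids$n_effective), parent$n_effective)
})

test_that("a root query has no same-level categories and a leaf no children", {
  aln <- default_fixture(seed = 3)
  lv_root <- compare_levels(aln, "3.40", "I", taxon = "All")
  expect_equal(nrow(lv_root), 0L)
  lv_leaf <- compare_levels(aln, "3.40", "I", gpcr_class = "A",
                            taxon = "Human", scheme = "fredriksson",
                            path = "alpha/amine")
  expect_length(lv_leaf$category[lv_leaf$level == "sub"], 0L)
  expect_true("alpha/opsin" %in% lv_leaf$category[lv_leaf$level == "same"])
})
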