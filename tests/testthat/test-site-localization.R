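# site_localization: ladder-based site assignment and derivatization typing

let7a <- "UGAGGUAGUAGGUUGUAUAGUU"

sim_full_ladder <- function(seq, pos, id = "m6A") {
  ol <- oligo(seq, mods = sprintf("%d:%s", pos, id))
  ladder <- fragment_ladder(ol)
  peaklist(sort(unique(ladder$mz)),
           rep(100, length(unique(ladder$mz))), ms_level = 2L)
}

test_that("a complete noiseless ladder localizes the planted site uniquely", {
  # let-7a-5p carries adenines at 3, 7, 10, 17, 19
  msms <- sim_full_ladder(let7a, 10)
  res <- localize(msms, oligo(let7a), "m6A")
  expect_equal(res$position[1], 10)
  expect_equal(attr(res, "ambiguity"), 10)
  expect_true(all(res$score[-1] < res$score[1]))
})

test_that("missing separating ions produce the expected ambiguity set", {
  s <- "UGCAGAGUCC"          # adenines at 4 and 6
  ol_true <- oligo(s, mods = "4:m6A")
  # c/y/w only: for those series the methyl shift follows containment
  # exactly, so dropping the separating ions makes 4 and 6 indistinguishable
  ladder <- fragment_ladder(ol_true, series = c("c", "y", "w"))
  sep <- (ladder$contains_from <= 4 & ladder$contains_to >= 4) !=
    (ladder$contains_from <= 6 & ladder$contains_to >= 6)
  kept <- ladder[!sep, ]
  msms <- peaklist(sort(unique(kept$mz)), rep(100, length(unique(kept$mz))),
                   ms_level = 2L)
  res <- localize(msms, oligo(s), "m6A", series = c("c", "y", "w"))
  expect_setequal(attr(res, "ambiguity"), c(4, 6))
})

test_that("an empty MS/MS spectrum scores every candidate zero", {
  msms <- peaklist(numeric(), numeric(), ms_level = 2L)
  res <- localize(msms, oligo(let7a), "m6A")
  expect_true(all(res$score == 0))
  expect_setequal(attr(res, "ambiguity"),
                  which(strsplit(let7a, "")[[1]] == "A"))
})

test_that("localization errors without a legal candidate position", {
  expect_error(localize(peaklist(numeric(), numeric()), oligo("GGUU"),
                        "m6A"), "no candidate")
})

test_that("hydrazine cleaves unprotected cytosines only", {
  s <- "AACGAUCGG"           # C at 3 and 7
  ol <- oligo(s, mods = "7:m5C")
  prod <- hydrazine_cleavage_pattern(ol)
  expect_equal(nrow(prod), 2)  # cleavage only at position 3
  expect_equal(prod$from, c(1, 4))
  expect_equal(prod$to, c(2, 9))
  # masses match the structural oracle: AA (5'P parent, 3'P cut) and
  # GAUCGG with the m5C methyl on its (shifted) cytosine
  expect_equal(prod$neutral_mass[1],
               oracle_oligo_mass("AA", "phosphate", "phosphate"),
               tolerance = 1e-9)
  expect_equal(prod$neutral_mass[2],
               oracle_oligo_mass("GAUCGG", "phosphate", "hydroxyl",
                                 n_methyl = 1), tolerance = 1e-9)
})

test_that("hydrazine degenerate cases: no C, all protected, bad input", {
  # no cytosines: intact mass, single product
  prod <- hydrazine_cleavage_pattern(oligo("AAGU"))
  expect_equal(nrow(prod), 1)
  expect_equal(prod$neutral_mass, oligo_mass(oligo("AAGU")), tolerance = 1e-9)
  # all C protected: identical to intact
  s <- "ACGCU"
  prod2 <- hydrazine_cleavage_pattern(oligo(s), protected_positions = c(2, 4))
  expect_equal(nrow(prod2), 1)
  expect_equal(prod2$neutral_mass, oligo_mass(oligo(s)), tolerance = 1e-9)
  expect_error(hydrazine_cleavage_pattern(oligo(s), protected_positions = 3),
               "cytosines")
  expect_error(hydrazine_cleavage_pattern(oligo(s), protected_positions = 9),
               "outside")
})

test_that("m5C placements are distinguishable iff segment signatures differ", {
  # Two placements are genuinely confusable when their cleavage products
  # have identical base-composition/terminus multisets (e.g. protecting
  # either C of ...GCGG...GGCG... environments).  The mass pattern must
  # separate exactly the placements whose signatures differ.
  signature <- function(s, p) {
    bases <- strsplit(s, "")[[1]]
    cut <- setdiff(which(bases == "C"), p)
    bounds <- c(0L, cut, length(bases) + 1L)
    segs <- character()
    for (i in seq_len(length(bounds) - 1L)) {
      from <- bounds[i] + 1L; to <- bounds[i + 1L] - 1L
      if (from > to) next
      cnt <- table(factor(bases[from:to], levels = c("A", "C", "G", "U")))
      segs <- c(segs, paste(paste(cnt, collapse = ","),
                            from == 1L, to == length(bases),
                            p >= from && p <= to, sep = "|"))
    }
    paste(sort(segs), collapse = ";")
  }
  set.seed(23)
  n_diff <- 0L
  for (rep in 1:40) {
    s <- random_oligo_seq(sample(8:20, 1))
    cpos <- which(strsplit(s, "")[[1]] == "C")
    if (length(cpos) < 2) next
    pair <- sample(cpos, 2)
    masses <- lapply(pair, function(p) {
      ol <- oligo(s, mods = sprintf("%d:m5C", p))
      sort(round(hydrazine_cleavage_pattern(ol)$neutral_mass, 6))
    })
    sig_equal <- signature(s, pair[1]) == signature(s, pair[2])
    expect_equal(identical(masses[[1]], masses[[2]]), sig_equal, info = s)
    if (!sig_equal) n_diff <- n_diff + 1L
  }
  expect_gt(n_diff, 10)   # the generic case is distinguishable
  # documented confusable counterexample: protecting C6 vs C9 of this
  # sequence yields interior products GCGG+me vs GGCG+me (same
  # composition) and swaps two single-G products — identical patterns
  s_conf <- "UCACGCGGCGCUAAGUG"
  m6 <- hydrazine_cleavage_pattern(oligo(s_conf, mods = "6:m5C"))
  m9 <- hydrazine_cleavage_pattern(oligo(s_conf, mods = "9:m5C"))
  expect_equal(sort(m6$neutral_mass), sort(m9$neutral_mass),
               tolerance = 1e-9)
})

test_that("DMS shift discriminates m6A from m1A", {
  ch2 <- methyl_delta_mass()
  s <- "AUAAGCAAUG"          # 5 adenines
  expect_equal(as.character(
    classify_adenine_methylation(s, 5 * ch2 + 0.1)), "m6A")
  expect_equal(as.character(
    classify_adenine_methylation(s, 4 * ch2 - 0.2)), "m1A")
  expect_equal(as.character(
    classify_adenine_methylation(s, 35.0)), "undetermined")
  res <- classify_adenine_methylation(s, 5 * ch2)
  expect_equal(attr(res, "predicted_m6A"), 5 * ch2, tolerance = 1e-9)
  expect_equal(attr(res, "predicted_m1A"), 4 * ch2, tolerance = 1e-9)
  expect_error(classify_adenine_methylation("GGCU", 14), "no adenine")
})
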