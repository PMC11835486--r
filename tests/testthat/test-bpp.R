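test_that("hairpin validation names the record and rejects malformed input", {
  h <- hairpin_record("toy", "GGGGAAAACCCC", "((((....))))",
                      arm5 = c(0, 4), arm3 = c(8, 12))
  expect_s3_class(h, "hairpin_record")

  expect_error(hairpin_record("bad1", "GGGGAAAACCCC", "((((....)))",
                              c(0, 4), c(8, 12)), "bad1.*length")
  expect_error(hairpin_record("bad2", "GGGGAAAACCCC", "((((....()))",
                              c(0, 4), c(8, 12)), "unbalanced")
  expect_error(hairpin_record("bad3", "GGGGAAAACCCC", "))((....(())",
                              c(0, 4), c(8, 12)), "unbalanced")
  expect_error(hairpin_record("bad4", "GGGGAAAACCCC", "((((....))))",
                              c(0, 9), c(8, 12)), "overlap")
  expect_error(hairpin_record("bad5", "GGGGAAAACCCC", "((((....))))",
                              c(0, 4), c(8, 14)), "arm3")
  expect_error(hairpin_record("bad6", "GGGXAAAACCCC", "((((....))))",
                              c(0, 4), c(8, 12)), "non-ACGU")
})

test_that("mature duplex extraction keeps exactly the inter-arm bonds", {
  # perfect 8-bp stem: bonds (0,7), (1,6), ... in arm-local coordinates
  h <- hairpin_record("stem", "GGGGGGGGAAAACCCCCCCC",
                      "((((((((....))))))))", c(0, 8), c(12, 20))
  d <- extract_mature_duplex(h)
  expect_equal(d$n_bonds, 8L)
  expect_equal(d$bonds$i5, 0:7)
  expect_equal(d$bonds$j3, 7:0)
  expect_equal(d$seq5, "GGGGGGGG")
  expect_equal(d$seq3, "CCCCCCCC")

  # structure pairs confined to the loop region: no inter-arm bonds
  h2 <- hairpin_record("loopy", "AAAAGGAACCAAAA", "....((..))....",
                       c(0, 4), c(10, 14))
  d2 <- extract_mature_duplex(h2)
  expect_equal(d2$n_bonds, 0L)

  # one internal bulge on the 5' arm: arm5 has 9 nt, position 4 bulged,
  # so 8 bonds; hand-enumerated arm-local pairs
  #   arm5: ( ( ( ( . ( ( ( (   -> i5 = 0,1,2,3,5,6,7,8
  #   arm3: ) ) ) ) ) ) ) )     -> j3 = 7..0 matched inside-out
  seqn <- paste0("GGGGAGGGG", "AAAA", "CCCCCCCC")
  stru <- paste0("((((.((((", "....", "))))))))")
  h3 <- hairpin_record("bulge", seqn, stru, c(0, 9), c(13, 21))
  d3 <- extract_mature_duplex(h3)
  expect_equal(d3$n_bonds, 8L)
  expect_equal(d3$bonds$i5, c(0:3, 5:8))
  expect_equal(d3$bonds$j3, c(7:4, 3:0))
})

test_that("duplex constructor enforces bond sanity", {
  expect_error(mature_duplex("x", "GGG", "CCC",
                             data.frame(i5 = 3L, j3 = 0L)), "out of range")
  expect_error(mature_duplex("x", "GGG", "CCC",
                             data.frame(i5 = c(0L, 0L), j3 = c(1L, 2L))),
               "more than one bond")
  expect_error(mature_duplex("x", "GGG", "CCC",
                             data.frame(i5 = c(0L, 1L), j3 = c(0L, 1L))),
               "cross")
})

test_that("reference engine equals exhaustive enumeration of matchings", {
  none <- data.frame(i5 = integer(0), j3 = integer(0))
  # no WC/GU pair possible: all-zero matrix
  dA <- mature_duplex("a", "AAAA", "AAAA", none)
  expect_true(all(cofold_bpp(dA) == 0))

  # the worked GC/GC example
  dGC <- mature_duplex("gc", "GC", "GC", none)
  expect_equal(unclass(cofold_bpp(dGC)), brute_force_bpp("GC", "GC"),
               ignore_attr = TRUE)

  set.seed(13)
  for (i in 1:20) {
    m <- sample(2:6, 1L); n <- sample(2:6, 1L)
    s5 <- paste0(sample(c("A", "C", "G", "U"), m, TRUE), collapse = "")
    s3 <- paste0(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    d <- mature_duplex("r", s5, s3, none)
    P <- cofold_bpp(d)
    expect_equal(unclass(P), brute_force_bpp(s5, s3), ignore_attr = TRUE)
    expect_true(all(rowSums(P) <= 1 + 1e-12))
    expect_true(all(colSums(P) <= 1 + 1e-12))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("BPP curve looks up recorded bonds and fills the rest with row means", {
  d <- mature_duplex("t", "GGG", "CCCC",
                     data.frame(i5 = 2L, j3 = 1L))
  m <- matrix(0, 3, 4)
  m[3, 2] <- 0.9           # the recorded bond
  m[1, ] <- c(0.2, 0.4, 0, 0)  # an unrecorded 5' position
  cv <- bpp_curve(m, d)
  # 5' arm positions -3..-1 (position -1 abuts the loop = seq5 index 3)
  expect_equal(cv$position, c(-3, -2, -1, 1, 2, 3, 4))
  expect_equal(cv$bpp[cv$position == -1], 0.9)
  expect_equal(cv$bpp[cv$position == 2], 0.9)   # same bond from the 3' side
  expect_equal(cv$bpp[cv$position == -3], mean(c(0.2, 0.4, 0, 0)))
  # recorded flags: 5' index 3 (position -1) and 3' index 2 (position +2)
  expect_equal(cv$recorded,
               c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))

  # all-zero matrix gives an all-zero curve
  cv0 <- bpp_curve(matrix(0, 3, 4), d)
  expect_true(all(cv0$bpp == 0))

  expect_error(bpp_curve(matrix(0, 2, 4), d), "dimensions")
})

test_that("AUC is the trapezoidal integral of the curve", {
  mk <- function(pos, val) {
    structure(data.frame(position = pos, bpp = val,
                         recorded = TRUE),
              class = c("bpp_curve", "data.frame"), id = "t")
  }
  # constant 1.0 spanning 22 unit intervals (no position 0)
  expect_equal(bpp_auc(mk(c(-11:-1, 1:11), rep(1, 22)))$auc, 22)
  expect_equal(bpp_auc(mk(c(-3:-1, 1:3), rep(0, 6)))$auc, 0)
  expect_equal(bpp_auc(mk(-1:1, c(0, 1, 0)))$auc, 1)
  expect_error(bpp_auc(mk(0, 1)), "at least 2")

  # AUC never exceeds the position span
  set.seed(3)
  for (i in 1:10) {
    pos <- sort(sample(-10:10, 6))
    val <- runif(6)
    a <- bpp_auc(mk(pos, val))
    expect_lte(a$auc, diff(range(pos)))
    expect_gte(a$auc, 0)
  }
})

test_that("the hairpin scoring pipeline is deterministic end to end", {
  recs <- gen_hairpin_dataset(5, theta = 0.7, seed = 21)
  s1 <- hairpin_bpp_auc(recs)
  s2 <- hairpin_bpp_auc(recs)
  expect_identical(s1$auc, s2$auc)
  expect_equal(nrow(s1), 5L)
  expect_true(all(s1$auc >= 0))
  # curve length equals the number of distinct mature positions
  curves <- attr(s1, "curves")
  for (i in seq_along(recs)) {
    d <- extract_mature_duplex(recs[[i]])
    expect_equal(nrow(curves[[d$id]]), nchar(d$seq5) + nchar(d$seq3))
  }
})

test_that("strengthening the stem never decreases the AUC score", {
  # fully complementary 7-bp stem vs the same hairpin with the middle
  # stem position replaced by an A-C mismatch
  strong <- hairpin_record("strong", "GCGCGCGAAAACGCGCGC",
                           "(((((((....)))))))", c(0, 7), c(11, 18))
  weak <- hairpin_record("weak", "GCGAGCGAAAACGCCCGC",
                         "(((.(((....))).)))", c(0, 7), c(11, 18))
  score <- function(h) {
    d <- extract_mature_duplex(h)
    bpp_auc(bpp_curve(cofold_bpp(d), d))
  }
  a_strong <- score(strong)
  a_weak <- score(weak)
  expect_equal(a_strong$n_bonds, 14L)
  expect_equal(a_weak$n_bonds, 12L)
  expect_gte(a_strong$auc, a_weak$auc)
})

test_that("hairpin TSV round trip preserves records and logs exclusions", {
  recs <- gen_hairpin_dataset(4, theta = 0.9, seed = 33)
  path <- tempfile(fileext = ".tsv")
  write_hairpins_tsv(recs, path)
  back <- read_hairpins_tsv(path)
  expect_length(back, 4L)
  expect_equal(back[[2L]]$sequence, recs[[2L]]$sequence)
  expect_equal(back[[2L]]$arm3, recs[[2L]]$arm3)

  # corrupt one structure: the record is excluded with a reason
  lines <- readLines(path)
  f <- strsplit(lines[3L], "\t")[[1L]]
  f[3L] <- substr(f[3L], 1, nchar(f[3L]) - 1L)
  lines[3L] <- paste(f, collapse = "\t")
  writeLines(lines, path)
  expect_message(back2 <- read_hairpins_tsv(path), "excluding")
  expect_length(back2, 3L)
  excl <- attr(back2, "excluded")
  expect_equal(nrow(excl), 1L)
  expect_match(excl$reason, "length")
  expect_error(read_hairpins_tsv(path, strict = TRUE), "length")
})

test_that("cohort-mean filling differs only at unrecorded positions", {
  recs <- gen_hairpin_dataset(6, theta = 0.5, seed = 8)
  a_partner <- hairpin_bpp_auc(recs, fill = "partner_mean")
  a_cohort <- hairpin_bpp_auc(recs, fill = "cohort_mean")
  cp <- attr(a_partner, "curves"); cc <- attr(a_cohort, "curves")
  for (id in names(cp)) {
    rec <- cp[[id]]$recorded
    expect_identical(cp[[id]]$bpp[rec], cc[[id]]$bpp[rec])
    expect_identical(cp[[id]]$recorded, cc[[id]]$recorded)
  }
  expect_false(identical(a_partner$auc, a_cohort$auc))
})
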