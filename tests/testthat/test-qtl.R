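sig_df <- function(pos, chrom = "1", lod = NULL) {
  if (is.null(lod)) lod <- seq(5, 5 + 0.1 * (length(pos) - 1), by = 0.1)
  data.frame(snp_id = sprintf("c%s_p%d", chrom, pos), chrom = chrom,
             pos = pos, neglog10p = lod)
}

test_that("significance selection is strictly greater than the threshold", {
  scan <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                     pos = c(100, 200, 300),
                     neglog10p = c(4.0, -log10(1e-5), 3.9))
  sig <- significant_snps(scan, threshold = 4)
  expect_identical(sig$snp_id, "b")
  expect_identical(nrow(significant_snps(scan[0, ], 4)), 0L)
})

test_that("QTL calling handles the canonical window examples", {
  q <- call_qtl(sig_df(c(1000000, 1400000, 1900000)), trait = "E10")
  expect_identical(nrow(q), 1L)
  expect_equal(c(q$start, q$end), c(1000000, 1900000))
  expect_identical(q$n_snps, 3L)

  expect_identical(nrow(call_qtl(sig_df(c(1000000, 2500000)))), 0L)

  # peak is the member with the highest score
  q2 <- call_qtl(sig_df(c(100, 200, 300), lod = c(5, 9, 6)))
  expect_identical(q2$peak_snp, "c1_p200")
  expect_equal(q2$peak_lod, 9)

  expect_error(call_qtl(sig_df(c(300, 100, 200))), "sorted")
})

test_that("QTL caller agrees with the brute-force window oracle", {
  set.seed(31)
  for (rep in 1:300) {
    m <- sample(3:50, 1)
    pos <- sort(sample.int(5e6, m))
    sig <- sig_df(pos, lod = runif(m, 4.1, 10))
    got <- call_qtl(sig, window = 1e6, min_snps = 3)
    want <- oracle_call_qtl(pos, window = 1e6, min_snps = 3)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      want_members <- lapply(want, function(idx) sig$snp_id[idx])
      got_members <- lapply(got$members[order(got$start)], identity)
      want_members <- want_members[order(vapply(want, min, integer(1)))]
      expect_identical(got_members, unname(want_members))
    }
  }
})

test_that("unique-QTL merging uses >= 1 bp overlap, transitively", {
  q <- data.frame(chrom = c("1", "1", "2"),
                  start = c(1, 5, 1), end = c(10, 20, 10),
                  n_snps = 3L, peak_snp = c("x", "y", "z"),
                  peak_lod = c(5, 7, 6), trait = c("E10", "L10", "E10"))
  q$members <- list(c("a", "b", "c"), c("c", "d", "e"), c("f", "g", "h"))
  m <- merge_unique(q)
  expect_identical(nrow(m), 2L)
  chr1 <- m[m$chrom == "1", ]
  expect_equal(c(chr1$start, chr1$end), c(1, 20))
  expect_identical(chr1$members[[1]], c("a", "b", "c", "d", "e"))
  expect_identical(chr1$traits, "E10+L10")
  expect_identical(chr1$peak_snp, "y")

  # touching intervals do not merge; merging is idempotent
  qt <- q[1:2, ]; qt$start <- c(1, 11); qt$end <- c(10, 20)
  expect_identical(nrow(merge_unique(qt)), 2L)
  expect_identical(nrow(merge_unique(merge_unique(q)[, ])), 2L)
})

test_that("merging agrees with an independent sweep-line oracle", {
  set.seed(32)
  for (rep in 1:100) {
    k <- sample(2:25, 1)
    st <- sample.int(1e6, k)
    df <- data.frame(chrom = sample(c("1", "2"), k, replace = TRUE),
                     start = st, end = st + sample.int(2e5, k),
                     n_snps = 3L, peak_snp = "x", peak_lod = 5,
                     trait = sample(c("E10", "L12"), k, replace = TRUE))
    df$members <- replicate(k, list("x"))
    got <- merge_unique(df)
    got <- got[order(got$chrom, got$start), c("chrom", "start", "end")]
    want <- oracle_merge_intervals(df)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("multi-trait QTL require two distinct sources and follow the naming", {
  q <- data.frame(chrom = c("5", "5", "5", "5", "7"),
                  start = c(100, 150, 180, 5000, 10),
                  end = c(200, 250, 300, 6000, 40),
                  n_snps = 3L, peak_snp = letters[1:5],
                  peak_lod = c(5, 6, 7, 8, 9),
                  trait = c("E8", "L10", "L16", "LT50", "L10"))
  q$members <- replicate(5, list("x"))
  merged <- merge_unique(q)
  mt <- multi_trait(merged)
  # overlapping E8+L10+L16 region qualifies; lone-LT50 and lone-L10 do not
  expect_identical(nrow(mt), 1L)
  expect_identical(mt$qtl, "qMT5")
  expect_setequal(mt$sources[[1]], c("E8", "L10", "L16"))

  # a four-source merged region keeps all its trait-temperature labels
  q2 <- q
  q2$start <- c(100, 150, 180, 210, 10); q2$end <- c(200, 250, 300, 400, 40)
  mt2 <- multi_trait(merge_unique(q2))
  expect_setequal(mt2$sources[[1]], c("E8", "L10", "L16", "LT50"))

  # one region per chromosome drops the index, several keep it
  q3 <- rbind(q2, within(q2[1:2, ], { start <- c(9000, 9100); end <- c(9500, 9600) }))
  mt3 <- multi_trait(merge_unique(q3))
  expect_identical(mt3$qtl[mt3$chrom == "5"], c("qMT5-1", "qMT5-2"))
})

test_that("genome coverage uses union semantics and matches a bitmap oracle", {
  one <- data.frame(chrom = "1", start = 1, end = 25e6)
  expect_equal(genome_coverage(one, c(`1` = 100e6)), 0.25)
  expect_equal(genome_coverage(rbind(one, one), c(`1` = 100e6)), 0.25)
  expect_error(genome_coverage(data.frame(chrom = "1", start = 1, end = 2e6),
                               c(`1` = 1e6)), "exceeds")
  expect_error(genome_coverage(one, c(`2` = 1e8)), "missing chromosome")

  set.seed(33)
  lengths <- c(`1` = 1e6, `2` = 5e5)
  for (rep in 1:20) {
    k <- sample(1:15, 1)
    ch <- sample(names(lengths), k, replace = TRUE)
    st <- vapply(ch, function(c0) sample.int(lengths[[c0]] - 1e4, 1), numeric(1))
    df <- data.frame(chrom = ch, start = st,
                     end = pmin(st + sample.int(2e5, k), lengths[ch]))
    expect_equal(genome_coverage(df, lengths), oracle_coverage(df, lengths))
  }
})

test_that("legacy-QTL annotation respects the inclusive-overlap boundary", {
  qtls <- data.frame(chrom = "1", start = 10, end = 20)
  hit <- legacy_overlap(qtls, data.frame(chrom = "1", start = 15, end = 30,
                                         name = "qCTS1"))
  expect_identical(hit$legacy_hits, "qCTS1")
  touch <- legacy_overlap(qtls, data.frame(chrom = "1", start = 21, end = 30,
                                           name = "qCTS1"))
  expect_identical(touch$legacy_hits, "")
  other <- legacy_overlap(qtls, data.frame(chrom = "2", start = 10, end = 20,
                                           name = "qCTS2"))
  expect_identical(other$n_legacy, 0L)
})

test_that("published-QTL flags of the packaged table are reproduced by overlap", {
  tab <- load_table1()
  qtls <- data.frame(qtl = tab$qtl, chrom = as.character(tab$chr),
                     start = tab$start, end = tab$end)
  # synthetic legacy set: each published name is laid over its host interval
  has <- tab$published_qtl != ""
  legacy <- do.call(rbind, lapply(which(has), function(i)
    data.frame(chrom = as.character(tab$chr[i]), start = tab$start[i],
               end = tab$end[i],
               name = strsplit(tab$published_qtl[i], ";")[[1]])))
  ann <- legacy_overlap(qtls, legacy)
  expect_true(all(ann$n_legacy[has] >= 1))
  # regions that never overlap a legacy interval stay unannotated
  clean <- !has & !vapply(seq_len(nrow(tab)), function(i)
    any(has & tab$chr == tab$chr[i] & tab$start <= tab$end[i] &
          tab$end >= tab$start[i]), logical(1))
  expect_true(all(ann$n_legacy[clean] == 0))
})
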