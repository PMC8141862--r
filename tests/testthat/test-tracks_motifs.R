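test_that("bedGraph round-trips through the track reader and writer", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr14\t10\t20\t12.5", "chr14\t0\t10\t3",
               "chr14\t25\t30\t40", "chr2\t0\t5\t1"), bg)
  tr <- read_bedgraph(bg, strand = "top")
  expect_equal(nrow(tr$intervals), 4L)
  # unsorted input comes back sorted with the same interval multiset
  expect_equal(tr$intervals$start, c(0L, 10L, 25L, 0L))
  expect_equal(tr$intervals$chrom, c("chr14", "chr14", "chr14", "chr2"))

  out <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, out)
  tr2 <- read_bedgraph(out, strand = "top")
  expect_equal(tr2$intervals, tr$intervals)
})

test_that("overlapping bedGraph intervals are rejected", {
  expect_error(mismatch_track(data.frame(chrom = "c", start = c(0, 5),
                                         end = c(10, 15),
                                         value = c(1, 2))), "overlapping")
  expect_error(mismatch_track(data.frame(chrom = "c", start = 0, end = 0,
                                         value = 1)), "end > start")
  expect_error(mismatch_track(data.frame(chrom = "c", start = 0, end = 5,
                                         value = 120)), "\\[0, 100\\]")
})

test_that("BED regions round-trip with strand and inferred class", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr14\t100\t200\tIGHV3-15\t0\t+",
               "chr14\t300\t400\tSmu\t0\t-",
               "chr14\t500\t600\tCmu\t0\t-"), bed)
  r <- read_bed_regions(bed)
  expect_equal(r$region_class, c("V", "S", "C"))
  expect_equal(r$start, c(100L, 300L, 500L))
  expect_equal(r$strand, c("+", "-", "-"))
  out <- tempfile(fileext = ".bed")
  write_bed_regions(r, out)
  expect_equal(read_bed_regions(out), r)
})

test_that("observed-G4 calling thresholds and merges adjacent intervals", {
  tr <- mismatch_track(data.frame(chrom = "g", start = c(0, 5, 10, 15),
                                  end = c(5, 10, 15, 20),
                                  value = c(10, 30, 40, 5)), "top")
  g4 <- call_observed_g4(tr, threshold = 25)
  expect_equal(nrow(g4), 1L)
  expect_equal(g4$start, 5L)
  expect_equal(g4$end, 15L)
  expect_equal(g4$peak_value, 40)
  expect_equal(g4$strand, "top")

  low <- mismatch_track(data.frame(chrom = "g", start = 0, end = 10,
                                   value = 24.9), "top")
  expect_equal(nrow(call_observed_g4(low)), 0L)
})

test_that("observed-G4 calling matches position-wise brute force", {
  set.seed(31)
  for (i in 1:200) {
    iv <- random_track_intervals(sample(3:10, 1))
    tr <- mismatch_track(iv, "bottom")
    got <- call_observed_g4(tr, threshold = 25)
    want <- brute_call_g4(tr$intervals, 25)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, unname(want[, "start"]))
      expect_equal(got$end, unname(want[, "end"]))
      expect_equal(got$peak_value, unname(want[, "peak"]))
    }
  }
})

test_that("region mismatch stats weight by covered width and report gaps as missing", {
  tr <- mismatch_track(data.frame(chrom = "g", start = c(0, 10),
                                  end = c(10, 20), value = c(10, 30)), "top")
  st <- region_mismatch_stats(tr, list(chrom = "g", start = 0, end = 20))
  expect_equal(st$max, 30)
  expect_equal(st$mean, 20)
  expect_equal(st$covered, 20L)

  miss <- region_mismatch_stats(tr, list(chrom = "g", start = 50, end = 60))
  expect_true(is.na(miss$max) && is.na(miss$mean))
  expect_equal(miss$covered, 0L)

  # partial overlap weights by the clipped width
  st2 <- region_mismatch_stats(tr, list(chrom = "g", start = 5, end = 15))
  expect_equal(st2$mean, 20)
  expect_equal(st2$covered, 10L)
})

test_that("region stats are invariant under splitting an interval in half", {
  set.seed(8)
  for (i in 1:20) {
    width <- sample(2:6, 6, replace = TRUE)  # splittable widths
    gap <- sample(0:2, 6, replace = TRUE)
    start <- cumsum(c(0L, (width + gap)[-6]))
    iv <- data.frame(chrom = "chr", start = start, end = start + width,
                     value = round(runif(6, 0, 50), 1))
    tr1 <- mismatch_track(iv, "top")
    mid <- floor((iv$start[3] + iv$end[3]) / 2)
    split_iv <- rbind(iv[-3, ],
                      data.frame(chrom = iv$chrom[3], start = iv$start[3],
                                 end = mid, value = iv$value[3]),
                      data.frame(chrom = iv$chrom[3], start = mid,
                                 end = iv$end[3], value = iv$value[3]))
    tr2 <- mismatch_track(split_iv, "top")
    region <- list(chrom = iv$chrom[1], start = 0, end = max(iv$end))
    expect_equal(region_mismatch_stats(tr2, region),
                 region_mismatch_stats(tr1, region))
    expect_equal(call_observed_g4(tr2, 25)[c("start", "end", "peak_value")],
                 call_observed_g4(tr1, 25)[c("start", "end", "peak_value")])
  }
})

test_that("motif density counts overlapping occurrences per nt", {
  s <- paste0(strrep("AT", 48), "AGCT", strrep("TA", 48), "AGCT",
              strrep("AT", 48), "AGCT", strrep("TA", 48), "AGCT")
  expect_equal(nchar(s), 400L)
  expect_equal(motif_density(s, "AGCT"), 0.01)
  expect_equal(motif_density("AGCTAGCT", "AGCT"), 2 / 8)
  expect_equal(motif_density("AGAGAG", "AGA"), 2 / 6)  # overlapping counted
  expect_error(motif_density("", "AGCT"), "empty|invalid|single")
  expect_error(motif_density("ACG", "AGCT"), "longer")
})

test_that("AGCT density is strand-symmetric and stable under doubling", {
  set.seed(19)
  for (i in 1:30) {
    s <- random_dna(120)
    expect_equal(motif_density(s, "AGCT"),
                 motif_density(reverse_complement(s), "AGCT"))
  }
  s <- paste0(random_dna(100), "T")  # seam TA cannot complete AGCT
  expect_equal(motif_density(paste0(s, s), "AGCT"), motif_density(s, "AGCT"))
})

test_that("AID motif scan reports overlapping palindromic hotspots", {
  m <- scan_aid_motifs("AGCT")
  expect_equal(nrow(m), 2L)
  top <- m[m$strand == "top", ]
  bottom <- m[m$strand == "bottom", ]
  expect_equal(top$trinucleotide, "AGC")
  expect_equal(top$pos, 3L)
  expect_equal(bottom$trinucleotide, "AGC")
  expect_equal(bottom$pos, 2L)

  ccc <- scan_aid_motifs("CCC")
  expect_equal(nrow(ccc), 1L)
  expect_equal(ccc$motif_class, "SYC_coldspot")
  expect_equal(ccc$strand, "top")
  expect_equal(ccc$pos, 3L)
})

test_that("AID motif scan matches the brute-force window oracle", {
  set.seed(37)
  for (i in 1:200) {
    s <- random_dna(sample(10:60, 1))
    got <- scan_aid_motifs(s)
    want <- brute_aid_scan(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_equal(got, want, ignore_attr = TRUE, info = s)
    }
  }
})

test_that("potential/activity correlations behave at the extremes", {
  per_gene <- rbind(
    data.frame(gene = paste0("g", 1:5), strand = "top",
               potential = (1:5) / 10, max_mismatch = c(10, 20, 30, 40, 50)),
    data.frame(gene = paste0("g", 1:5), strand = "bottom",
               potential = (1:5) / 10, max_mismatch = c(50, 40, 30, 20, 10)))
  res <- correlate_potential_vs_activity(per_gene)
  expect_equal(res$correlations$rho[res$correlations$strand == "top"], 1)
  expect_equal(res$correlations$rho[res$correlations$strand == "bottom"], -1)
  expect_true(res$strand_test$p_value > 0 || is.na(res$strand_test$p_value))

  flat <- per_gene
  flat$potential <- 0.5
  res2 <- correlate_potential_vs_activity(flat)
  expect_true(all(is.na(res2$correlations$rho)))
  expect_match(res2$correlations$note[1], "undefined")

  expect_error(correlate_potential_vs_activity(per_gene[1:2, ]),
               "at least 3")
})

test_that("fold differences reproduce the printed density ratios", {
  expect_equal(round(fold_difference(9.78e-3, 3.75e-3), 1), 2.6)
  expect_equal(round(fold_difference(2e-2, 9.78e-3)), 2)
  expect_equal(fold_difference(0.5, 0.5), 1)
  expect_error(fold_difference(1, 0), "positive")
})

test_that("region activity tables combine densities and mismatch stats", {
  tr_top <- mismatch_track(data.frame(chrom = "chr", start = c(0, 10),
                                      end = c(10, 20), value = c(10, 30)),
                           "top")
  tr_bot <- mismatch_track(data.frame(chrom = "chr", start = 0, end = 20,
                                      value = 5), "bottom")
  regions <- data.frame(name = c("IGHV3-1", "Smu"), chrom = "chr",
                        start = c(0, 10), end = c(10, 20),
                        strand = "+", region_class = c("V", "S"))
  seqs <- c("IGHV3-1" = strrep("AGCT", 5), "Smu" = strrep("AT", 10))
  tab <- region_activity_table(regions, tr_top, tr_bot, seqs)
  expect_equal(tab$motif_density, c(5 / 20, 0))
  expect_equal(tab$mean_mismatch_top, c(10, 30))
  expect_equal(tab$mean_mismatch_bottom, c(5, 5))
  expect_equal(tab$max_mismatch_top, c(10, 30))
})
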