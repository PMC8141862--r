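make_reads <- function(germ, n, mutations = list()) {
  # mutations: list of list(pos, base, reads = indices)
  reads <- rep(germ, n)
  for (m in mutations) {
    for (r in m$reads) {
      substr(reads[r], m$pos, m$pos) <- m$base
    }
  }
  reads
}

test_that("alignments validate read lengths and alphabet", {
  germ <- make_allele("ACGTACGT")
  expect_error(repertoire_alignment(germ, c("ACGTACG")), "length")
  expect_error(repertoire_alignment(germ, c("ACGTACGU")), "invalid")
  aln <- repertoire_alignment(germ, c("ACGTACGT", "ACNTACGT"))
  expect_equal(aln$n_reads, 2L)
})

test_that("site frequencies count coverage and mutations per column", {
  germ <- make_allele("AAAAAAAAAA")
  reads <- make_reads(germ$ungapped_seq, 10,
                      list(list(pos = 4, base = "G", reads = 1:3)))
  aln <- repertoire_alignment(germ, reads)
  f <- site_mutation_frequencies(aln)
  expect_equal(f$frequency[4], 0.3)
  expect_equal(f$coverage, rep(10L, 10))
  expect_equal(f$mutated[4], 3L)
  expect_equal(sum(f$mutated[-4]), 0L)

  ident <- repertoire_alignment(germ, rep(germ$ungapped_seq, 5))
  expect_true(all(site_mutation_frequencies(ident)$frequency == 0))
})

test_that("N bases drop out of coverage and uncovered sites are missing", {
  germ <- make_allele("ACGT")
  aln <- repertoire_alignment(germ, c("NCGT", "NCGA", "NNGT"))
  f <- site_mutation_frequencies(aln)
  expect_equal(f$coverage, c(0L, 2L, 3L, 3L))
  expect_true(is.na(f$frequency[1]))
  expect_equal(f$frequency[4], 1 / 3)
})

test_that("site frequencies match brute-force column counting", {
  set.seed(41)
  for (i in 1:100) {
    L <- sample(5:20, 1)
    germ <- make_allele(random_dna(L))
    reads <- vapply(1:sample(3:12, 1), function(j) {
      r <- strsplit(germ$ungapped_seq, "")[[1]]
      k <- sample(L, sample(0:3, 1))
      r[k] <- sample(c("A", "C", "G", "T", "N"), length(k), replace = TRUE)
      paste(r, collapse = "")
    }, character(1))
    aln <- repertoire_alignment(germ, reads)
    got <- site_mutation_frequencies(aln)
    want <- brute_site_freq(reads, germ$ungapped_seq)
    expect_equal(got$coverage, want$coverage)
    expect_equal(got$mutated, want$mutated)
    expect_equal(got$frequency, want$frequency)
  }
})

test_that("tabular mutation-count input is accepted", {
  tab <- data.frame(position = c(2, 1), mutated = c(3, 0),
                    coverage = c(10, 8))
  f <- site_mutation_frequencies(tab)
  expect_equal(f$position, c(1L, 2L))
  expect_equal(f$frequency, c(0, 0.3))
  expect_error(site_mutation_frequencies(
    data.frame(position = 1, mutated = 9, coverage = 5)), "exceeds")
})

test_that("motif mutability averages targeted-site frequencies", {
  # two top-strand AGC sites; frequencies 0.1 and 0.3 at their C
  germ <- make_allele("TTAGCTTTAGCTTT")
  pos <- scan_aid_motifs(germ$ungapped_seq)
  agc_top <- pos[pos$trinucleotide == "AGC" & pos$strand == "top", "pos"]
  expect_equal(agc_top, c(5L, 11L))
  reads <- make_reads(germ$ungapped_seq, 10, list(
    list(pos = 5, base = "T", reads = 1),
    list(pos = 11, base = "T", reads = 1:3)))
  aln <- repertoire_alignment(germ, reads)
  mm <- motif_mutability(aln)
  row <- mm[mm$trinucleotide == "AGC" & mm$strand == "top", ]
  expect_equal(row$mean_freq, 0.2)
  expect_equal(row$n_sites, 2L)
})

test_that("reverse-complement relabeling swaps top and bottom mutability", {
  set.seed(43)
  germ <- make_allele(random_dna(60))
  reads <- vapply(1:30, function(j) {
    r <- strsplit(germ$ungapped_seq, "")[[1]]
    k <- sample(60, sample(1:4, 1))
    r[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
    paste(r, collapse = "")
  }, character(1))
  aln <- repertoire_alignment(germ, reads)
  flipped <- revcomp_alignment(aln)
  a <- motif_mutability(aln)
  b <- motif_mutability(flipped)
  for (i in seq_len(nrow(a))) {
    other <- b[b$trinucleotide == a$trinucleotide[i] &
                 b$strand == setdiff(c("top", "bottom"), a$strand[i]), ]
    expect_equal(nrow(other), 1L)
    expect_equal(other$mean_freq, a$mean_freq[i])
    expect_equal(other$n_sites, a$n_sites[i])
  }
})

test_that("planted hotspot multipliers are recovered from simulation", {
  sim <- simulate_germline_alleles(germline_sim_config(
    n_alleles = 1, g4_cassette = NULL,
    planted_motifs = list(list(motif = "TAGCT", strand = "top", count = 4)),
    seed = 51))
  allele <- sim$alleles[[1]]
  aln <- simulate_shm_repertoire(allele, shm_sim_config(
    n_reads = 2000, hotspot_multiplier = 5, seed = 52))
  freqs <- site_mutation_frequencies(aln)
  motifs <- scan_aid_motifs(allele$ungapped_seq)
  hot <- unique(motifs$pos[motifs$motif_class == "WRC_hotspot"])
  cold <- unique(motifs$pos[motifs$motif_class == "SYC_coldspot"])
  neutral <- setdiff(seq_len(nchar(allele$ungapped_seq)), c(hot, cold))
  ratio <- mean(freqs$frequency[hot]) / mean(freqs$frequency[neutral])
  expect_gt(ratio, 5 * 0.8)
  expect_lt(ratio, 5 * 1.2)
})

test_that("top-bottom mutability differences track the coupled strand", {
  set.seed(61)
  # genes with a top-strand cassette get extra top-strand hotspot
  # mutations via the coupling; uncoupled genes do not
  mutab <- list()
  scores <- list()
  for (g in 1:8) {
    carry <- g <= 4
    sim <- simulate_germline_alleles(germline_sim_config(
      n_alleles = 1, families = "IGHV3",
      g4_cassette = if (carry) list(frac_alleles = 1) else NULL,
      planted_motifs = list(list(motif = "TAGCT", strand = "top",
                                 count = 3),
                            list(motif = "TAGCT", strand = "bottom",
                                 count = 3)),
      seed = 100 + g))
    a <- sim$alleles[[1]]
    a$allele_id <- sprintf("IGHV3-%d*01", g)
    a$gene_id <- sprintf("IGHV3-%d", g)
    aln <- simulate_shm_repertoire(a, shm_sim_config(
      n_reads = 1500, g4_strand_coupling = 4, seed = 200 + g))
    mutab[[g]] <- motif_mutability(aln)
    ss <- score_both_strands(a$ungapped_seq)
    scores[[g]] <- data.frame(gene_id = a$gene_id, top = ss$top,
                              bottom = ss$bottom)
  }
  res <- topbottom_difference_vs_potential(do.call(rbind, mutab),
                                           do.call(rbind, scores),
                                           motifs = "AGC")
  r_top <- res$r[res$potential_strand == "top"]
  expect_gt(r_top, 0)
})

test_that("fewer than three genes refuses the correlation", {
  mutab <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                      trinucleotide = "AGC",
                      motif_class = "WRC_hotspot",
                      strand = c("top", "bottom", "top", "bottom"),
                      mean_freq = c(0.1, 0.05, 0.2, 0.1),
                      n_sites = 2L)
  scores <- data.frame(gene_id = c("g1", "g2"), top = c(0.5, 0.2),
                       bottom = c(0, 0))
  expect_error(topbottom_difference_vs_potential(mutab, scores,
                                                 motifs = "AGC"),
               "at least 3")
})

test_that("mutated-read potentials average to germline when unmutated", {
  germ <- make_allele(paste0("AT", "GGGAGGGTTGGGAGGG", "AT"))
  aln <- repertoire_alignment(germ, rep(germ$ungapped_seq, 4))
  res <- mutated_vs_germline_potential(aln)
  expect_equal(unname(res$mutated_mean["top"]), unname(res$germline["top"]))
  expect_equal(res$n_reads_used, 4L)

  # reads destroying the only canonical motif lower the mean
  broken <- sub("GGGAGGG", "GGAAGGG", germ$ungapped_seq)
  aln2 <- repertoire_alignment(germ, c(germ$ungapped_seq, broken, broken))
  res2 <- mutated_vs_germline_potential(aln2)
  expect_lt(res2$mutated_mean["top"], res2$germline["top"])
  # oracle: mean of per-read scores
  expect_equal(unname(res2$mutated_mean["top"]),
               mean(c(reference_g4_score(germ$ungapped_seq),
                      reference_g4_score(broken), reference_g4_score(broken))))
})

test_that("unscorable reads are skipped and counted", {
  germ <- make_allele("ACGTACGT")
  aln <- repertoire_alignment(germ, c("ACGTACGT", "ACNTACGT"))
  expect_message(res <- mutated_vs_germline_potential(aln), "skipped")
  expect_equal(res$n_reads_used, 1L)
  expect_equal(res$n_skipped, 1L)
})

test_that("CCC sites split by predicted bottom-strand impact", {
  # bottom-strand motif -> top CCC runs; plus CCC far from any motif
  germ <- make_allele(paste0("ATAT", reverse_complement("GGGAGGGTTGGGAGGG"),
                             "ATATATAT", "ACCCA", "ATAT"))
  muts <- classify_mutant_c_sites(enumerate_h_to_g(germ), germ)
  aln <- repertoire_alignment(germ, rep(germ$ungapped_seq, 5))
  res <- ccc_split_comparison(aln, muts, epsilon = 0.01)
  expect_gt(res$n_negative, 0)
  expect_gt(res$n_no_difference, 0)
  expect_true(all(res$sites$group %in% c("negative_change", "no_difference")))
  # sites with delta_bottom > +epsilon are excluded from both groups
  pos_delta <- muts[muts$trinucleotide %in% "CCC" &
                      muts$delta_bottom > 0.01, "ungapped_pos"]
  expect_false(any(res$sites$position %in% pos_delta))
})

test_that("coupled CCC coldspots show elevated mutability at planted settings", {
  sim <- simulate_germline_alleles(germline_sim_config(
    n_alleles = 1, families = "IGHV4",
    g4_cassette = list(strand = "bottom", count = 4, frac_alleles = 1),
    planted_motifs = list(list(motif = "ACCCA", strand = "top", count = 10)),
    seed = 71))
  allele <- sim$alleles[[1]]
  aln <- simulate_shm_repertoire(allele, shm_sim_config(
    n_reads = 2000, base_rate = 5e-3, g4_strand_coupling = 3, seed = 72))
  muts <- classify_mutant_c_sites(enumerate_h_to_g(allele), allele)
  res <- ccc_split_comparison(aln, muts)
  expect_gt(res$n_negative, 0)
  expect_gt(res$n_no_difference, 0)
  neg <- res$sites$frequency[res$sites$group == "negative_change"]
  nod <- res$sites$frequency[res$sites$group == "no_difference"]
  expect_gt(mean(neg), mean(nod))
  expect_lt(res$p_value, 0.05)
})

test_that("repertoire FASTA reader uses the first record as germline", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">IGHV1-1*01", "ACGTACGT",
               ">read1", "ACGTACGA", ">read2", "NCGTACGT"), fa)
  aln <- read_repertoire_fasta(fa)
  expect_equal(aln$germline$allele_id, "IGHV1-1*01")
  expect_equal(aln$n_reads, 2L)
})
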