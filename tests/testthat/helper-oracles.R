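# Brute-force oracles and fixture builders, kept deliberately independent
# of the package implementations they check.

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Reverse complement by direct character mapping (no Biostrings).
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Maximal G-runs by explicit iteration.
runs_chr <- function(s, min_run) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- NULL
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "G") {
      j <- i
      while (j < length(chars) && chars[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= min_run) out <- rbind(out, c(i, j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Canonical G4 matches by full enumeration: all 4-subsets of maximal
# G-runs with inter-run gaps in [1, max_loop]; matches selected left to
# right, non-overlapping, lexicographically earliest chain first.
brute_g4_matches <- function(s, min_run = 3L, max_loop = 7L) {
  runs <- runs_chr(s, min_run)
  if (is.null(runs) || nrow(runs) < 4L) return(NULL)
  combos <- utils::combn(nrow(runs), 4L)
  chains <- list()
  for (c_i in seq_len(ncol(combos))) {
    idx <- combos[, c_i]
    st <- runs[idx, 1L]
    en <- st + runs[idx, 2L] - 1L
    gaps <- st[-1L] - en[-4L] - 1L
    if (all(gaps >= 1L & gaps <= max_loop)) {
      chains[[length(chains) + 1L]] <- list(starts = st, ends = en)
    }
  }
  if (!length(chains)) return(NULL)
  key <- t(vapply(chains, function(ch) ch$starts, numeric(4L)))
  ord <- do.call(order, as.data.frame(key))
  chains <- chains[ord]
  selected <- list()
  cursor <- 0L
  repeat {
    ok <- which(vapply(chains, function(ch) ch$starts[1L] > cursor,
                       logical(1L)))
    if (!length(ok)) break
    ch <- chains[[ok[1L]]]
    selected[[length(selected) + 1L]] <-
      c(start0 = ch$starts[1L] - 1L, end0 = ch$ends[4L])
    cursor <- ch$ends[4L]
  }
  do.call(rbind, selected)
}

# AID motif scan by explicit window iteration over the sequence and its
# reverse complement.
brute_aid_scan <- function(s) {
  classify_window <- function(tri) {
    b <- strsplit(tri, "", fixed = TRUE)[[1L]]
    if (b[3L] != "C") return(NA_character_)
    if (b[1L] %in% c("A", "T") && b[2L] %in% c("A", "G")) return("WRC_hotspot")
    if (b[1L] %in% c("C", "G") && b[2L] %in% c("C", "T")) return("SYC_coldspot")
    NA_character_
  }
  n <- nchar(s)
  rows <- list()
  for (strand in c("top", "bottom")) {
    subj <- if (strand == "top") s else rc_chr(s)
    for (i in seq_len(n - 2L)) {
      tri <- substr(subj, i, i + 2L)
      cls <- classify_window(tri)
      if (is.na(cls)) next
      pos <- if (strand == "top") i + 2L else n - (i + 2L) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        motif_class = cls, trinucleotide = tri, strand = strand, pos = pos)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$pos, out$strand), , drop = FALSE]
}

# Observed-G4 calling by expanding a single-chrom track to per-position
# values, thresholding position-wise and merging runs of passing
# positions.
brute_call_g4 <- function(intervals, threshold) {
  n <- max(intervals$end)
  vals <- rep(NA_real_, n)
  for (i in seq_len(nrow(intervals))) {
    vals[(intervals$start[i] + 1L):intervals$end[i]] <- intervals$value[i]
  }
  pass <- !is.na(vals) & vals >= threshold
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (pass[i]) {
      j <- i
      while (j < n && pass[j + 1L]) j <- j + 1L
      out <- rbind(out, c(start = i - 1L, end = j,
                          peak = max(vals[i:j])))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Per-site mutation frequencies by explicit column counting.
brute_site_freq <- function(reads, germ) {
  L <- nchar(germ)
  gch <- strsplit(germ, "", fixed = TRUE)[[1L]]
  cov <- integer(L)
  mut <- integer(L)
  for (r in reads) {
    rch <- strsplit(r, "", fixed = TRUE)[[1L]]
    for (j in seq_len(L)) {
      if (rch[j] != "N") {
        cov[j] <- cov[j] + 1L
        if (rch[j] != gch[j]) mut[j] <- mut[j] + 1L
      }
    }
  }
  data.frame(coverage = cov, mutated = mut,
             frequency = ifelse(cov > 0L, mut / cov, NA_real_))
}

# Quick allele builder for ungapped toy sequences.
make_allele <- function(seq, id = "IGHV3-1*01", region_map = NULL) {
  ighv_allele(id, seq, region_map = region_map)
}

# Random single-chrom mismatch-track intervals with occasional gaps.
random_track_intervals <- function(n_intervals = 8L, chrom = "chr") {
  width <- sample(1:5, n_intervals, replace = TRUE)
  gap <- sample(0:2, n_intervals, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  start <- cumsum(c(0L, (width + gap)[-n_intervals]))
  data.frame(chrom = chrom, start = start, end = start + width,
             value = round(runif(n_intervals, 0, 50), 1))
}
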