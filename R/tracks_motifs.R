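#' Construct a percent-mismatch track
#'
#' A `mismatch_track` holds strand-resolved percent-mismatch intervals of
#' the kind produced by the G4-seq assay: 0-based half-open intervals with
#' a percent value in `[0, 100]`. Intervals are sorted and must not
#' overlap within a chromosome; strand is a property of the whole track
#' (the assay reports the two strands as separate files).
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `value` (percent in `[0, 100]`).
#' @param strand `"top"` or `"bottom"`.
#' @return An object of class `mismatch_track`.
#' @export
mismatch_track <- function(intervals, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  intervals <- intervals[, c("chrom", "start", "end", "value")]
  intervals$chrom <- as.character(intervals$chrom)
  if (nrow(intervals)) {
    if (any(!is.finite(intervals$value))) {
      stop("track values must be finite", call. = FALSE)
    }
    if (any(intervals$value < 0 | intervals$value > 100)) {
      stop("percent-mismatch values must lie in [0, 100]", call. = FALSE)
    }
    if (any(intervals$end <= intervals$start)) {
      stop("intervals must satisfy end > start", call. = FALSE)
    }
    intervals <- intervals[order(intervals$chrom, intervals$start), ]
    by_chrom <- split(intervals, intervals$chrom)
    for (d in by_chrom) {
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
        stop("overlapping intervals on ", d$chrom[1L], call. = FALSE)
      }
    }
    rownames(intervals) <- NULL
  }
  structure(list(strand = strand, intervals = intervals),
            class = "mismatch_track")
}

#' @export
print.mismatch_track <- function(x, ...) {
  cat("<mismatch_track> ", x$strand, " strand, ", nrow(x$intervals),
      " intervals on ", length(unique(x$intervals$chrom)),
      " sequence(s)\n", sep = "")
  invisible(x)
}

#' Read a percent-mismatch track from a bedGraph file
#'
#' Strand is not representable in bedGraph and is carried out-of-band
#' (one file per strand), matching how G4-seq tracks are distributed.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param strand `"top"` or `"bottom"`.
#' @return A [mismatch_track()].
#' @export
read_bedgraph <- function(path, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("malformed bedGraph ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  mismatch_track(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    value = gr$score), strand = strand)
}

#' Write a percent-mismatch track as bedGraph
#'
#' @param track A [mismatch_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "mismatch_track"))
  write.table(track$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read region definitions from a BED file
#'
#' Reads BED (>= 4 columns; strand from column 6 when present) into region
#' definitions. The region class (V gene, switch region, constant region)
#' is inferred from the name: names starting with `IGHV` are class `"V"`,
#' names starting with `S` class `"S"`, names starting with `C` class
#' `"C"`; anything else gets `NA` and can be set manually.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `name`, `chrom`, `start` (0-based),
#'   `end`, `strand`, `region_class`.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  nm <- if (!is.null(gr$name)) gr$name else
    paste0("region", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  out <- data.frame(
    name = nm,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    region_class = ifelse(grepl("^IGHV", nm), "V",
                          ifelse(grepl("^S", nm), "S",
                                 ifelse(grepl("^C", nm), "C",
                                        NA_character_))))
  if (any(is.na(out$region_class))) {
    message("region class could not be inferred for: ",
            paste(out$name[is.na(out$region_class)], collapse = ", "))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write region definitions to a BED file
#'
#' @param regions `data.frame` as returned by [read_bed_regions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_regions <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, name = regions$name, score = 0L,
                    strand = regions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Call observed G4 regions from a mismatch track
#'
#' An observed G4 is a maximal run of track intervals whose percent
#' mismatch meets the threshold; adjacent (zero-gap) qualifying intervals
#' are merged and the peak (maximum) value within each merged region is
#' reported. The 25% default is the calling threshold established for the
#' G4-seq assay.
#'
#' @param track A [mismatch_track()].
#' @param threshold Percent-mismatch threshold (default 25).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `peak_value`.
#' @export
call_observed_g4 <- function(track, threshold = 25) {
  stopifnot(inherits(track, "mismatch_track"))
  iv <- track$intervals[track$intervals$value >= threshold, , drop = FALSE]
  if (!nrow(iv)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      peak_value = numeric(0)))
  }
  out <- lapply(split(iv, iv$chrom), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 1L)
    hits <- IRanges::findOverlaps(ir, merged)
    peak <- tapply(d$value[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), max)
    data.frame(chrom = d$chrom[1L],
               start = BiocGenerics::start(merged) - 1L,
               end = BiocGenerics::end(merged),
               strand = track$strand,
               peak_value = as.numeric(peak))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent-mismatch statistics within a region
#'
#' Computes the maximum and the coverage-weighted mean percent mismatch
#' over track positions falling inside a region. Positions with no track
#' data are excluded from the mean (the assay reports mismatch only where
#' reads align); a region with no covered positions yields missing stats,
#' not zeros.
#'
#' @param track A [mismatch_track()].
#' @param region A list or one-row `data.frame` with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return A list with `max`, `mean` and `covered` (number of covered nt).
#' @export
region_mismatch_stats <- function(track, region) {
  stopifnot(inherits(track, "mismatch_track"))
  iv <- track$intervals
  iv <- iv[iv$chrom == region$chrom & iv$start < region$end &
             iv$end > region$start, , drop = FALSE]
  if (!nrow(iv)) {
    return(list(max = NA_real_, mean = NA_real_, covered = 0L))
  }
  w <- pmin(iv$end, region$end) - pmax(iv$start, region$start)
  list(max = max(iv$value),
       mean = sum(iv$value * w) / sum(w),
       covered = as.integer(sum(w)))
}

#' Motif density per nucleotide
#'
#' Counts possibly-overlapping occurrences of a motif and normalises by
#' the sequence length in nt.
#'
#' @param seq DNA string.
#' @param motif DNA word, e.g. `"AGCT"`.
#' @return Occurrences per nt.
#' @examples
#' motif_density(strrep("AGCTAAAATTTTCCGG", 25), "AGCT")  # 25/400
#' @export
motif_density <- function(seq, motif = "AGCT") {
  .check_dna(seq)
  .check_dna(motif, what = "motif")
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  if (nchar(motif) > nchar(seq)) {
    stop("motif longer than the sequence", call. = FALSE)
  }
  Biostrings::countPattern(motif, Biostrings::DNAString(seq)) / nchar(seq)
}

#' Scan both strands for AID hotspot and coldspot motifs
#'
#' Finds every WRC hotspot (W = A/T, R = A/G) and SYC coldspot (S = C/G,
#' Y = C/T) on both strands. Bottom-strand occurrences are reported at the
#' top-strand coordinate of the complementary G. Because AGCT is
#' palindromic, each AGCT emits two overlapping AGC hotspots, one per
#' strand.
#'
#' @param seq DNA string over `A,C,G,T` (top strand).
#' @return A `data.frame` with columns `motif_class` (`"WRC_hotspot"` /
#'   `"SYC_coldspot"`), `trinucleotide` (read on the motif's own strand),
#'   `strand`, `pos` (1-based top-strand coordinate of the targeted base).
#' @examples
#' scan_aid_motifs("AGCT")
#' @export
scan_aid_motifs <- function(seq) {
  .check_dna(seq)
  subject <- Biostrings::DNAString(seq)
  n <- nchar(seq)
  scan_one <- function(subj, pattern, cls, strand) {
    m <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
    if (!length(m)) return(NULL)
    targeted <- BiocGenerics::start(m) + 2L  # third base of the trinucleotide
    pos <- if (strand == "top") targeted else n - targeted + 1L
    data.frame(motif_class = cls,
               trinucleotide = as.character(m),
               strand = strand, pos = pos)
  }
  rc <- Biostrings::reverseComplement(subject)
  out <- rbind(scan_one(subject, "WRC", "WRC_hotspot", "top"),
               scan_one(subject, "SYC", "SYC_coldspot", "top"),
               scan_one(rc, "WRC", "WRC_hotspot", "bottom"),
               scan_one(rc, "SYC", "SYC_coldspot", "bottom"))
  if (is.null(out)) {
    return(data.frame(motif_class = character(0),
                      trinucleotide = character(0),
                      strand = character(0), pos = integer(0)))
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate predicted potential with observed G4 activity per gene
#'
#' For each strand, the Spearman correlation between per-gene predicted G4
#' potential and per-gene maximum percent mismatch; plus a two-sided
#' Mann-Whitney U test comparing the per-gene maxima between strands.
#' P-values are raw. A constant input vector yields an undefined (`NA`)
#' correlation, flagged in the `note` column.
#'
#' @param per_gene `data.frame` with columns `gene`, `strand` (`"top"` /
#'   `"bottom"`), `potential`, `max_mismatch`.
#' @return A list with `correlations` (per-strand `rho`, `p_value`, `n`,
#'   `note`) and `strand_test` (Mann-Whitney `p_value` and `n` per strand).
#' @export
correlate_potential_vs_activity <- function(per_gene) {
  stopifnot(all(c("gene", "strand", "potential", "max_mismatch") %in%
                  names(per_gene)))
  per_gene <- per_gene[stats::complete.cases(
    per_gene[, c("potential", "max_mismatch")]), , drop = FALSE]
  cors <- lapply(c("top", "bottom"), function(s) {
    d <- per_gene[per_gene$strand == s, , drop = FALSE]
    if (nrow(d) < 3L) {
      stop("need at least 3 genes with data on the ", s, " strand",
           call. = FALSE)
    }
    if (sd(d$potential) == 0 || sd(d$max_mismatch) == 0) {
      return(data.frame(strand = s, rho = NA_real_, p_value = NA_real_,
                        n = nrow(d), note = "undefined: constant input"))
    }
    ct <- suppressWarnings(cor.test(d$potential, d$max_mismatch,
                                    method = "spearman", exact = FALSE))
    data.frame(strand = s, rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d), note = "")
  })
  top <- per_gene$max_mismatch[per_gene$strand == "top"]
  bottom <- per_gene$max_mismatch[per_gene$strand == "bottom"]
  st <- suppressWarnings(wilcox.test(top, bottom,
                                     alternative = "two.sided",
                                     exact = FALSE))
  list(correlations = do.call(rbind, cors),
       strand_test = list(p_value = .safe_p(st$p.value),
                          n_top = length(top), n_bottom = length(bottom)))
}

#' Fold difference between two densities
#'
#' @param d1,d2 Densities (per-nt motif counts); `d2` must be positive.
#' @return `d1 / d2`.
#' @examples
#' fold_difference(9.78e-3, 3.75e-3)  # ~2.6
#' @export
fold_difference <- function(d1, d2) {
  if (!is.finite(d2) || d2 <= 0) {
    stop("denominator density must be positive", call. = FALSE)
  }
  d1 / d2
}

#' Region activity table: motif density and mismatch statistics
#'
#' For each region, counts the motif density in the region's sequence and
#' summarises per-strand mean and maximum percent mismatch from the
#' supplied tracks.
#'
#' @param regions `data.frame` as from [read_bed_regions()].
#' @param track_top,track_bottom [mismatch_track()] objects per strand.
#' @param seqs Named character vector of region sequences (names matching
#'   `regions$name`); may be `NULL` to skip densities.
#' @param motif Motif for the density column (default `"AGCT"`).
#' @return A `data.frame` with one row per region: `name`, `region_class`,
#'   `motif_density`, `mean_mismatch_top`, `max_mismatch_top`,
#'   `mean_mismatch_bottom`, `max_mismatch_bottom`.
#' @export
region_activity_table <- function(regions, track_top, track_bottom,
                                  seqs = NULL, motif = "AGCT") {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    st <- region_mismatch_stats(track_top, r)
    sb <- region_mismatch_stats(track_bottom, r)
    dens <- if (!is.null(seqs) && r$name %in% names(seqs)) {
      motif_density(seqs[[r$name]], motif)
    } else NA_real_
    data.frame(name = r$name, region_class = r$region_class,
               motif_density = dens,
               mean_mismatch_top = st$mean, max_mismatch_top = st$max,
               mean_mismatch_bottom = sb$mean, max_mismatch_bottom = sb$max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
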