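#' Construct a substitution-only repertoire alignment
#'
#' Bundles a germline allele with mutated reads pre-aligned to it. Every
#' read must have the same length as the germline ungapped sequence and
#' use the alphabet `A,C,G,T,N`, with `N` marking positions not covered by
#' the read. Indel-containing reads are not representable and must be
#' resolved upstream.
#'
#' @param germline An [ighv_allele()].
#' @param reads Character vector of aligned reads.
#' @return An object of class `repertoire_alignment`.
#' @export
repertoire_alignment <- function(germline, reads) {
  stopifnot(inherits(germline, "ighv_allele"), is.character(reads),
            length(reads) > 0L)
  L <- nchar(germline$ungapped_seq)
  reads <- toupper(reads)
  bad_len <- which(nchar(reads) != L)
  if (length(bad_len)) {
    stop("read(s) ", paste(utils::head(bad_len, 5L), collapse = ", "),
         " do not match the germline length (", L, " nt); ",
         "only substitution-only alignments are supported", call. = FALSE)
  }
  for (i in seq_along(reads)) {
    .check_dna(reads[i], allow_n = TRUE, what = paste0("read ", i))
  }
  structure(list(germline = germline, reads = reads,
                 n_reads = length(reads)),
            class = "repertoire_alignment")
}

#' @export
print.repertoire_alignment <- function(x, ...) {
  cat("<repertoire_alignment> ", x$n_reads, " reads aligned to ",
      x$germline$allele_id, " (", nchar(x$germline$ungapped_seq),
      " nt)\n", sep = "")
  invisible(x)
}

#' Read an aligned repertoire from FASTA (first record = germline)
#'
#' @param path Path to a FASTA file whose first record is the germline
#'   allele and remaining records are aligned reads.
#' @return A [repertoire_alignment()].
#' @export
read_repertoire_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) {
    stop("repertoire FASTA needs a germline plus at least one read",
         call. = FALSE)
  }
  germ <- ighv_allele(strsplit(trimws(names(set)[1L]), "[ \t|]+")[[1L]][1L],
                      as.character(set[[1L]]))
  repertoire_alignment(germ, as.character(set[-1L]))
}

.read_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$reads, "", fixed = TRUE), use.names = FALSE),
         nrow = aln$n_reads, byrow = TRUE)
}

#' Per-site coverage, mutation counts and frequencies
#'
#' For every germline position: coverage is the number of reads with a
#' non-N base, the mutated count is the number of covering reads whose
#' base differs from germline, and the frequency their ratio (missing at
#' zero coverage).
#'
#' @param aln A [repertoire_alignment()], or a `data.frame` with columns
#'   `position`, `mutated`, `coverage` (the tabular input for
#'   privacy-reduced datasets).
#' @return A `data.frame` with columns `position`, `ref` (where known),
#'   `coverage`, `mutated`, `frequency`.
#' @export
site_mutation_frequencies <- function(aln) {
  if (is.data.frame(aln)) {
    stopifnot(all(c("position", "mutated", "coverage") %in% names(aln)))
    if (any(aln$mutated > aln$coverage)) {
      stop("mutated count exceeds coverage", call. = FALSE)
    }
    out <- data.frame(position = as.integer(aln$position),
                      ref = if ("ref" %in% names(aln)) aln$ref else
                        NA_character_,
                      coverage = as.integer(aln$coverage),
                      mutated = as.integer(aln$mutated))
    out$frequency <- ifelse(out$coverage > 0L, out$mutated / out$coverage,
                            NA_real_)
    return(out[order(out$position), , drop = FALSE])
  }
  stopifnot(inherits(aln, "repertoire_alignment"))
  M <- .read_matrix(aln)
  germ <- strsplit(aln$germline$ungapped_seq, "", fixed = TRUE)[[1L]]
  covered <- M != "N"
  coverage <- colSums(covered)
  mutated <- colSums(covered & (M != matrix(germ, nrow = nrow(M),
                                            ncol = ncol(M), byrow = TRUE)))
  data.frame(position = seq_along(germ), ref = germ,
             coverage = as.integer(coverage), mutated = as.integer(mutated),
             frequency = ifelse(coverage > 0L, mutated / coverage, NA_real_))
}

#' Per-motif, per-strand mean mutation frequency
#'
#' Averages the per-site mutation frequency of the targeted base over the
#' occurrences of each AID motif (trinucleotide) on each strand.
#' Bottom-strand motifs are located at the top-strand coordinate of the
#' complementary base. Motifs without occurrences are simply absent from
#' the table.
#'
#' @param aln A [repertoire_alignment()].
#' @param motifs Optional motif scan (as from [scan_aid_motifs()] on the
#'   germline ungapped sequence); computed when `NULL`.
#' @return A `data.frame` with columns `gene_id`, `trinucleotide`,
#'   `motif_class`, `strand`, `mean_freq`, `n_sites`.
#' @export
motif_mutability <- function(aln, motifs = NULL) {
  stopifnot(inherits(aln, "repertoire_alignment"))
  if (is.null(motifs)) motifs <- scan_aid_motifs(aln$germline$ungapped_seq)
  freqs <- site_mutation_frequencies(aln)
  motifs$frequency <- freqs$frequency[motifs$pos]
  motifs <- motifs[!is.na(motifs$frequency), , drop = FALSE]
  if (!nrow(motifs)) {
    return(data.frame(gene_id = character(0), trinucleotide = character(0),
                      motif_class = character(0), strand = character(0),
                      mean_freq = numeric(0), n_sites = integer(0)))
  }
  groups <- split(motifs, list(motifs$trinucleotide, motifs$strand),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(d) {
    data.frame(gene_id = aln$germline$gene_id,
               trinucleotide = d$trinucleotide[1L],
               motif_class = d$motif_class[1L],
               strand = d$strand[1L],
               mean_freq = mean(d$frequency),
               n_sites = nrow(d))
  }))
  out <- out[order(out$trinucleotide, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate top-bottom mutability difference with G4 potential
#'
#' For each gene, the difference between the mean mutation frequencies of
#' a hotspot motif on the two strands (top minus bottom) is compared to
#' the gene's predicted G4 potential: a Pearson correlation is computed
#' per motif and per potential strand. At least 3 genes with both strands
#' of the motif and a potential are required.
#'
#' @param mutab Row-bound [motif_mutability()] tables across genes.
#' @param scores `data.frame` with columns `gene_id`, `top`, `bottom`
#'   (per-gene G4 potential per strand).
#' @param motifs Trinucleotides to analyse (default the four WRC
#'   hotspots).
#' @return A `data.frame` with `trinucleotide`, `potential_strand`, `r`,
#'   `p_value`, `n`, `note` (flagging undefined correlations).
#' @export
topbottom_difference_vs_potential <- function(mutab, scores,
                                              motifs = c("AAC", "AGC",
                                                         "TAC", "TGC")) {
  stopifnot(all(c("gene_id", "trinucleotide", "strand", "mean_freq") %in%
                  names(mutab)),
            all(c("gene_id", "top", "bottom") %in% names(scores)))
  rows <- list()
  for (tri in motifs) {
    sub <- mutab[mutab$trinucleotide == tri, , drop = FALSE]
    wide <- merge(sub[sub$strand == "top", c("gene_id", "mean_freq")],
                  sub[sub$strand == "bottom", c("gene_id", "mean_freq")],
                  by = "gene_id", suffixes = c("_top", "_bottom"))
    wide <- merge(wide, scores, by = "gene_id")
    if (nrow(wide) < 3L) {
      stop("need at least 3 genes with both strands of ", tri,
           " and a potential; got ", nrow(wide), call. = FALSE)
    }
    diff <- wide$mean_freq_top - wide$mean_freq_bottom
    for (ps in c("top", "bottom")) {
      pot <- wide[[ps]]
      if (sd(diff) == 0 || sd(pot) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          trinucleotide = tri, potential_strand = ps, r = NA_real_,
          p_value = NA_real_, n = nrow(wide),
          note = "undefined: constant input")
        next
      }
      ct <- cor.test(diff, pot, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        trinucleotide = tri, potential_strand = ps,
        r = unname(ct$estimate), p_value = ct$p.value, n = nrow(wide),
        note = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean mutated-read G4 potential versus germline
#'
#' Scores every read on both strands and compares the mean to the
#' germline potential. Reads the scorer cannot handle (e.g. containing N)
#' are skipped and counted.
#'
#' @param aln A [repertoire_alignment()].
#' @param scorer A [g4_scorer()].
#' @return A list with `germline` (named top/bottom scores),
#'   `mutated_mean` (named means over scored reads), `n_reads_used`,
#'   `n_skipped`.
#' @export
mutated_vs_germline_potential <- function(aln,
                                          scorer = reference_g4_scorer()) {
  stopifnot(inherits(aln, "repertoire_alignment"))
  germ <- score_both_strands(aln$germline$ungapped_seq, scorer,
                             id = aln$germline$allele_id)
  tops <- numeric(0)
  bottoms <- numeric(0)
  skipped <- 0L
  for (r in aln$reads) {
    ss <- tryCatch(score_both_strands(r, scorer), error = function(e) NULL)
    if (is.null(ss)) {
      skipped <- skipped + 1L
    } else {
      tops <- c(tops, ss$top)
      bottoms <- c(bottoms, ss$bottom)
    }
  }
  if (skipped > 0L) {
    message(skipped, " read(s) skipped (unscorable)")
  }
  list(germline = c(top = germ$top, bottom = germ$bottom),
       mutated_mean = c(top = mean(tops), bottom = mean(bottoms)),
       n_reads_used = length(tops), n_skipped = skipped)
}

#' Compare mutability of CCC coldspots by their predicted G4 impact
#'
#' Splits top-strand CCC coldspot sites into those whose mutation is
#' predicted to leave the bottom-strand G4 potential unchanged
#' (`|delta_bottom| <= epsilon`, "no difference") and those predicted to
#' decrease it (`delta_bottom < -epsilon`, "negative change"; sites with
#' `delta_bottom > epsilon` are excluded), then compares the observed
#' per-site mutation frequencies of the two groups with a two-sided
#' Mann-Whitney U test (raw p).
#'
#' @param aln A [repertoire_alignment()].
#' @param mutants Classified C-site mutants from
#'   [classify_mutant_c_sites()] for the same allele.
#' @param epsilon "No difference" threshold on the score scale (default
#'   0.01).
#' @return A list with `sites` (`position`, `group`, `delta_bottom`,
#'   `frequency`), `p_value` (`NA` with a message when either group is
#'   empty), `n_negative`, `n_no_difference`.
#' @export
ccc_split_comparison <- function(aln, mutants, epsilon = 0.01) {
  stopifnot(inherits(aln, "repertoire_alignment"),
            all(c("trinucleotide", "strand_mutated", "delta_bottom") %in%
                  names(mutants)))
  ccc <- mutants[!is.na(mutants$trinucleotide) &
                   mutants$trinucleotide == "CCC" &
                   mutants$strand_mutated == "top", , drop = FALSE]
  if (!nrow(ccc)) stop("no top-strand CCC coldspot mutants supplied",
                       call. = FALSE)
  group <- ifelse(ccc$delta_bottom < -epsilon, "negative_change",
                  ifelse(abs(ccc$delta_bottom) <= epsilon, "no_difference",
                         NA_character_))
  keep <- !is.na(group)
  freqs <- site_mutation_frequencies(aln)
  sites <- data.frame(position = ccc$ungapped_pos[keep],
                      group = group[keep],
                      delta_bottom = ccc$delta_bottom[keep],
                      frequency = freqs$frequency[ccc$ungapped_pos[keep]])
  neg <- sites$frequency[sites$group == "negative_change"]
  nod <- sites$frequency[sites$group == "no_difference"]
  p <- NA_real_
  if (!length(neg) || !length(nod)) {
    message("one of the CCC groups is empty; comparison skipped")
  } else {
    p <- .safe_p(suppressWarnings(
      wilcox.test(neg, nod, alternative = "two.sided",
                  exact = FALSE))$p.value)
  }
  list(sites = sites, p_value = p,
       n_negative = length(neg), n_no_difference = length(nod))
}

#' Reverse-complement an entire repertoire alignment
#'
#' Relabels the germline and every read by reverse complement, swapping
#' the roles of the two strands (used for strand-symmetry checks).
#'
#' @param aln A [repertoire_alignment()].
#' @return A [repertoire_alignment()] on the opposite strand.
#' @export
revcomp_alignment <- function(aln) {
  stopifnot(inherits(aln, "repertoire_alignment"))
  germ <- ighv_allele(aln$germline$allele_id,
                      reverse_complement(aln$germline$ungapped_seq))
  repertoire_alignment(germ, vapply(aln$reads, reverse_complement,
                                    character(1L), USE.NAMES = FALSE))
}
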