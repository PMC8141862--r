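
# Normal-approximation Mann-Whitney/Wilcoxon p is NaN when every value is
# tied; report NA (undefined) in that case.
.safe_p <- function(p) if (is.nan(p)) NA_real_ else p

.substitute_base <- function(seq, pos, alt) {
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + 1L, nchar(seq)))
}

.mutant_row <- function(allele, pos, ref, alt, strand_mutated,
                        score_top, score_bottom, germ) {
  data.frame(
    allele_id = allele$allele_id,
    ungapped_pos = pos,
    gapped_pos = ungapped_to_gapped(allele, pos),
    ref_base = ref, alt_base = alt,
    strand_mutated = strand_mutated,
    score_top = score_top, score_bottom = score_bottom,
    delta_top = score_top - germ$top,
    delta_bottom = score_bottom - germ$bottom,
    region = region_at(allele, pos)
  )
}

#' Score a single point substitution
#'
#' Applies one substitution to the allele's ungapped sequence and scores
#' the mutated sequence on both strands.
#'
#' @param allele An [ighv_allele()].
#' @param pos 1-based ungapped position.
#' @param alt Replacement base.
#' @param scorer A [g4_scorer()].
#' @return A one-row mutant `data.frame` (see [enumerate_h_to_g()]).
#' @export
mutate_and_score <- function(allele, pos, alt, scorer = reference_g4_scorer()) {
  stopifnot(inherits(allele, "ighv_allele"), alt %in% DNA_BASES)
  seq <- allele$ungapped_seq
  if (pos < 1L || pos > nchar(seq)) {
    stop("position ", pos, " outside sequence of ", sQuote(allele$allele_id),
         call. = FALSE)
  }
  ref <- substr(seq, pos, pos)
  if (ref == alt) stop("alt base equals the germline base at position ", pos,
                       call. = FALSE)
  germ <- score_both_strands(seq, scorer, id = allele$allele_id)
  mut <- .substitute_base(seq, pos, alt)
  ss <- tryCatch(score_both_strands(mut, scorer),
                 error = function(e)
                   stop("scoring failed for ", sQuote(allele$allele_id),
                        " at position ", pos, ": ", conditionMessage(e),
                        call. = FALSE))
  .mutant_row(allele, pos, ref, alt,
              strand_mutated = switch(ref, C = "top", G = "bottom",
                                      NA_character_),
              ss$top, ss$bottom, germ)
}

#' Enumerate all single H-to-G substitutions
#'
#' The "gain a G" in-silico experiment: one mutant per non-G position
#' (H = A/C/T), each scored on both strands against the germline. AID acts
#' on cytosines, so `strand_mutated` is `"top"` where the germline base is
#' C, and `NA` for A/T sites.
#'
#' @param allele An [ighv_allele()].
#' @param scorer A [g4_scorer()].
#' @return A `data.frame`, one row per non-G position, with columns
#'   `allele_id`, `ungapped_pos`, `gapped_pos`, `ref_base`, `alt_base`,
#'   `strand_mutated`, `score_top`, `score_bottom`, `delta_top`,
#'   `delta_bottom`, `region`.
#' @export
enumerate_h_to_g <- function(allele, scorer = reference_g4_scorer()) {
  stopifnot(inherits(allele, "ighv_allele"))
  seq <- allele$ungapped_seq
  germ <- score_both_strands(seq, scorer, id = allele$allele_id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  positions <- which(chars != "G")
  rows <- lapply(positions, function(p) {
    mut <- .substitute_base(seq, p, "G")
    ss <- tryCatch(score_both_strands(mut, scorer),
                   error = function(e)
                     stop("scoring failed for ", sQuote(allele$allele_id),
                          " at position ", p, ": ", conditionMessage(e),
                          call. = FALSE))
    .mutant_row(allele, p, chars[p], "G",
                strand_mutated = if (chars[p] == "C") "top" else NA_character_,
                ss$top, ss$bottom, germ)
  })
  if (!length(rows)) return(.empty_mutant_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate averaged G-to-H substitutions
#'
#' The "lose a G" experiment: for every G position, the three mutational
#' outcomes (G>A, G>C, G>T) are scored separately and averaged into one
#' record (`alt_base = "avg(G>H)"`), whose delta is the mean mutated score
#' minus the germline score. A germline G is a C on the bottom strand, so
#' `strand_mutated` is `"bottom"`.
#'
#' @param allele An [ighv_allele()].
#' @param scorer A [g4_scorer()].
#' @return A `data.frame` with the same columns as [enumerate_h_to_g()],
#'   one row per G position.
#' @export
enumerate_g_to_h <- function(allele, scorer = reference_g4_scorer()) {
  stopifnot(inherits(allele, "ighv_allele"))
  seq <- allele$ungapped_seq
  germ <- score_both_strands(seq, scorer, id = allele$allele_id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  positions <- which(chars == "G")
  rows <- lapply(positions, function(p) {
    scores <- vapply(c("A", "C", "T"), function(alt) {
      mut <- .substitute_base(seq, p, alt)
      ss <- tryCatch(score_both_strands(mut, scorer),
                     error = function(e)
                       stop("scoring failed for ", sQuote(allele$allele_id),
                            " at position ", p, ": ", conditionMessage(e),
                            call. = FALSE))
      c(ss$top, ss$bottom)
    }, numeric(2L))
    .mutant_row(allele, p, "G", "avg(G>H)", strand_mutated = "bottom",
                mean(scores[1L, ]), mean(scores[2L, ]), germ)
  })
  if (!length(rows)) return(.empty_mutant_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_mutant_table <- function() {
  data.frame(allele_id = character(0), ungapped_pos = integer(0),
             gapped_pos = integer(0), ref_base = character(0),
             alt_base = character(0), strand_mutated = character(0),
             score_top = numeric(0), score_bottom = numeric(0),
             delta_top = numeric(0), delta_bottom = numeric(0),
             region = character(0))
}

#' Classify a cytosine site into AID hotspot/coldspot/neutral
#'
#' Classifies the trinucleotide context of a C from the two bases 5' of it
#' on the strand where the C lives: WRC (W = A/T, R = A/G) is a hotspot,
#' SYC (S = C/G, Y = C/T) a coldspot, anything else a neutral C. For the
#' bottom strand, `pos` is the top-strand coordinate of the complementary
#' G and the context is read off the reverse complement. Cs with fewer
#' than two 5' context bases are neutral by convention.
#'
#' @param seq DNA string over `A,C,G,T` (top strand as written).
#' @param pos 1-based top-strand position of the targeted base.
#' @param strand `"top"` or `"bottom"`.
#' @return A list with `site_class` (`"WRC_hotspot"`, `"SYC_coldspot"` or
#'   `"neutral_C"`) and `trinucleotide` (the context on the strand of the
#'   C; `NA` when truncated by a sequence boundary).
#' @examples
#' classify_c_site("ATGC", 4, "top")  # TGC -> WRC hotspot
#' @export
classify_c_site <- function(seq, pos, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  .check_dna(seq)
  n <- nchar(seq)
  if (pos < 1L || pos > n) stop("position out of range", call. = FALSE)
  base <- substr(seq, pos, pos)
  if (strand == "top") {
    if (base != "C") {
      stop("base at position ", pos, " on the top strand is ", base,
           ", not C", call. = FALSE)
    }
    if (pos < 3L) {
      return(list(site_class = "neutral_C", trinucleotide = NA_character_))
    }
    tri <- substr(seq, pos - 2L, pos)
  } else {
    if (base != "G") {
      stop("base at position ", pos, " is ", base,
           ", not C on the bottom strand", call. = FALSE)
    }
    if (pos > n - 2L) {
      return(list(site_class = "neutral_C", trinucleotide = NA_character_))
    }
    tri <- reverse_complement(substr(seq, pos, pos + 2L))
  }
  b1 <- substr(tri, 1L, 1L)
  b2 <- substr(tri, 2L, 2L)
  cls <- if (b1 %in% c("A", "T") && b2 %in% c("A", "G")) {
    "WRC_hotspot"
  } else if (b1 %in% c("C", "G") && b2 %in% c("C", "T")) {
    "SYC_coldspot"
  } else {
    "neutral_C"
  }
  list(site_class = cls, trinucleotide = tri)
}

#' Restrict a mutant table to classified C sites
#'
#' Keeps mutants whose germline base is a C on either strand (top-strand
#' C, or top-strand G = bottom-strand C) and annotates each with its AID
#' site class and trinucleotide context on the mutated strand.
#'
#' @param mutants Mutant `data.frame` from [enumerate_h_to_g()] and/or
#'   [enumerate_g_to_h()].
#' @param allele The [ighv_allele()] the mutants came from.
#' @return The filtered `data.frame` with added `site_class` and
#'   `trinucleotide` columns.
#' @export
classify_mutant_c_sites <- function(mutants, allele) {
  stopifnot(inherits(allele, "ighv_allele"))
  keep <- mutants$ref_base %in% c("C", "G")
  sub <- mutants[keep, , drop = FALSE]
  if (!nrow(sub)) {
    sub$site_class <- character(0)
    sub$trinucleotide <- character(0)
    return(sub)
  }
  info <- lapply(seq_len(nrow(sub)), function(i) {
    classify_c_site(allele$ungapped_seq, sub$ungapped_pos[i],
                    if (sub$ref_base[i] == "C") "top" else "bottom")
  })
  sub$site_class <- vapply(info, `[[`, character(1L), "site_class")
  sub$trinucleotide <- vapply(info, `[[`, character(1L), "trinucleotide")
  rownames(sub) <- NULL
  sub
}

.affected_delta <- function(mutants, strand_affected) {
  same <- mutants$strand_mutated == "top"
  if (strand_affected == "same") {
    ifelse(same, mutants$delta_top, mutants$delta_bottom)
  } else {
    ifelse(same, mutants$delta_bottom, mutants$delta_top)
  }
}

#' Strand-resolved effect summary over classified C-site mutants
#'
#' Groups C-site mutant deltas into the site-class (hotspot / coldspot /
#' neutral) by strand-mutated by strand-affected grid. Each mutant
#' contributes its delta on the mutated strand to the `same` cell and its
#' delta on the other strand to the `opposite` cell. Within each
#' (strand_mutated, strand_affected) group, pairwise two-sided
#' Mann-Whitney U tests compare the three site classes; p-values are raw.
#'
#' @param mutants Classified mutants from [classify_mutant_c_sites()].
#' @param epsilon Score-scale threshold below which a delta counts as "no
#'   effect" in the reported `prop_no_effect` (default 0.01).
#' @return A list with `cells` (a `data.frame` with `site_class`,
#'   `strand_mutated`, `strand_affected`, `n`, `mean_delta`, `sd_delta`,
#'   `prop_no_effect`, and a `deltas` list column) and `tests` (pairwise
#'   Mann-Whitney results with raw `p_value`; tests involving an empty
#'   class are skipped).
#' @export
strand_effect_summary <- function(mutants, epsilon = 0.01) {
  stopifnot(all(c("site_class", "strand_mutated") %in% names(mutants)))
  mutants <- mutants[!is.na(mutants$strand_mutated), , drop = FALSE]
  classes <- c("WRC_hotspot", "SYC_coldspot", "neutral_C")
  grid <- expand.grid(site_class = classes,
                      strand_mutated = c("top", "bottom"),
                      strand_affected = c("same", "opposite"),
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- mutants$site_class == g$site_class &
      mutants$strand_mutated == g$strand_mutated
    d <- .affected_delta(mutants[sel, , drop = FALSE], g$strand_affected)
    data.frame(g, n = length(d),
               mean_delta = if (length(d)) mean(d) else NA_real_,
               sd_delta = if (length(d) > 1L) sd(d) else
                 if (length(d) == 1L) 0 else NA_real_,
               prop_no_effect = if (length(d)) mean(abs(d) <= epsilon)
                 else NA_real_,
               deltas = I(list(d)))
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  pairs <- utils::combn(classes, 2L)
  tests <- list()
  for (sm in c("top", "bottom")) {
    for (sa in c("same", "opposite")) {
      for (j in seq_len(ncol(pairs))) {
        da <- cells$deltas[[which(cells$site_class == pairs[1L, j] &
                                    cells$strand_mutated == sm &
                                    cells$strand_affected == sa)]]
        db <- cells$deltas[[which(cells$site_class == pairs[2L, j] &
                                    cells$strand_mutated == sm &
                                    cells$strand_affected == sa)]]
        if (!length(da) || !length(db)) next
        p <- .safe_p(suppressWarnings(
          wilcox.test(da, db, alternative = "two.sided",
                      exact = FALSE))$p.value)
        tests[[length(tests) + 1L]] <- data.frame(
          strand_mutated = sm, strand_affected = sa,
          class_a = pairs[1L, j], class_b = pairs[2L, j],
          n_a = length(da), n_b = length(db), p_value = p)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(strand_mutated = character(0), strand_affected = character(0),
               class_a = character(0), class_b = character(0),
               n_a = integer(0), n_b = integer(0), p_value = numeric(0))
  rownames(tests) <- NULL
  list(cells = cells, tests = tests)
}

#' Mean G4 potential change per trinucleotide motif
#'
#' Summarises classified C-site mutant deltas per trinucleotide context
#' (e.g. AAC, AGC, TAC, TGC hotspots and CCC, CTC, GCC, GTC coldspots),
#' per mutated strand and per affected strand. Optionally adds a raw
#' one-sample two-sided Wilcoxon p-value against zero.
#'
#' @param mutants Classified mutants from [classify_mutant_c_sites()].
#' @param wilcoxon Add a one-sample Wilcoxon test per row (default FALSE).
#' @return A `data.frame` with `trinucleotide`, `site_class`,
#'   `strand_mutated`, `strand_affected`, `n`, `mean_delta`, `sd_delta`
#'   (and `p_value` when requested). Motifs without occurrences are simply
#'   absent.
#' @export
per_trinucleotide_delta <- function(mutants, wilcoxon = FALSE) {
  stopifnot(all(c("site_class", "trinucleotide") %in% names(mutants)))
  mutants <- mutants[!is.na(mutants$trinucleotide) &
                       !is.na(mutants$strand_mutated), , drop = FALSE]
  rows <- list()
  for (tri in sort(unique(mutants$trinucleotide))) {
    for (sm in c("top", "bottom")) {
      sel <- mutants$trinucleotide == tri & mutants$strand_mutated == sm
      if (!any(sel)) next
      sub <- mutants[sel, , drop = FALSE]
      for (sa in c("same", "opposite")) {
        d <- .affected_delta(sub, sa)
        row <- data.frame(trinucleotide = tri,
                          site_class = sub$site_class[1L],
                          strand_mutated = sm, strand_affected = sa,
                          n = length(d), mean_delta = mean(d),
                          sd_delta = if (length(d) > 1L) sd(d) else 0)
        if (wilcoxon) {
          row$p_value <- if (all(d == 0)) NA_real_ else .safe_p(
            suppressWarnings(wilcox.test(d, mu = 0,
                                         alternative = "two.sided",
                                         exact = FALSE))$p.value)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-position mutation effect profile with FW/CDR annotation
#'
#' Joins single-mutation records to gapped (IMGT) positions and annotates
#' each with its framework/CDR region, supporting per-position plots of
#' mutated-sequence potential and the robustness census (the fraction of
#' positions whose potential stays within a tolerance of germline).
#'
#' @param mutants Mutant `data.frame` covering the allele (typically
#'   `rbind(enumerate_h_to_g(...), enumerate_g_to_h(...))`).
#' @param allele The [ighv_allele()] the mutants came from.
#' @return The mutant table ordered by position, with `region` re-derived
#'   from the allele's region map (`"unassigned"` outside it).
#' @export
delta_profile_by_position <- function(mutants, allele) {
  stopifnot(inherits(allele, "ighv_allele"))
  out <- mutants[order(mutants$ungapped_pos), , drop = FALSE]
  out$region <- region_at(allele, out$ungapped_pos)
  rownames(out) <- NULL
  out
}

#' Fraction of mutations leaving the G4 potential near germline
#'
#' @param mutants Mutant `data.frame`.
#' @param tol Tolerance on the score scale (default 0.1).
#' @return Named list with the fraction of records whose `delta_top`,
#'   `delta_bottom`, and both, stay within `tol` in absolute value.
#' @export
g4_robustness <- function(mutants, tol = 0.1) {
  list(frac_top = mean(abs(mutants$delta_top) <= tol),
       frac_bottom = mean(abs(mutants$delta_bottom) <= tol),
       frac_both = mean(abs(mutants$delta_top) <= tol &
                          abs(mutants$delta_bottom) <= tol))
}
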