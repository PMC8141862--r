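#' Pluggable G4 scorer contract
#'
#' A `g4_scorer` wraps any function mapping a DNA string to a potential in
#' `[0, 1]`. Built-in scoring uses [reference_g4_scorer()]; an external
#' learned model (e.g. a CNN accessed out of process) can be plugged in by
#' supplying its scoring function here, optionally with an input `width`
#' and `base_order` the adapter uses to build one-hot inputs.
#'
#' @param name Scorer name, recorded in all outputs.
#' @param score_fun Function of one DNA string returning a single number in
#'   `[0, 1]`.
#' @param deterministic Logical flag recorded on the object.
#' @return An object of class `g4_scorer`.
#' @export
g4_scorer <- function(name, score_fun, deterministic = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(score_fun))
  structure(list(name = name, score_fun = score_fun,
                 deterministic = isTRUE(deterministic)),
            class = "g4_scorer")
}

#' @export
print.g4_scorer <- function(x, ...) {
  cat("<g4_scorer> ", x$name,
      if (x$deterministic) " (deterministic)" else " (stochastic)", "\n",
      sep = "")
  invisible(x)
}

#' Score one sequence with a scorer, validating the contract
#'
#' @param scorer A [g4_scorer()].
#' @param seq DNA string over `A,C,G,T`.
#' @return A number in `[0, 1]`.
#' @export
score_sequence <- function(scorer, seq) {
  stopifnot(inherits(scorer, "g4_scorer"))
  .check_dna(seq)
  val <- scorer$score_fun(seq)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
    stop("scorer ", sQuote(scorer$name),
         " returned a non-finite or non-scalar value", call. = FALSE)
  }
  if (val < 0 || val > 1) {
    stop("scorer ", sQuote(scorer$name), " returned ", val,
         ", outside [0, 1]", call. = FALSE)
  }
  val
}

# Maximal G-runs of length >= min_run as (start, length), 1-based starts.
.g_runs <- function(seq, min_run) {
  m <- gregexpr("G+", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(matrix(integer(0), ncol = 2L))
  len <- attr(m, "match.length")
  keep <- len >= min_run
  cbind(start = as.integer(m[keep]), length = len[keep])
}

# Depth-first search for the lexicographically smallest chain of
# `needed` runs starting at or after run index `from`, with inter-run
# gaps in [1, max_loop]. Returns run indices or NULL.
.chain_search <- function(runs, from, needed, max_loop) {
  recurse <- function(prev_idx, left) {
    if (left == 0L) return(integer(0))
    prev_end <- runs[prev_idx, 1L] + runs[prev_idx, 2L]  # one past run end
    for (j in seq_len(nrow(runs))) {
      if (runs[j, 1L] <= prev_end) next
      gap <- runs[j, 1L] - prev_end
      if (gap > max_loop) next  # runs sorted by start, but later runs may
                                # still start earlier-ending? no: starts
                                # ascend, so once gap > max_loop for the
                                # nearest, larger j only grows it
      rest <- recurse(j, left - 1L)
      if (!is.null(rest)) return(c(j, rest))
    }
    NULL
  }
  for (i in from:nrow(runs)) {
    rest <- recurse(i, needed - 1L)
    if (!is.null(rest)) return(c(i, rest))
  }
  NULL
}

#' Find canonical G-quadruplex motifs
#'
#' Scans for the canonical quadruplex consensus: four G-runs of length at
#' least `min_run`, separated by loops of 1 to `max_loop` nt. G-runs are
#' maximal (greedily extended) and matches are selected left to right,
#' non-overlapping, taking at each step the lexicographically earliest
#' valid run chain; loops may themselves contain shorter G-runs.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param min_run Minimum G-run length (default 3).
#' @param max_loop Maximum loop length (default 7).
#' @return A `data.frame` with one row per match: `start`, `end` (0-based,
#'   half-open), `min_run_length`, plus list columns `g_runs` (four-row
#'   matrices of 0-based `start` and `length`) and `loop_lengths`.
#' @examples
#' find_canonical_g4_motifs("GGGAGGGTTGGGAGGG")
#' @export
find_canonical_g4_motifs <- function(seq, min_run = 3L, max_loop = 7L) {
  .check_dna(seq)
  stopifnot(min_run >= 2L, max_loop >= 1L)
  runs <- .g_runs(seq, min_run)
  out <- list()
  if (nrow(runs) >= 4L) {
    # restrict to runs starting at/after the cursor by dropping used rows
    avail <- runs
    repeat {
      if (nrow(avail) < 4L) break
      chain <- .chain_search(avail, 1L, 4L, max_loop)
      if (is.null(chain)) break
      r <- avail[chain, , drop = FALSE]
      starts0 <- r[, 1L] - 1L
      ends0 <- starts0 + r[, 2L]
      loops <- starts0[-1L] - ends0[-4L]
      out[[length(out) + 1L]] <- list(
        start = starts0[1L], end = ends0[4L],
        g_runs = cbind(start = starts0, length = r[, 2L]),
        loop_lengths = as.integer(loops),
        min_run_length = min(r[, 2L]))
      avail <- avail[avail[, 1L] > ends0[4L], , drop = FALSE]
    }
  }
  data.frame(
    start = vapply(out, `[[`, numeric(1L), "start"),
    end = vapply(out, `[[`, numeric(1L), "end"),
    min_run_length = vapply(out, `[[`, numeric(1L), "min_run_length"),
    g_runs = I(lapply(out, `[[`, "g_runs")),
    loop_lengths = I(lapply(out, `[[`, "loop_lengths"))
  )
}

#' Deterministic canonical-motif G4 potential
#'
#' A built-in, fully deterministic surrogate scorer mapping a sequence to
#' `1 - 2^(-q)`, where `q` sums, over the non-overlapping canonical motifs
#' found by [find_canonical_g4_motifs()], the motif's shortest G-run length
#' minus 2. A sequence with no canonical motif scores exactly 0; longer
#' G-runs and additional motifs push the score toward 1. The constants are
#' package choices made for determinism: this scorer does not reproduce the
#' numeric values of any learned G4 model.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @return A number in `[0, 1)`.
#' @examples
#' reference_g4_score("GGGAGGGTTGGGAGGG")  # 0.5
#' @export
reference_g4_score <- function(seq) {
  matches <- find_canonical_g4_motifs(seq)
  q <- if (nrow(matches)) sum(matches$min_run_length - 2) else 0
  1 - 2^(-q)
}

#' The built-in reference scorer as a `g4_scorer`
#'
#' @return A [g4_scorer()] wrapping [reference_g4_score()].
#' @export
reference_g4_scorer <- function() {
  g4_scorer("reference", reference_g4_score, deterministic = TRUE)
}

#' Score a sequence on both strands
#'
#' The top strand is the sequence as written (coding strand); the bottom
#' strand score is the score of the reverse complement. Coordinates
#' elsewhere in the package are always top-strand coordinates.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param scorer A [g4_scorer()]; default the reference scorer.
#' @param id Optional identifier used in error messages.
#' @return A list of class `strand_scores` with elements `top`, `bottom`,
#'   `scorer_name`.
#' @export
score_both_strands <- function(seq, scorer = reference_g4_scorer(),
                               id = NULL) {
  res <- tryCatch(
    list(top = score_sequence(scorer, seq),
         bottom = score_sequence(scorer, reverse_complement(seq))),
    error = function(e) {
      stop("scoring failed", if (!is.null(id)) paste0(" for ", sQuote(id)),
           ": ", conditionMessage(e), call. = FALSE)
    })
  structure(c(res, list(scorer_name = scorer$name)), class = "strand_scores")
}

#' Per-family (or per-gene) summary of strand-resolved G4 potentials
#'
#' Scores every allele's ungapped sequence on both strands and summarises
#' mean and standard deviation per family (or per gene) and strand. The
#' standard deviation of a single observation is reported as 0 so summary
#' tables have no missing cells; `n` is always recorded.
#'
#' @param alleles List of [ighv_allele()] objects.
#' @param scorer A [g4_scorer()].
#' @param by `"family"` or `"gene"`.
#' @return A `data.frame` with columns `group`, `strand`, `mean`, `sd`, `n`.
#' @export
family_potential_summary <- function(alleles, scorer = reference_g4_scorer(),
                                     by = c("family", "gene")) {
  by <- match.arg(by)
  if (!length(alleles)) stop("no alleles supplied", call. = FALSE)
  tab <- allele_score_table(alleles, scorer)
  tab$group <- if (by == "family") tab$family else tab$gene_id
  agg <- lapply(split(tab, list(tab$group, tab$strand), drop = TRUE),
                function(d) {
    data.frame(group = d$group[1L], strand = d$strand[1L],
               mean = mean(d$score),
               sd = if (nrow(d) > 1L) sd(d$score) else 0,
               n = nrow(d))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$group, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Per-allele strand-resolved score table
#'
#' @param alleles List of [ighv_allele()] objects.
#' @param scorer A [g4_scorer()].
#' @return A `data.frame` with columns `allele_id`, `gene_id`, `family`,
#'   `strand`, `scorer`, `score` (one row per allele and strand).
#' @export
allele_score_table <- function(alleles, scorer = reference_g4_scorer()) {
  rows <- lapply(alleles, function(a) {
    ss <- score_both_strands(a$ungapped_seq, scorer, id = a$allele_id)
    data.frame(allele_id = a$allele_id, gene_id = a$gene_id,
               family = a$family, strand = c("top", "bottom"),
               scorer = scorer$name, score = c(ss$top, ss$bottom))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrated-gradients attribution over a one-hot input
#'
#' Computes integrated gradients of a differentiable scorer along the
#' straight-line path from the all-zeros baseline to the input:
#' `attribution_i = x_i * mean_{k=1..n} grad_i(f)((k/n) * x)`, a
#' right-endpoint Riemann approximation of the path integral. The
#' completeness axiom (attributions summing to `f(x) - f(0)`) holds exactly
#' for linear scorers and up to a gap shrinking like `1/n_steps` otherwise;
#' the realised gap is returned with the attributions.
#'
#' @param f Scalar-valued function of a numeric vector (the scorer on
#'   one-hot inputs).
#' @param grad Gradient function: numeric vector in, numeric vector out.
#' @param x A `one_hot` encoding (or plain numeric vector) for the input.
#' @param n_steps Path resolution (default 128).
#' @return A list of class `attribution_vector` with elements
#'   `attributions`, `n_steps`, `completeness_gap`, `f_input`, `f_baseline`,
#'   and the encoding attributes `width`/`base_order` when available.
#' @export
integrated_gradients <- function(f, grad, x, n_steps = 128L) {
  stopifnot(is.function(f), is.function(grad), n_steps >= 1L)
  width <- attr(x, "width")
  base_order <- attr(x, "base_order")
  xv <- as.numeric(x)
  acc <- numeric(length(xv))
  for (k in seq_len(n_steps)) {
    g <- grad((k / n_steps) * xv)
    if (length(g) != length(xv)) {
      stop("gradient oracle returned a vector of length ", length(g),
           ", expected ", length(xv), call. = FALSE)
    }
    if (any(!is.finite(g))) stop("non-finite gradients at step ", k,
                                 call. = FALSE)
    acc <- acc + g
  }
  attributions <- xv * acc / n_steps
  f_input <- f(xv)
  f_baseline <- f(numeric(length(xv)))
  gap <- abs(sum(attributions) - (f_input - f_baseline))
  structure(list(attributions = attributions, n_steps = as.integer(n_steps),
                 completeness_gap = gap, f_input = f_input,
                 f_baseline = f_baseline, width = width,
                 base_order = base_order),
            class = "attribution_vector")
}

#' Reshape attributions into a per-position logo table
#'
#' Produces the tidy position-by-base table used to render attribution
#' logos: one row per sequence position, one column per base. The table's
#' total equals the total attribution (padding positions carry exactly
#' zero attribution because their one-hot input is zero).
#'
#' @param attr An `attribution_vector` from [integrated_gradients()].
#' @param seq The DNA string that was encoded.
#' @return A `data.frame` with columns `pos`, `base` (`A`,`C`,`G`,`T`
#'   columns named by base), i.e. `pos`, `A`, `C`, `G`, `T`.
#' @export
attribution_to_logo_table <- function(attr, seq) {
  stopifnot(inherits(attr, "attribution_vector"))
  .check_dna(seq)
  n <- nchar(seq)
  vals <- attr$attributions
  if (length(vals) %% 4L != 0L || length(vals) < 4L * n) {
    stop("attribution length ", length(vals),
         " inconsistent with sequence length ", n, call. = FALSE)
  }
  if (length(vals) > 4L * n && any(vals[-seq_len(4L * n)] != 0)) {
    stop("non-zero attributions beyond the sequence length: ",
         "attribution/sequence mismatch", call. = FALSE)
  }
  m <- matrix(vals[seq_len(4L * n)], ncol = 4L, byrow = TRUE)
  base_order <- attr$base_order
  if (is.null(base_order)) base_order <- DNA_BASES
  out <- data.frame(pos = seq_len(n))
  out[base_order] <- as.data.frame(m)
  out
}
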