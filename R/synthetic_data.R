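# Run the expression with a locally seeded RNG, restoring global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default FW/CDR region layout for simulated V-like sequences
#'
#' Scales the standard IMGT nucleotide boundaries of the V region
#' (FW1 1-78, CDR1 79-114, FW2 115-165, CDR2 166-195, FW3 196-312) to the
#' requested sequence length.
#'
#' @param length Sequence length in nt.
#' @return A region-map `data.frame` (`region`, `start`, `end`).
#' @export
default_region_layout <- function(length = 300L) {
  bounds <- c(0, 78, 114, 165, 195, 312) / 312
  cuts <- round(bounds * length)
  data.frame(region = c("FW1", "CDR1", "FW2", "CDR2", "FW3"),
             start = cuts[-6L] + 1L, end = cuts[-1L])
}

#' Configuration for simulated V-like germline alleles
#'
#' The defaults emulate the statistical shape of the real germline input:
#' 40 genes (the number of functional IGHV genes locatable in the
#' reference genome), ~300-nt V-like sequences at IGHV-like GC content,
#' half the alleles carrying one canonical G4 cassette, and three planted
#' AGCT motifs per allele (matching the observed V-region AGCT density of
#' about 1e-2 per nt). Background sequence never contains a G or C run of
#' length `>= min_run`, so canonical G4 motifs exist exactly where
#' planted.
#'
#' @param n_alleles Number of alleles to simulate (default 40).
#' @param length Sequence length in nt (default 300).
#' @param gc_content Background GC fraction (default 0.55).
#' @param g4_cassette List with `strand` (`"top"`/`"bottom"`), `count`
#'   (cassettes per carrying allele), `min_run` (G-run length), `loops`
#'   (three loop lengths), `frac_alleles` (fraction of alleles carrying
#'   cassettes).
#' @param planted_motifs List of lists with `motif`, `strand`, `count`.
#' @param region_layout Region-map template (default
#'   [default_region_layout()]).
#' @param families Family labels recycled over alleles.
#' @param seed Mandatory RNG seed.
#' @return A list of class `germline_sim_config`.
#' @export
germline_sim_config <- function(n_alleles = 40L, length = 300L,
                                gc_content = 0.55,
                                g4_cassette = list(strand = "top",
                                                   count = 1L, min_run = 3L,
                                                   loops = c(2L, 2L, 2L),
                                                   frac_alleles = 0.5),
                                planted_motifs = list(
                                  list(motif = "AGCT", strand = "top",
                                       count = 3L)),
                                region_layout = NULL, families = "IGHV3",
                                seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n_alleles >= 1L, length >= 30L,
            gc_content > 0, gc_content < 1)
  if (!is.null(g4_cassette)) {
    g4_cassette <- utils::modifyList(
      list(strand = "top", count = 1L, min_run = 3L, loops = c(2L, 2L, 2L),
           frac_alleles = 0.5), g4_cassette)
    stopifnot(g4_cassette$strand %in% c("top", "bottom"),
              g4_cassette$min_run >= 3L,
              length(g4_cassette$loops) == 3L,
              all(g4_cassette$loops >= 1L & g4_cassette$loops <= 7L),
              g4_cassette$frac_alleles >= 0, g4_cassette$frac_alleles <= 1)
    cassette_len <- 4L * g4_cassette$min_run + sum(g4_cassette$loops)
    if (cassette_len + 2L > length) {
      stop("cassette does not fit in the sequence length", call. = FALSE)
    }
  }
  structure(list(n_alleles = as.integer(n_alleles),
                 length = as.integer(length), gc_content = gc_content,
                 g4_cassette = g4_cassette,
                 planted_motifs = planted_motifs,
                 region_layout = region_layout,
                 families = families, seed = as.integer(seed)),
            class = "germline_sim_config")
}

# Background sequence with G- and C-homopolymer runs capped at max_run.
.background_seq <- function(length, gc_content, max_run) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  out <- character(length)
  run_base <- ""
  run_len <- 0L
  for (i in seq_len(length)) {
    allowed <- DNA_BASES
    if (run_len >= max_run && run_base %in% c("C", "G")) {
      allowed <- setdiff(allowed, run_base)
    }
    probs <- p[allowed] / sum(p[allowed])
    b <- sample(allowed, 1L, prob = probs)
    out[i] <- b
    if (b == run_base) run_len <- run_len + 1L else {
      run_base <- b
      run_len <- 1L
    }
  }
  paste(out, collapse = "")
}

.cassette_string <- function(min_run, loops) {
  loop_fill <- function(n) paste(rep(c("A", "T"), length.out = n),
                                 collapse = "")
  paste0(strrep("G", min_run), loop_fill(loops[1L]),
         strrep("G", min_run), loop_fill(loops[2L]),
         strrep("G", min_run), loop_fill(loops[3L]),
         strrep("G", min_run))
}

# Place features (list of strings) into a background without overlap.
# Cassettes (`buffered`) get a 1-nt A/T buffer on each side so flanking
# background G/C cannot extend their runs; plain motifs are placed bare
# (accidental boundary occurrences are caught by the planting validation
# and trigger a resample). Returns the assembled sequence and 1-based
# inclusive footprints, or NULL if placement failed.
.place_features <- function(background, features, buffered) {
  L <- nchar(background)
  occupied <- matrix(numeric(0), ncol = 2L)
  placements <- vector("list", length(features))
  for (i in seq_along(features)) {
    flen <- nchar(features[[i]]) + if (buffered[i]) 2L else 0L
    placed <- FALSE
    for (try in seq_len(200L)) {
      s <- sample.int(L - flen + 1L, 1L)
      e <- s + flen - 1L
      if (nrow(occupied) &&
          any(s <= occupied[, 2L] + 1 & e >= occupied[, 1L] - 1)) next
      occupied <- rbind(occupied, c(s, e))
      placements[[i]] <- c(s, e)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  seq <- background
  for (i in seq_along(features)) {
    s <- placements[[i]][1L]
    e <- placements[[i]][2L]
    piece <- if (buffered[i]) paste0("T", features[[i]], "A") else
      features[[i]]
    seq <- paste0(substr(seq, 1L, s - 1L), piece,
                  substr(seq, e + 1L, L))
  }
  list(seq = seq,
       footprints = lapply(seq_along(placements), function(i) {
         p <- placements[[i]]
         if (buffered[i]) c(p[1L] + 1L, p[2L] - 1L) else c(p[1L], p[2L])
       }))
}

#' Simulate V-like germline alleles with planted features
#'
#' Generates alleles with canonical G4 cassettes and AID motifs planted at
#' recorded positions over a run-capped random background, and emits the
#' ground truth alongside. Each allele is validated: the canonical motif
#' scanner must recover exactly the planted cassettes (per strand) and the
#' planted motif counts must equal the total occurrence counts; an allele
#' is resampled until valid (an error is raised if planting is
#' infeasible).
#'
#' @param cfg A [germline_sim_config()].
#' @return A list with `alleles` (list of [ighv_allele()] objects, each
#'   carrying a `features` ground-truth `data.frame`) and `truth` (all
#'   features row-bound, with `allele_id`, `type`, `name`, `strand`,
#'   `start`, `end` 1-based inclusive).
#' @export
simulate_germline_alleles <- function(cfg) {
  stopifnot(inherits(cfg, "germline_sim_config"))
  .with_seed(cfg$seed, {
    min_run <- if (!is.null(cfg$g4_cassette)) cfg$g4_cassette$min_run else 3L
    layout <- cfg$region_layout
    if (is.null(layout)) layout <- default_region_layout(cfg$length)
    carriers <- logical(cfg$n_alleles)
    if (!is.null(cfg$g4_cassette) && cfg$g4_cassette$count > 0L) {
      n_carry <- round(cfg$g4_cassette$frac_alleles * cfg$n_alleles)
      carriers[sample.int(cfg$n_alleles, n_carry)] <- TRUE
    }
    families <- rep_len(cfg$families, cfg$n_alleles)
    alleles <- vector("list", cfg$n_alleles)
    truth <- list()
    for (i in seq_len(cfg$n_alleles)) {
      allele_id <- sprintf("%s-%d*01", families[i], i)
      feats <- list()
      meta <- list()
      if (carriers[i]) {
        cas <- .cassette_string(cfg$g4_cassette$min_run,
                                cfg$g4_cassette$loops)
        if (cfg$g4_cassette$strand == "bottom") {
          cas <- reverse_complement(cas)
        }
        for (k in seq_len(cfg$g4_cassette$count)) {
          feats[[length(feats) + 1L]] <- cas
          meta[[length(meta) + 1L]] <- list(type = "g4_cassette",
                                            name = "canonical_g4",
                                            strand = cfg$g4_cassette$strand)
        }
      }
      for (pm in cfg$planted_motifs) {
        m <- toupper(pm$motif)
        planted <- if (identical(pm$strand, "bottom")) {
          reverse_complement(m)
        } else m
        for (k in seq_len(pm$count)) {
          feats[[length(feats) + 1L]] <- planted
          meta[[length(meta) + 1L]] <- list(type = "motif", name = m,
                                            strand = pm$strand)
        }
      }
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        bg <- .background_seq(cfg$length, cfg$gc_content, min_run - 1L)
        res <- .place_features(bg, feats,
                               vapply(meta, `[[`, character(1L),
                                      "type") == "g4_cassette")
        if (is.null(res)) next
        if (.valid_planting(res$seq, feats, meta, res$footprints,
                            min_run)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("infeasible planting for allele ", allele_id,
             " (motifs collide or background cannot be cleaned)",
             call. = FALSE)
      }
      a <- ighv_allele(allele_id, res$seq, region_map = layout)
      fdf <- if (length(feats)) {
        data.frame(allele_id = allele_id,
                   type = vapply(meta, `[[`, character(1L), "type"),
                   name = vapply(meta, `[[`, character(1L), "name"),
                   strand = vapply(meta, `[[`, character(1L), "strand"),
                   start = vapply(res$footprints, `[`, numeric(1L), 1L),
                   end = vapply(res$footprints, `[`, numeric(1L), 2L))
      } else {
        data.frame(allele_id = character(0), type = character(0),
                   name = character(0), strand = character(0),
                   start = numeric(0), end = numeric(0))
      }
      a$features <- fdf
      alleles[[i]] <- a
      truth[[i]] <- fdf
    }
    list(alleles = alleles, truth = do.call(rbind, truth))
  })
}

# Planted-feature validation: canonical matches per strand must coincide
# exactly with planted cassette footprints, and each planted motif's total
# occurrence count must equal the planted count.
.valid_planting <- function(seq, feats, meta, footprints, min_run) {
  types <- vapply(meta, `[[`, character(1L), "type")
  strands <- vapply(meta, `[[`, character(1L), "strand")
  L <- nchar(seq)
  for (s in c("top", "bottom")) {
    expect <- which(types == "g4_cassette" & strands == s)
    found <- find_canonical_g4_motifs(
      if (s == "top") seq else reverse_complement(seq), min_run = min_run)
    if (nrow(found) != length(expect)) return(FALSE)
    if (length(expect)) {
      planted <- vapply(footprints[expect], function(fp) {
        if (s == "top") fp[1L] - 1L else L - fp[2L]
      }, numeric(1L))
      if (!setequal(found$start, planted)) return(FALSE)
    }
  }
  motif_names <- unique(vapply(meta[types == "motif"], `[[`, character(1L),
                               "name"))
  for (m in motif_names) {
    idx <- types == "motif" & vapply(meta, `[[`, character(1L),
                                     "name") == m
    n_top <- Biostrings::countPattern(m, Biostrings::DNAString(seq))
    n_bottom <- Biostrings::countPattern(
      m, Biostrings::DNAString(reverse_complement(seq)))
    planted_top <- sum(idx & strands != "bottom")
    planted_bottom <- sum(idx & strands == "bottom")
    if (m == reverse_complement(m)) {
      # palindromic motifs appear on both strands at once
      if (n_top != planted_top + planted_bottom) return(FALSE)
    } else {
      if (n_top != planted_top || n_bottom != planted_bottom) return(FALSE)
    }
  }
  TRUE
}

#' Configuration for simulated SHM repertoires
#'
#' Defaults reflect the biology the simulator emulates: a per-site
#' mutation rate of 1e-3 per nt (the SHM rate per bp per cell division),
#' AID hotspots mutating several-fold faster and coldspots slower, and an
#' optional G4-coupled strand bias (`g4_strand_coupling`) that multiplies
#' the rate of hotspot sites on the strand carrying a planted G4 cassette
#' and of CCC coldspot sites on the opposite strand overlapping the
#' cassette footprint.
#'
#' @param n_reads Number of reads (default 2000).
#' @param base_rate Per-site mutation probability (default 1e-3).
#' @param hotspot_multiplier Rate multiplier at WRC hotspot sites
#'   (default 5).
#' @param coldspot_multiplier Rate multiplier at SYC coldspot sites
#'   (default 0.3).
#' @param g4_strand_coupling Coupling multiplier (default 1 = no
#'   coupling).
#' @param seed Mandatory RNG seed.
#' @return A list of class `shm_sim_config`.
#' @export
shm_sim_config <- function(n_reads = 2000L, base_rate = 1e-3,
                           hotspot_multiplier = 5,
                           coldspot_multiplier = 0.3,
                           g4_strand_coupling = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n_reads >= 1L, base_rate >= 0, base_rate <= 1,
            hotspot_multiplier >= 0, coldspot_multiplier >= 0,
            g4_strand_coupling >= 0)
  structure(list(n_reads = as.integer(n_reads), base_rate = base_rate,
                 hotspot_multiplier = hotspot_multiplier,
                 coldspot_multiplier = coldspot_multiplier,
                 g4_strand_coupling = g4_strand_coupling,
                 seed = as.integer(seed)),
            class = "shm_sim_config")
}

# Per-site mutation rates for an allele under an shm_sim_config.
.site_rates <- function(allele, cfg) {
  seq <- allele$ungapped_seq
  L <- nchar(seq)
  rate <- rep(cfg$base_rate, L)
  motifs <- scan_aid_motifs(seq)
  hot <- motifs[motifs$motif_class == "WRC_hotspot", , drop = FALSE]
  cold <- motifs[motifs$motif_class == "SYC_coldspot", , drop = FALSE]
  rate[unique(hot$pos)] <- rate[unique(hot$pos)] * cfg$hotspot_multiplier
  rate[unique(cold$pos)] <- rate[unique(cold$pos)] * cfg$coldspot_multiplier
  if (cfg$g4_strand_coupling != 1 && !is.null(allele$features)) {
    cas <- allele$features[allele$features$type == "g4_cassette", ,
                           drop = FALSE]
    coupled <- integer(0)
    for (ci in seq_len(nrow(cas))) {
      s <- cas$strand[ci]
      coupled <- c(coupled, hot$pos[hot$strand == s])
      opp <- if (s == "top") "bottom" else "top"
      ccc <- cold[cold$strand == opp & cold$trinucleotide == "CCC", ,
                  drop = FALSE]
      if (nrow(ccc)) {
        # trinucleotide footprint in top coordinates
        fs <- if (opp == "top") ccc$pos - 2L else ccc$pos
        fe <- if (opp == "top") ccc$pos else ccc$pos + 2L
        overlapping <- fs <= cas$end[ci] & fe >= cas$start[ci]
        coupled <- c(coupled, ccc$pos[overlapping])
      }
    }
    # a site couples once, however many cassettes share its strand
    coupled <- unique(coupled)
    rate[coupled] <- rate[coupled] * cfg$g4_strand_coupling
  }
  if (any(rate > 1)) {
    message("per-site rates capped at 1 for ", sum(rate > 1), " site(s)")
    rate <- pmin(rate, 1)
  }
  rate
}

#' Simulate an SHM repertoire for one allele
#'
#' Each read mutates each site independently with probability
#' `base_rate * class multiplier * coupling factor`; the substituted base
#' is uniform over the three alternatives. Rates exceeding 1 after
#' multiplication are capped (with a message).
#'
#' @param allele An [ighv_allele()] (a simulated allele's planted-feature
#'   ground truth, when present, drives the G4 coupling).
#' @param cfg An [shm_sim_config()].
#' @return A [repertoire_alignment()].
#' @export
simulate_shm_repertoire <- function(allele, cfg) {
  stopifnot(inherits(allele, "ighv_allele"), inherits(cfg, "shm_sim_config"))
  .with_seed(cfg$seed, {
    seq <- allele$ungapped_seq
    L <- nchar(seq)
    rate <- .site_rates(allele, cfg)
    germ <- strsplit(seq, "", fixed = TRUE)[[1L]]
    M <- matrix(rep(germ, each = cfg$n_reads), nrow = cfg$n_reads)
    hit <- matrix(runif(cfg$n_reads * L), nrow = cfg$n_reads) <
      matrix(rate, nrow = cfg$n_reads, ncol = L, byrow = TRUE)
    idx <- which(hit)
    if (length(idx)) {
      ref <- M[idx]
      alt <- vapply(ref, function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1L))
      M[idx] <- alt
    }
    reads <- apply(M, 1L, paste, collapse = "")
    repertoire_alignment(allele, reads)
  })
}

#' Configuration for simulated percent-mismatch tracks
#'
#' @param peak_height Mean percent mismatch over planted cassette
#'   footprints (default 60).
#' @param peak_sd Peak noise SD (default 5).
#' @param background_mean Background mean percent mismatch (default 5).
#' @param background_sd Background noise SD (default 2).
#' @param interval_width Track interval width in nt (default 15).
#' @param seed Mandatory RNG seed.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(peak_height = 60, peak_sd = 5,
                             background_mean = 5, background_sd = 2,
                             interval_width = 15L, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(peak_height >= 0, peak_height <= 100,
            background_mean >= 0, background_mean <= 100,
            peak_sd >= 0, background_sd >= 0, interval_width >= 1L)
  structure(list(peak_height = peak_height, peak_sd = peak_sd,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 interval_width = as.integer(interval_width),
                 seed = as.integer(seed)),
            class = "track_sim_config")
}

.truncnorm <- function(n, mean, sd) pmin(pmax(rnorm(n, mean, sd), 0), 100)

#' Simulate percent-mismatch tracks over simulated alleles
#'
#' Emits one strand-resolved track pair whose values are background noise
#' (truncated normal on `[0, 100]`), elevated to around `peak_height` over
#' the footprint of every planted G4 cassette on the cassette's strand,
#' plus matching region definitions (one V region per allele, with the
#' allele id doubling as the chromosome name).
#'
#' @param alleles List of alleles from [simulate_germline_alleles()]
#'   (their `features` ground truth drives the peaks).
#' @param cfg A [track_sim_config()].
#' @return A list with `top` and `bottom` [mismatch_track()]s and
#'   `regions` (a `data.frame` as from [read_bed_regions()]).
#' @export
simulate_mismatch_track <- function(alleles, cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  .with_seed(cfg$seed, {
    per_strand <- list(top = list(), bottom = list())
    regions <- list()
    for (a in alleles) {
      L <- nchar(a$ungapped_seq)
      starts <- seq.int(0L, L - 1L, by = cfg$interval_width)
      ends <- pmin(starts + cfg$interval_width, L)
      cas <- if (!is.null(a$features)) {
        a$features[a$features$type == "g4_cassette", , drop = FALSE]
      } else NULL
      for (s in c("top", "bottom")) {
        vals <- .truncnorm(length(starts), cfg$background_mean,
                           cfg$background_sd)
        if (!is.null(cas) && nrow(cas)) {
          for (ci in which(cas$strand == s)) {
            over <- starts < cas$end[ci] & ends > (cas$start[ci] - 1L)
            vals[over] <- .truncnorm(sum(over), cfg$peak_height,
                                     cfg$peak_sd)
          }
        }
        per_strand[[s]][[length(per_strand[[s]]) + 1L]] <-
          data.frame(chrom = a$allele_id, start = starts, end = ends,
                     value = vals)
      }
      regions[[length(regions) + 1L]] <-
        data.frame(name = a$allele_id, chrom = a$allele_id, start = 0L,
                   end = L, strand = "+", region_class = "V")
    }
    list(top = mismatch_track(do.call(rbind, per_strand$top), "top"),
         bottom = mismatch_track(do.call(rbind, per_strand$bottom),
                                 "bottom"),
         regions = do.call(rbind, regions))
  })
}
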