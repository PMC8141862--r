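#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor.test kruskal.test p.adjust rnorm runif sd setNames
#'   wilcox.test
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

REGION_NAMES <- c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3-part")

.check_dna <- function(seq, allow_n = FALSE, allow_gap = FALSE, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  alphabet <- c(DNA_BASES, if (allow_n) "N", if (allow_gap) ".")
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1L]]), alphabet)
  if (length(bad)) {
    stop(what, " contains invalid character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Construct an IGHV germline allele record
#'
#' An `ighv_allele` bundles a germline V-gene allele: its identifiers
#' (allele, gene, family), the IMGT-gapped sequence (gaps as `.`), the
#' ungapped sequence, and an optional framework/CDR region map given in
#' gapped (IMGT) coordinates, 1-based inclusive.
#'
#' Identifiers follow IMGT nomenclature: an allele id such as
#' `"IGHV3-49*02"` implies gene `"IGHV3-49"` and family `"IGHV3"`.
#'
#' @param allele_id Allele identifier, e.g. `"IGHV3-49*02"`.
#' @param gapped_seq Sequence over `A,C,G,T,N` optionally containing `.`
#'   gap characters (IMGT numbering).
#' @param region_map Optional `data.frame` with columns `region`, `start`,
#'   `end` (1-based inclusive, gapped coordinates). Regions must be ordered
#'   and non-overlapping.
#' @return An object of class `ighv_allele`.
#' @examples
#' a <- ighv_allele("IGHV3-49*02", "ACGT.GGG")
#' a$ungapped_seq
#' @export
ighv_allele <- function(allele_id, gapped_seq, region_map = NULL) {
  stopifnot(is.character(allele_id), length(allele_id) == 1L, nzchar(allele_id))
  gapped_seq <- toupper(gapped_seq)
  .check_dna(gapped_seq, allow_n = TRUE, allow_gap = TRUE,
             what = paste0("sequence of record ", sQuote(allele_id)))
  gene_id <- sub("\\*.*$", "", allele_id)
  family <- sub("(-|S).*$", "", gene_id)
  ungapped <- gsub(".", "", gapped_seq, fixed = TRUE)
  if (!nzchar(ungapped)) {
    stop("record ", sQuote(allele_id), " has an empty sequence", call. = FALSE)
  }
  if (!is.null(region_map)) {
    region_map <- as.data.frame(region_map)
    stopifnot(all(c("region", "start", "end") %in% names(region_map)))
    region_map <- region_map[, c("region", "start", "end")]
    region_map$start <- as.integer(region_map$start)
    region_map$end <- as.integer(region_map$end)
    n <- nchar(gapped_seq)
    ok <- region_map$start >= 1L & region_map$end <= n &
      region_map$start <= region_map$end
    if (!all(ok)) {
      stop("region_map of ", sQuote(allele_id),
           " has intervals outside [1, ", n, "]", call. = FALSE)
    }
    if (nrow(region_map) > 1L &&
        any(region_map$start[-1L] <= region_map$end[-nrow(region_map)])) {
      stop("region_map of ", sQuote(allele_id),
           " has overlapping or unordered intervals", call. = FALSE)
    }
    rownames(region_map) <- NULL
  }
  structure(
    list(allele_id = allele_id, gene_id = gene_id, family = family,
         gapped_seq = gapped_seq, ungapped_seq = ungapped,
         region_map = region_map),
    class = "ighv_allele"
  )
}

#' @export
print.ighv_allele <- function(x, ...) {
  cat("<ighv_allele> ", x$allele_id,
      " (gene ", x$gene_id, ", family ", x$family, ")\n", sep = "")
  cat("  gapped length: ", nchar(x$gapped_seq),
      ", ungapped length: ", nchar(x$ungapped_seq), "\n", sep = "")
  if (!is.null(x$region_map)) {
    cat("  regions: ", paste(x$region_map$region, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read germline V alleles from a FASTA file
#'
#' Headers may be plain allele identifiers (`>IGHV3-49*02`) or IMGT-style
#' pipe-delimited headers (`>X92343|IGHV1-2*01|Homo sapiens|...`), in which
#' case the second field is taken as the allele id. Sequences may contain
#' IMGT `.` gap characters; the ungapped sequence is derived by removing
#' them. A region-annotation sidecar (TSV with columns `allele_id`,
#' `region_name`, `gapped_start`, `gapped_end`) can populate each allele's
#' region map.
#'
#' @param path Path to a FASTA file.
#' @param regions Optional path to a region-annotation TSV, or a
#'   `data.frame` with the columns named above.
#' @return A list of [ighv_allele()] objects.
#' @export
read_ighv_fasta <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("cannot parse FASTA ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file ", path, " contains no records",
                              call. = FALSE)
  ids <- vapply(names(set), function(h) {
    h <- trimws(h)
    if (grepl("|", h, fixed = TRUE)) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1L]]
      if (length(parts) < 2L || !nzchar(trimws(parts[2L]))) {
        stop("unparsable IMGT-style header: ", sQuote(h), call. = FALSE)
      }
      trimws(parts[2L])
    } else {
      id <- strsplit(h, "[ \t]+")[[1L]][1L]
      if (is.na(id) || !nzchar(id)) {
        stop("unparsable FASTA header: ", sQuote(h), call. = FALSE)
      }
      id
    }
  }, character(1L))
  region_tab <- NULL
  if (!is.null(regions)) {
    region_tab <- if (is.character(regions)) read.delim(regions) else
      as.data.frame(regions)
    needed <- c("allele_id", "region_name", "gapped_start", "gapped_end")
    if (!all(needed %in% names(region_tab))) {
      stop("region annotation must have columns: ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
  }
  lapply(seq_along(set), function(i) {
    rm <- NULL
    if (!is.null(region_tab)) {
      sub <- region_tab[region_tab$allele_id == ids[[i]], , drop = FALSE]
      if (nrow(sub)) {
        rm <- data.frame(region = sub$region_name,
                         start = sub$gapped_start, end = sub$gapped_end)
      }
    }
    ighv_allele(ids[[i]], as.character(set[[i]]), region_map = rm)
  })
}

#' Write alleles to a FASTA file
#'
#' @param alleles List of [ighv_allele()] objects.
#' @param path Output path.
#' @param gapped Write the IMGT-gapped sequence (default) or the ungapped one.
#' @return Invisibly, `path`.
#' @export
write_ighv_fasta <- function(alleles, path, gapped = TRUE) {
  seqs <- vapply(alleles, function(a)
    if (gapped) a$gapped_seq else a$ungapped_seq, character(1L))
  set <- Biostrings::BStringSet(setNames(seqs,
    vapply(alleles, `[[`, character(1L), "allele_id")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. `N` maps to `N`.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("GGG")  # "CCC"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq, allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Map a gapped (IMGT) position to its ungapped position
#'
#' @param allele An [ighv_allele()].
#' @param gapped_pos 1-based position in the gapped sequence.
#' @return The 1-based position in the ungapped sequence, or `NA` if the
#'   gapped position is a `.` gap.
#' @export
gapped_to_ungapped <- function(allele, gapped_pos) {
  stopifnot(inherits(allele, "ighv_allele"))
  n <- nchar(allele$gapped_seq)
  if (any(gapped_pos < 1L | gapped_pos > n)) {
    stop("gapped position out of range [1, ", n, "]", call. = FALSE)
  }
  chars <- strsplit(allele$gapped_seq, "", fixed = TRUE)[[1L]]
  cum <- cumsum(chars != ".")
  out <- cum[gapped_pos]
  out[chars[gapped_pos] == "."] <- NA_integer_
  out
}

#' Map an ungapped position to its gapped (IMGT) position
#'
#' Inverse of [gapped_to_ungapped()] for non-gap positions.
#'
#' @param allele An [ighv_allele()].
#' @param ungapped_pos 1-based position in the ungapped sequence.
#' @return The 1-based position in the gapped sequence.
#' @export
ungapped_to_gapped <- function(allele, ungapped_pos) {
  stopifnot(inherits(allele, "ighv_allele"))
  n <- nchar(allele$ungapped_seq)
  if (any(ungapped_pos < 1L | ungapped_pos > n)) {
    stop("ungapped position out of range [1, ", n, "]", call. = FALSE)
  }
  chars <- strsplit(allele$gapped_seq, "", fixed = TRUE)[[1L]]
  which(chars != ".")[ungapped_pos]
}

#' Annotate an ungapped position with its FW/CDR region
#'
#' @param allele An [ighv_allele()] with a region map.
#' @param ungapped_pos 1-based ungapped position(s).
#' @return Character vector of region names; `"unassigned"` where the
#'   position falls outside the region map (or the map is absent).
#' @export
region_at <- function(allele, ungapped_pos) {
  if (is.null(allele$region_map)) {
    return(rep("unassigned", length(ungapped_pos)))
  }
  gp <- ungapped_to_gapped(allele, ungapped_pos)
  vapply(gp, function(p) {
    hit <- allele$region_map$start <= p & allele$region_map$end >= p
    if (any(hit)) allele$region_map$region[which(hit)[1L]] else "unassigned"
  }, character(1L))
}

#' Fixed-width one-hot encoding of a DNA sequence
#'
#' Encodes a sequence as a flat 0/1 vector of length `4 * width`, the input
#' convention of fixed-width learned G4 scorers. Each consecutive group of
#' four slots represents one nucleotide position, with base order
#' `A,C,G,T`. Sequences shorter than `width` are zero-padded at the 3' end;
#' longer sequences are truncated to their 5'-most `width` nt.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param width Encoding width in nt (default 297).
#' @return An integer vector of class `one_hot` with attributes `width`,
#'   `base_order` and `n_bases` (number of encoded, non-padding positions).
#' @examples
#' length(encode_one_hot(strrep("A", 297)))  # 1188
#' @export
encode_one_hot <- function(seq, width = 297L) {
  .check_dna(seq)
  stopifnot(width >= 1L)
  if (!nzchar(seq)) stop("cannot encode an empty sequence", call. = FALSE)
  width <- as.integer(width)
  n <- min(nchar(seq), width)
  chars <- strsplit(substr(seq, 1L, n), "", fixed = TRUE)[[1L]]
  base_idx <- match(chars, DNA_BASES)
  vec <- integer(4L * width)
  vec[(seq_len(n) - 1L) * 4L + base_idx] <- 1L
  structure(vec, width = width, base_order = DNA_BASES, n_bases = n,
            class = "one_hot")
}

#' Decode a one-hot encoding back to a DNA string
#'
#' @param x A `one_hot` object from [encode_one_hot()].
#' @return The encoded (possibly truncated) sequence, without padding.
#' @export
decode_one_hot <- function(x) {
  stopifnot(inherits(x, "one_hot"))
  width <- attr(x, "width")
  m <- matrix(as.integer(x), nrow = 4L)
  filled <- colSums(m) == 1L
  paste(attr(x, "base_order")[apply(m[, filled, drop = FALSE], 2L, which.max)],
        collapse = "")
}
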