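#' Tile a genome into fixed-width bins
#'
#' Builds the coordinate backbone used by every downstream step: contiguous
#' non-overlapping bins of `bin_size` bp per chromosome (the last bin of a
#' chromosome may be shorter). Sex chromosomes (X/Y, chrX/chrY) are dropped
#' unless requested, since copy-number normalisation assumes the autosomal
#' baseline.
#'
#' @param genome_index data frame with columns `chrom` and `length` (bp), or
#'   a named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 20 kb).
#' @param include_sex keep X/Y chromosomes (default FALSE).
#' @return tibble with `chrom`, `start`, `end` (0-based half-open), `gc`,
#'   `mappability` (NA until computed), `usable`.
#' @export
make_bins <- function(genome_index, bin_size = 20000L, include_sex = FALSE) {
  if (is.numeric(genome_index) && !is.null(names(genome_index))) {
    genome_index <- data.frame(chrom = names(genome_index),
                               length = unname(genome_index))
  }
  stopifnot(all(c("chrom", "length") %in% names(genome_index)))
  if (nrow(genome_index) == 0L) stop("empty genome index")
  if (bin_size < 1000L) stop("bin_size must be at least 1 kb")
  if (any(genome_index$length <= 0)) stop("chromosome lengths must be positive")
  if (!include_sex) {
    sex <- grepl("^(chr)?[XY]$", genome_index$chrom, ignore.case = TRUE)
    genome_index <- genome_index[!sex, , drop = FALSE]
    if (nrow(genome_index) == 0L)
      stop("no autosomes left after excluding sex chromosomes")
  }
  pieces <- lapply(seq_len(nrow(genome_index)), function(i) {
    len <- genome_index$length[i]
    start <- seq(0L, len - 1L, by = bin_size)
    tibble::tibble(chrom = genome_index$chrom[i], start = start,
                   end = pmin(start + bin_size, len))
  })
  bins <- dplyr::bind_rows(pieces)
  bins$gc <- NA_real_
  bins$mappability <- NA_real_
  bins$usable <- FALSE
  attr(bins, "bin_size") <- as.integer(bin_size)
  bins
}

#' Fill GC content per bin
#'
#' GC is the frequency of G and C over unambiguous bases (A/C/G/T) of the
#' bin's reference sequence. Bins whose sequence is at least
#' `max_ambiguous` ambiguous (N) get `gc = NA` and are excluded from use:
#' GC-bias correction is undefined there.
#'
#' @param bins bin table from [make_bins()].
#' @param genome `Biostrings::DNAStringSet` (names = chromosomes) or a path
#'   to a FASTA file.
#' @param max_ambiguous ambiguous-base fraction above which gc is NA
#'   (default 0.5).
#' @return `bins` with `gc` filled and `usable` refreshed.
#' @export
gc_content <- function(bins, genome, max_ambiguous = 0.5) {
  genome <- load_genome(genome)
  gc <- rep(NA_real_, nrow(bins))
  for (chr in unique(bins$chrom)) {
    if (!chr %in% names(genome)) stop("chromosome absent from genome: ", chr)
    idx <- which(bins$chrom == chr)
    seqlen <- length(genome[[chr]])
    if (max(bins$end[idx]) > seqlen)
      stop("bin beyond sequence end on ", chr)
    v <- Biostrings::Views(genome[[chr]],
                           start = bins$start[idx] + 1L, end = bins$end[idx])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    width <- bins$end[idx] - bins$start[idx]
    g <- (freq[, "C"] + freq[, "G"]) / acgt
    g[acgt == 0 | (1 - acgt / width) >= max_ambiguous] <- NA_real_
    gc[idx] <- g
  }
  bins$gc <- gc
  refresh_usable(bins)
}

#' Read-simulation parameters for the mappability track
#'
#' @param read_length read length in bp.
#' @param layout `"single-end"` or `"paired-end"`.
#' @param fragment_size fragment size in bp (paired-end only).
#' @param error_rate per-base substitution probability (default 0.001).
#' @return a `read_params` list.
#' @export
read_params <- function(read_length = 100L,
                        layout = c("single-end", "paired-end"),
                        fragment_size = NULL, error_rate = 0.001) {
  layout <- match.arg(layout)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (layout == "paired-end" && is.null(fragment_size))
    stop("fragment_size required for paired-end layout")
  structure(list(read_length = as.integer(read_length), layout = layout,
                 fragment_size = fragment_size, error_rate = error_rate),
            class = "read_params")
}

#' Simulation-based bin mappability
#'
#' Simulates 1X coverage from the reference (one read starting at every
#' `read_length`-th position, so the per-bin number of source reads Rs is
#' exact), perturbs each read with independent substitution errors, remaps
#' every read with `aligner` (best hit only), and scores each bin as
#' `M = Rr / Rs`: remapped reads landing in the bin over reads generated
#' there. Unique sequence with zero error rate gives M = 1 everywhere; a
#' sequence duplicated across the genome splits its reads between the
#' copies (M near 0.5); repeat sinks can exceed 1. Bins outside the
#' 0.8-1.5 band are flagged unusable.
#'
#' @param bins bin table.
#' @param genome `DNAStringSet` or FASTA path.
#' @param params [read_params()].
#' @param aligner function(reads_character, genome) returning a data frame
#'   with `chrom` and `pos` (1-based start; NA = unmapped). Default is the
#'   bundled exact-match k-mer mapper with uniform random tie-breaking.
#' @param seed integer seed governing read errors and tie-breaking.
#' @return `bins` with `mappability` filled and `usable` refreshed.
#' @export
compute_mappability <- function(bins, genome, params = read_params(),
                                aligner = kmer_aligner, seed = 1L) {
  genome <- load_genome(genome)
  missing_chr <- setdiff(unique(bins$chrom), names(genome))
  if (length(missing_chr))
    stop("mismatched genome, chromosomes absent: ",
         paste(missing_chr, collapse = ", "))
  set.seed(seed)
  rl <- params$read_length
  src <- lapply(unique(bins$chrom), function(chr) {
    seqlen <- length(genome[[chr]])
    if (seqlen < rl) return(NULL)
    starts <- seq(1L, seqlen - rl + 1L, by = rl)
    data.frame(chrom = chr, pos = starts,
               read = as.character(Biostrings::Views(genome[[chr]],
                                                     start = starts,
                                                     width = rl)))
  })
  src <- do.call(rbind, src)
  if (is.null(src)) stop("genome shorter than read length")
  reads <- mutate_reads(src$read, params$error_rate)
  hits <- aligner(reads, genome)
  if (!is.data.frame(hits) || !all(c("chrom", "pos") %in% names(hits)) ||
      nrow(hits) != nrow(src))
    stop("aligner failure: expected one (chrom, pos) row per read")
  bins$mappability <- tally_ratio(bins, src, hits)
  refresh_usable(bins)
}

# internal: per-bin remapped/source read-count ratio
tally_ratio <- function(bins, src, hits) {
  bin_of <- function(chrom, pos) {
    # pos is 1-based read start; bin rows may arrive in any order
    out <- rep(NA_integer_, length(pos))
    for (chr in unique(bins$chrom)) {
      idx <- which(bins$chrom == chr)
      idx <- idx[order(bins$start[idx])]
      sel <- which(chrom == chr & !is.na(pos))
      if (!length(sel)) next
      j <- findInterval(pos[sel] - 1L, bins$start[idx])
      ok <- j >= 1L & (pos[sel] - 1L) < bins$end[idx][pmax(j, 1L)]
      out[sel[ok]] <- idx[j[ok]]
    }
    out
  }
  rs <- tabulate(bin_of(src$chrom, src$pos), nbins = nrow(bins))
  rr <- tabulate(bin_of(hits$chrom, hits$pos), nbins = nrow(bins))
  m <- rr / rs
  m[rs == 0] <- NA_real_
  m
}

# internal: independent per-base substitution errors
mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  rl <- nchar(reads[1L])
  n_err <- stats::rbinom(length(reads), rl, error_rate)
  todo <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(rl, n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Bundled exact-match k-mer read mapper
#'
#' Maps each read to the positions where its full sequence occurs in the
#' genome (exact match, both strands not considered: reads are simulated
#' from the forward strand). Best hit only; multi-mapping reads are placed
#' uniformly at random among their hits; reads with no exact hit are
#' unmapped (NA). This makes the mappability ratio aligner-independent and
#' testable without external binaries.
#'
#' @param reads character vector of read sequences.
#' @param genome `DNAStringSet`.
#' @param ties multi-mapper policy: `"random"` (uniform among best hits,
#'   the default; a two-copy repeat then re-collects on average all its
#'   reads and keeps M near 1, with inflated variance), `"first"`
#'   (leftmost hit wins: the first copy becomes a repeat sink with M near
#'   2 and later copies drop to 0, both outside the usable band) or
#'   `"drop"` (unique hits only; repeats get M = 0).
#' @return data frame with one row per read: `chrom`, `pos` (NA if unmapped).
#' @export
kmer_aligner <- function(reads, genome, ties = c("random", "first", "drop")) {
  ties <- match.arg(ties)
  rl <- nchar(reads[1L])
  index <- lapply(names(genome), function(chr) {
    seqlen <- length(genome[[chr]])
    if (seqlen < rl) return(NULL)
    starts <- seq_len(seqlen - rl + 1L)
    data.frame(chrom = chr, pos = starts,
               kmer = as.character(Biostrings::Views(genome[[chr]],
                                                     start = starts,
                                                     width = rl)))
  })
  index <- do.call(rbind, index)
  hit_groups <- split(seq_len(nrow(index)), index$kmer)
  out_chrom <- rep(NA_character_, length(reads))
  out_pos <- rep(NA_integer_, length(reads))
  grp <- hit_groups[reads]
  n_hits <- lengths(grp)
  single <- which(n_hits == 1L)
  if (length(single)) {
    j <- unlist(grp[single], use.names = FALSE)
    out_chrom[single] <- index$chrom[j]
    out_pos[single] <- index$pos[j]
  }
  multi <- which(n_hits > 1L)
  if (ties != "drop") {
    for (i in multi) {
      j <- if (ties == "random") grp[[i]][sample.int(n_hits[i], 1L)] else
        grp[[i]][1L]
      out_chrom[i] <- index$chrom[j]
      out_pos[i] <- index$pos[j]
    }
  }
  data.frame(chrom = out_chrom, pos = out_pos)
}

#' Mark blacklisted bins unusable
#'
#' @param bins bin table.
#' @param blacklist data frame with `chrom`, `start`, `end` (0-based
#'   half-open) or path to a 3-column BED file.
#' @return `bins` with overlapping bins excluded and `usable` refreshed.
#' @export
apply_blacklist <- function(bins, blacklist) {
  if (is.character(blacklist)) {
    blacklist <- utils::read.table(blacklist, sep = "\t",
                                   col.names = c("chrom", "start", "end"),
                                   colClasses = c("character", "integer",
                                                  "integer"))
  }
  b <- GenomicRanges::GRanges(bins$chrom,
                              IRanges::IRanges(bins$start + 1L, bins$end))
  bl <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$start + 1L,
                                                blacklist$end))
  hit <- IRanges::overlapsAny(b, bl)
  attr(bins, "blacklisted") <- hit | blacklisted(bins)
  refresh_usable(bins)
}

# internal accessors -------------------------------------------------------

blacklisted <- function(bins) {
  bl <- attr(bins, "blacklisted")
  if (is.null(bl)) rep(FALSE, nrow(bins)) else bl
}

refresh_usable <- function(bins) {
  bins$usable <- !is.na(bins$gc) &
    !is.na(bins$mappability) &
    bins$mappability >= 0.8 & bins$mappability <= 1.5 &
    !blacklisted(bins)
  bins
}

# internal: short trailing bins, excluded from GC-correction median pools
short_bins <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- stats::median(bins$end - bins$start)
  (bins$end - bins$start) < bs
}

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read / write a bin-annotation table
#'
#' Plain TSV with columns chrom, start, end, gc, mappability, usable.
#' @param bins bin table.
#' @param path file path.
#' @return the bins (write) or a bin tibble (read).
#' @export
write_bins <- function(bins, path) {
  utils::write.table(as.data.frame(bins)[, c("chrom", "start", "end", "gc",
                                             "mappability", "usable")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bins)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$gc <- as.numeric(df$gc)
  df$mappability <- as.numeric(df$mappability)
  bins <- tibble::as_tibble(df)
  attr(bins, "bin_size") <- as.integer(stats::median(bins$end - bins$start))
  bins
}
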