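#' Simulate a scored peak set with planted E-box motifs
#'
#' Generates peak sequences on a synthetic contig: each peak draws a motif
#' class from `class_probs`, receives a random background sequence at the
#' stated GC fraction guaranteed to contain no CACGTG/CATGTG core on either
#' strand, and (unless the class is `"none"`) has exactly one 8-mer of the
#' drawn class planted at a random position on a random strand. Candidate
#' sequences in which the background or the planting junction creates a
#' spurious core, or whose classification would differ from the planted
#' class, are resampled, so [classify_ebox()] recovers the planted class
#' with zero confusion. Peak scores are drawn from class-conditional
#' normal distributions recorded in the ground truth.
#'
#' @param n_peaks Number of peaks.
#' @param class_probs Named numeric vector of class proportions over
#'   [ebox_classes()] (subset allowed); must sum to 1.
#' @param peak_len Peak width in bp (default 200, >= 8).
#' @param gc Background GC fraction (default 0.41, genome-like).
#' @param score_means Named vector of per-class score means; defaults give
#'   canonical classes higher scores.
#' @param score_sd Score standard deviation (default 1).
#' @param seed Integer seed.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (strand the motif was planted on), `seq`,
#'   `class_true`; plus a `ground_truth` attribute.
#' @export
simulate_peakset <- function(n_peaks, class_probs, peak_len = 200L,
                             gc = 0.41, score_means = NULL, score_sd = 1,
                             seed = 1L) {
  n_peaks <- as.integer(n_peaks)
  peak_len <- as.integer(peak_len)
  if (peak_len < 8L) stop("peak_len must be >= 8", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    stop("class_probs must be >= 0 and sum to 1", call. = FALSE)
  }
  if (!all(names(class_probs) %in% ebox_classes())) {
    stop("unknown class in class_probs; see ebox_classes()", call. = FALSE)
  }
  default_means <- c(TCACGTGA = 10, TCACGTGB = 8, TCATGTGA = 7,
                     TCATGTGB = 6, CACGTG_other = 5, CATGTG_other = 4,
                     none = 3)
  if (is.null(score_means)) score_means <- default_means
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  plant_8mer <- function(cls) {
    B <- c("C", "G", "T")
    switch(cls,
      TCACGTGA = "TCACGTGA",
      TCACGTGB = paste0("TCACGTG", sample(B, 1)),
      TCATGTGA = "TCATGTGA",
      TCATGTGB = paste0("TCATGTG", sample(B, 1)),
      # non-T 5' flank on both strand readings (see classifier rules)
      CACGTG_other = paste0(sample(c("A", "C", "G"), 1), "CACGTG",
                            sample(c("C", "G", "T"), 1)),
      CATGTG_other = paste0(sample(c("A", "C", "G"), 1), "CATGTG",
                            sample(c("A", "C", "G", "T"), 1)),
      none = NULL
    )
  }
  count_cores <- function(s) {
    # core sites on either strand: CACGTG is its own reverse complement,
    # CATGTG reads CACATG on the opposite strand
    sum(vapply(c("CACGTG", "CATGTG", "CACATG"), function(core) {
      m <- gregexpr(core, s, fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
  }

  df <- withr::with_seed(as.integer(seed), {
    cls_drawn <- sample(names(class_probs), n_peaks, replace = TRUE,
                        prob = class_probs)
    seqs <- character(n_peaks)
    strands <- character(n_peaks)
    for (k in seq_len(n_peaks)) {
      repeat {
        bg <- paste(sample(names(base_probs), peak_len, replace = TRUE,
                           prob = base_probs), collapse = "")
        if (count_cores(bg) > 0L) next
        if (cls_drawn[k] == "none") {
          seqs[k] <- bg; strands[k] <- "."
          break
        }
        mer <- plant_8mer(cls_drawn[k])
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") mer else .revcomp(mer)
        pos <- sample.int(peak_len - 7L, 1)
        cand <- paste0(substr(bg, 1, pos - 1L), ins,
                       substr(bg, pos + 8L, peak_len))
        # the junction may create a spurious core; require exactly the
        # planted core site and a clean classifier read-back
        if (count_cores(cand) == 1L &&
            as.character(classify_ebox(cand)$class) == cls_drawn[k]) {
          seqs[k] <- cand; strands[k] <- strand
          break
        }
      }
    }
    scores <- stats::rnorm(n_peaks, score_means[cls_drawn], score_sd)
    starts <- (seq_len(n_peaks) - 1L) * (peak_len + 100L)
    data.frame(chrom = "chrSim", start = starts, end = starts + peak_len,
               name = sprintf("peak%05d", seq_len(n_peaks)),
               score = scores, strand = strands, seq = seqs,
               class_true = cls_drawn, stringsAsFactors = FALSE)
  })
  attr(df, "ground_truth") <- list(
    generator = "simulate_peakset", n_peaks = n_peaks,
    class_probs = as.list(class_probs), peak_len = peak_len, gc = gc,
    score_means = as.list(score_means[unique(df$class_true)]),
    score_sd = score_sd, seed = as.integer(seed)
  )
  df
}

#' Write peaks as a BED6 + FASTA pair
#'
#' The BED file carries the interval, name, score and motif strand; the
#' FASTA carries one record per peak keyed by the peak name.
#'
#' @param peaks Peak data frame as from [simulate_peakset()] or
#'   [read_peaks()].
#' @param bed_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_peaks <- function(peaks, bed_path, fasta_path) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$score, ifelse(peaks$strand %in% c("+", "-"),
                                        peaks$strand, "."))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ss <- Biostrings::DNAStringSet(peaks$seq)
  names(ss) <- peaks$name
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(c(bed_path, fasta_path))
}

#' Read peaks from a BED6 file plus sequences
#'
#' Sequences are taken either from a per-peak FASTA (record names matching
#' BED names) or extracted by interval from a genome FASTA. BED intervals
#' are 0-based half-open.
#'
#' @param bed_path BED6 file (chrom, start, end, name, score, strand).
#' @param fasta_path FASTA file of peak or genome sequences.
#' @param genome If `TRUE`, treat the FASTA as a genome and extract
#'   `[start, end)` from the matching chromosome record; otherwise match
#'   records to peak names.
#' @return Peak data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `seq`).
#' @export
read_peaks <- function(bed_path, fasta_path, genome = FALSE) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric",
                                          "character"))
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  if (genome) {
    missing_chr <- setdiff(unique(bed$chrom), names(fa))
    if (length(missing_chr)) {
      stop("chromosomes absent from FASTA: ",
           paste(missing_chr, collapse = ", "), call. = FALSE)
    }
    bed$seq <- vapply(seq_len(nrow(bed)), function(i) {
      as.character(Biostrings::subseq(fa[[bed$chrom[i]]],
                                      bed$start[i] + 1L, bed$end[i]))
    }, character(1))
  } else {
    if (!all(bed$name %in% names(fa))) {
      stop("FASTA is missing records for some peak names", call. = FALSE)
    }
    bed$seq <- as.character(fa[bed$name])
  }
  bed
}
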