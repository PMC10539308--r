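#' E-box motif classes
#'
#' The motif classes assigned to peak sequences, in priority order: the
#' palindromic CLEAR-box `TCACGTGA`; `TCACGTGB` (CACGTG core with the 5' T
#' but a non-A 3' flank, B = C/G/T); the TYR-type `TCATGTGA`; `TCATGTGB`
#' (includes the `TCATGTGT` M-box); CACGTG or CATGTG cores without the 5' T
#' flank (`CACGTG_other`, `CATGTG_other`); and `none`.
#'
#' @return Character vector of class labels in priority order.
#' @export
ebox_classes <- function() {
  c("TCACGTGA", "TCACGTGB", "TCATGTGA", "TCATGTGB",
    "CACGTG_other", "CATGTG_other", "none")
}

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# scan one strand's sequence for extended E-box occurrences;
# returns data.frame(class, start) in that strand's coordinates
.scan_strand <- function(s) {
  out <- list()
  for (core in c("CACGTG", "CATGTG")) {
    m <- gregexpr(core, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (p in as.integer(m)) {
      f5 <- if (p > 1L) substr(s, p - 1L, p - 1L) else ""
      f3 <- if (p + 6L <= nchar(s)) substr(s, p + 6L, p + 6L) else ""
      cls <- if (core == "CACGTG") {
        if (f5 == "T" && f3 == "A") "TCACGTGA"
        else if (f5 == "T" && f3 %in% c("C", "G", "T")) "TCACGTGB"
        else "CACGTG_other"
      } else {
        if (f5 == "T" && f3 == "A") "TCATGTGA"
        else if (f5 == "T" && f3 %in% c("C", "G", "T")) "TCATGTGB"
        else "CATGTG_other"
      }
      out[[length(out) + 1L]] <- data.frame(class = cls, start = p)
    }
  }
  if (length(out) == 0L) {
    data.frame(class = character(0), start = integer(0))
  } else {
    do.call(rbind, out)
  }
}

#' Classify the E-box motif class of peak sequences
#'
#' Scans both strands of each sequence for `CACGTG` and `CATGTG` cores,
#' reads the 5' and 3' flanking bases of each occurrence on its own strand
#' and assigns the highest-priority extended-E-box class present (see
#' [ebox_classes()]). Cores at a sequence edge that lack a flanking base
#' fall to the `_other` class of their core, and `N` never matches a core
#' or flank. Ties within a class are broken by the leftmost position on the
#' plus strand, so classification is invariant under reverse complement.
#'
#' @param seqs Character vector of A/C/G/T/N sequences (case-insensitive).
#' @return Data frame with one row per sequence: `class` (factor with
#'   levels [ebox_classes()]), `position` (1-based start of the matched
#'   core on the plus strand; `NA` for class `none`) and `strand`
#'   (`"+"`, `"-"` or `NA`).
#' @examples
#' classify_ebox(probe_oligos())  # TCACGTGA, TCATGTGA, TCATGTGB
#' @export
classify_ebox <- function(seqs) {
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequences may only contain A, C, G, T or N", call. = FALSE)
  }
  lv <- ebox_classes()
  rc <- .revcomp(seqs)
  res <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    plus <- .scan_strand(seqs[i])
    minus <- .scan_strand(rc[i])
    hits <- rbind(
      if (nrow(plus)) cbind(plus, strand = "+",
                            pos_plus = plus$start),
      if (nrow(minus)) cbind(minus, strand = "-",
                             pos_plus = L - minus$start - 4L)
    )
    if (is.null(hits) || nrow(hits) == 0L) {
      return(data.frame(class = "none", position = NA_integer_,
                        strand = NA_character_))
    }
    hits$rank <- match(hits$class, lv)
    # locale-independent tie-break: priority, then leftmost on plus, then +
    best <- hits[order(hits$rank, hits$pos_plus, hits$strand == "-"), ][1, ]
    data.frame(class = best$class, position = best$pos_plus,
               strand = best$strand)
  })
  out <- do.call(rbind, res)
  out$class <- factor(out$class, levels = lv)
  out
}

#' Per-condition motif-class proportions
#'
#' Tabulates the proportion of peaks in each E-box class per condition;
#' proportions within a condition sum to 1 exactly.
#'
#' @param classes Factor or character vector of classes (one per peak), as
#'   from `classify_ebox(peaks$seq)$class`.
#' @param condition Condition label per peak (single value recycled).
#' @return Data frame: `condition`, `class`, `n`, `proportion`.
#' @export
motif_ratio_table <- function(classes, condition = "all") {
  classes <- factor(as.character(classes), levels = ebox_classes())
  if (length(condition) == 1L) condition <- rep(condition, length(classes))
  do.call(rbind, lapply(unique(condition), function(cond) {
    tab <- table(classes[condition == cond])
    data.frame(condition = cond, class = names(tab), n = as.integer(tab),
               proportion = as.integer(tab) / sum(tab), row.names = NULL)
  }))
}

#' Peak score versus moving-average motif incidence
#'
#' Sorts peaks by descending score and computes, for each rank, the
#' centered moving average (window `window` peaks, truncated at the edges)
#' of the indicator that the peak's class belongs to `target_classes` —
#' the score-vs-incidence analysis of ranked ChIP peaks.
#'
#' @param scores Numeric peak scores.
#' @param classes Class labels parallel to `scores`.
#' @param target_classes Character vector of classes counted as incidence.
#' @param window Moving-average window in peaks (default 100, >= 2).
#' @return Data frame: `rank`, `score`, `incidence` (0/1),
#'   `moving_avg`.
#' @export
motif_incidence_moving_avg <- function(scores, classes, target_classes,
                                       window = 100L) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (length(scores) < window) {
    stop("need at least `window` peaks", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  inc <- as.integer(as.character(classes)[o] %in% target_classes)
  ma <- zoo::rollapply(inc, width = window, FUN = mean, partial = TRUE,
                       align = "center")
  data.frame(rank = seq_along(o), score = scores[o], incidence = inc,
             moving_avg = as.numeric(ma))
}
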