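# Plant-style miRNA target scoring.
#
# Scoring scheme (the plant convention implemented by the common target
# prediction tools): per aligned position a Watson-Crick match costs 0, a
# G:U wobble 0.5, any other mismatch 1; penalties are doubled at miRNA
# positions 2-13 (the functionally critical core).  A duplex is called a
# predicted target when its total score is strictly below 4.

normalize_rna <- function(seq) {
  s <- toupper(gsub("\\s", "", seq))
  s <- chartr("T", "U", s)
  if (nchar(s) == 0L) stop_ipnet("empty sequence")
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), RNA_BASES)
  if (length(bad)) {
    stop_ipnet("invalid base(s) in sequence: ", paste(bad, collapse = ", "))
  }
  chars
}

#' Reverse complement of an RNA sequence
#'
#' @param seq sequence over A/C/G/U (T accepted and treated as U).
#' @return reverse-complement string, 5'->3'.
#' @export
rna_reverse_complement <- function(seq) {
  paste(rev(RNA_COMPLEMENT[normalize_rna(seq)]), collapse = "")
}

#' Score an miRNA / target-site duplex
#'
#' The two sequences are given 5'->3' and must have equal length (only
#' ungapped duplexes are scored); miRNA position `i` pairs with site
#' position `L + 1 - i`.  Per position: match 0, G:U wobble 0.5,
#' mismatch 1, doubled at miRNA positions 2-13.  A score of 0 is a
#' perfect duplex; scores grow monotonically with added mismatches.
#'
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param site_seq target site sequence, 5'->3'.
#' @return the total penalty score.
#' @examples
#' score_duplex("UGGAAGCUA", rna_reverse_complement("UGGAAGCUA"))  # 0
#' @export
score_duplex <- function(mirna_seq, site_seq) {
  m <- normalize_rna(mirna_seq)
  s <- normalize_rna(site_seq)
  if (length(m) != length(s)) {
    stop_ipnet("miRNA and site must have equal length (ungapped duplex)")
  }
  L <- length(m)
  paired <- rev(s)  # site base opposite miRNA position i
  per_pos <- vapply(seq_len(L), function(i) {
    a <- m[i]; b <- paired[i]
    if (b == RNA_COMPLEMENT[[a]]) return(0)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(0.5)
    1
  }, numeric(1))
  core <- seq_len(L) >= 2 & seq_len(L) <= 13
  sum(per_pos * ifelse(core, 2, 1))
}

#' Scan a transcript for miRNA target sites
#'
#' Scores every ungapped window of miRNA length along the transcript
#' (windows taken 5'->3') with [score_duplex()] and reports windows whose
#' score is strictly below the threshold, best score first.  Coordinates
#' are 0-based half-open on the transcript.
#'
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param transcript_seq transcript sequence, 5'->3', at least as long as
#'   the miRNA.
#' @param threshold score cutoff (default 4, exclusive).
#' @return data.frame with columns `site_start`, `site_end`, `score`,
#'   `predicted` (all TRUE at the default threshold), ordered by score
#'   then position.
#' @export
scan_targets <- function(mirna_seq, transcript_seq, threshold = 4) {
  m <- normalize_rna(mirna_seq)
  tx <- normalize_rna(transcript_seq)
  L <- length(m)
  if (length(tx) < L) {
    stop_ipnet("transcript shorter than the miRNA")
  }
  starts <- 0:(length(tx) - L)
  scores <- vapply(starts, function(s0) {
    site <- paste(tx[(s0 + 1):(s0 + L)], collapse = "")
    score_duplex(mirna_seq, site)
  }, numeric(1))
  keep <- scores < threshold
  out <- data.frame(site_start = starts[keep],
                    site_end = starts[keep] + L,
                    score = scores[keep],
                    predicted = rep(TRUE, sum(keep)))
  out[order(out$score, out$site_start), , drop = FALSE]
}

#' Pearson correlation between miRNA and target expression profiles
#'
#' Reported alongside target predictions as supporting evidence (a
#' repressed target tends to be anticorrelated with its miRNA); no gate
#' is applied.
#'
#' @param mirna_profile,target_profile aligned numeric vectors (n >= 3).
#' @return Pearson r, or `NA` (with a message) when either profile has
#'   zero variance.
#' @export
expression_anticorrelation <- function(mirna_profile, target_profile) {
  if (length(mirna_profile) != length(target_profile) ||
      length(mirna_profile) < 3L) {
    stop_ipnet("profiles must be aligned vectors of length >= 3")
  }
  if (sd(mirna_profile) == 0 || sd(target_profile) == 0) {
    message("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  cor(mirna_profile, target_profile)
}
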