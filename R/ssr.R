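## Microsatellite (SSR) scanning.
##
## An SSR array of period p is a chain of perfect unit runs of one p-mer
## motif in which consecutive runs may be bridged by exactly one
## nucleotide (two adjacent non-motif bases terminate the array; N breaks
## any array). Minimum complete units: 6 for dinucleotides, 4 for
## trinucleotides, 3 for tetra-/penta-/hexanucleotides. Bridging bases do
## not count towards the unit tally. Motifs are reported as their
## lexicographically smallest rotation; arrays whose motif is itself a
## repetition of a shorter motif (poly-A as AA, ATAT as a 4-mer, ...) are
## only reported at the shorter period.
##
## Where calls of different periods overlap at one locus, one call is kept,
## preferring fewer interruptions, then the smaller period, then the
## earlier start, then more units. Preferring the uninterrupted call first
## matters: any perfect (p+1)-mer array also chains as an interrupted
## p-mer (abcde abcde ... = abcd e abcd e ...), and that degenerate shadow
## must not displace the true period.

.ssr_min_units <- c(`2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

## smallest rotation of a motif string
.canonical_rotation <- function(motif) {
  ch <- strsplit(motif, "")[[1L]]
  p <- length(ch)
  rots <- vapply(seq_len(p), function(i) {
    paste(ch[c(i:p, seq_len(i - 1L))[seq_len(p)]], collapse = "")
  }, character(1))
  min(rots)
}

## TRUE when the motif is a whole-number repetition of a shorter word
.is_degenerate_motif <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (strrep(substr(motif, 1L, d), p %/% d) == motif) return(TRUE)
  }
  FALSE
}

## rolling all-true over windows of width w: out[i] = all(v[i..i+w-1])
.roll_all <- function(v, w) {
  n <- length(v)
  if (n < w) return(logical(0))
  cs <- cumsum(!v)
  cs[seq(w, n)] - c(0, cs[seq_len(n - w)]) == 0L
}

## Shared post-processing: threshold, degeneracy and locus-overlap
## filters over a raw candidate table.
.ssr_select <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[cand$n_units >= .ssr_min_units[as.character(cand$period)], ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  ## maximality: an array whose span is contained in a longer array of
  ## the same period (e.g. a perfect run inside a bridged chain of a
  ## different phase) is not reported separately
  contained <- vapply(seq_len(nrow(cand)), function(i) {
    any(cand$period == cand$period[i] &
          cand$start <= cand$start[i] & cand$end >= cand$end[i] &
          !(cand$start == cand$start[i] & cand$end == cand$end[i]))
  }, logical(1))
  cand <- cand[!contained, , drop = FALSE]
  keep <- !vapply(cand$raw_motif, .is_degenerate_motif, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$n_interruptions, cand$period, cand$start,
                     -cand$n_units), , drop = FALSE]
  kept <- logical(nrow(cand))
  ends <- numeric(0)
  starts <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < ends & cand$end[i] > starts)) {
      kept[i] <- TRUE
      starts <- c(starts, cand$start[i])
      ends <- c(ends, cand$end[i])
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand$motif <- vapply(cand$raw_motif, .canonical_rotation, character(1))
  cand$raw_motif <- NULL
  cand <- cand[order(cand$start, cand$period), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Scan a sequence for microsatellite (SSR) arrays
#'
#' Detects maximal arrays of tandemly repeated 2-6 nt motifs in which
#' perfect unit runs may be bridged by single-nucleotide interruptions
#' (at most one in a row; interruptions do not count towards the unit
#' tally). Unit-count thresholds per motif length: di 6, tri 4,
#' tetra/penta/hexa 3.
#'
#' @param seq A single sequence: character scalar, [Biostrings::DNAString]
#'   or one-element `DNAStringSet`. `N` terminates any array.
#' @return Data.frame with columns `start`, `end` (0-based half-open span
#'   from the first to the last complete unit, bridges included), `period`,
#'   `motif` (canonical rotation), `n_units`, `n_interruptions`.
#' @examples
#' scan_ssrs("ATATATATATAT")   # one di array, 6 units
#' scan_ssrs("ACGACGACGACG")   # one tri array, 4 units
#' @export
scan_ssrs <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  x <- strsplit(toupper(as.character(seq)), "")[[1L]]
  n <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  empty <- data.frame(start = integer(0), end = integer(0),
                      period = integer(0), motif = character(0),
                      n_units = integer(0), n_interruptions = integer(0))
  if (n < 4L) return(empty)
  cand <- list()
  for (p in 2:6) {
    if (n < 2L * p) next
    ## UM[i]: the p-mer at i repeats immediately at i+p
    eqp <- x[seq_len(n - p)] == x[seq(p + 1L, n)] &
      valid[seq_len(n - p)] & valid[seq(p + 1L, n)]
    UM <- logical(n)
    um <- .roll_all(eqp, p)
    UM[seq_along(um)] <- um
    ## BM[i]: the p-mer at i repeats at i+p+1 (single bridging base, which
    ## must itself be a called base)
    BM <- logical(n)
    if (n >= 2L * p + 1L) {
      eqb <- x[seq_len(n - p - 1L)] == x[seq(p + 2L, n)] &
        valid[seq_len(n - p - 1L)] & valid[seq(p + 2L, n)]
      bm <- .roll_all(eqb, p)
      bm <- bm & valid[seq_along(bm) + p]
      BM[seq_along(bm)] <- bm
    }
    inchain <- UM | BM
    if (!any(inchain)) next
    idx <- which(inchain)
    pre1 <- idx - p
    pre2 <- idx - p - 1L
    haspred <- (pre1 >= 1L & UM[pmax(pre1, 1L)]) |
      (pre2 >= 1L & BM[pmax(pre2, 1L)] & !UM[pmax(pre2, 1L)])
    starts <- idx[!haspred]
    ## chain decomposition by memoized successor walk (successor of a
    ## unit start i is i+p on a perfect continuation, i+p+1 over a
    ## bridge); processing positions right-to-left makes this linear in
    ## the number of in-chain positions
    units_from <- integer(n)
    interr_from <- integer(n)
    last_unit <- integer(n)
    for (i in rev(idx)) {
      j <- if (UM[i]) i + p else i + p + 1L
      br <- !UM[i]
      if (inchain[j]) {
        units_from[i] <- units_from[j] + 1L
        interr_from[i] <- interr_from[j] + as.integer(br)
        last_unit[i] <- last_unit[j]
      } else {
        units_from[i] <- 2L
        interr_from[i] <- as.integer(br)
        last_unit[i] <- j
      }
    }
    thr <- .ssr_min_units[[as.character(p)]]
    starts <- starts[units_from[starts] >= thr]
    if (length(starts)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = starts - 1L, end = last_unit[starts] + p - 1L,
        period = p,
        raw_motif = vapply(starts, function(i) {
          paste(x[i:(i + p - 1L)], collapse = "")
        }, character(1)),
        n_units = units_from[starts],
        n_interruptions = interr_from[starts],
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  out <- .ssr_select(do.call(rbind, cand))
  if (nrow(out) == 0L) return(empty)
  out[, c("start", "end", "period", "motif", "n_units", "n_interruptions")]
}

#' Scan every scaffold of a genome for SSRs
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @return Data.frame as [scan_ssrs()] with a leading `scaffold` column.
#' @export
scan_ssrs_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- lapply(names(genome), function(sc) {
    res <- scan_ssrs(genome[[sc]])
    if (nrow(res) == 0L) return(NULL)
    cbind(data.frame(scaffold = sc, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(data.frame(scaffold = character(0)),
                 scan_ssrs("AAAA"))
  }
  rownames(out) <- NULL
  out
}
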