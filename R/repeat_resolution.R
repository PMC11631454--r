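## Resolution of overlapping repeat annotations.
##
## Two pairwise rules:
##   * partial overlap  - the overlap region is bisected at its midpoint,
##     each half going to the adjacent repeat (odd lengths: the extra base
##     goes to the earlier-starting repeat);
##   * full containment - the contained repeat's span is split 25/50/25,
##     the outer quarters (floor(L/4) each) going to the larger repeat and
##     the middle going to the contained repeat. Identical spans keep the
##     first annotation by input order and drop the duplicate.
## Chains of more than two mutually overlapping repeats are resolved by
## sorting on (start, -original length, input order) and applying the
## pairwise rules left-to-right against the running resolved set. "Larger"
## always refers to the original annotated length, not the post-split
## length, so the dominant annotation keeps its outer quarters even after
## losing bases elsewhere.

## Plain integer-interval set algebra on small 2-column matrices of
## disjoint 0-based half-open rows. Deliberately free of S4 dispatch:
## resolution visits every overlapping pair, and method dispatch costs
## dominate at realistic repeat densities.

.iv_empty <- matrix(numeric(0), ncol = 2L)

.iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(.iv_empty)
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L])
    e <- pmin(a[i, 2L], b[, 2L])
    k <- which(s < e)
    if (length(k)) out[[length(out) + 1L]] <- cbind(s[k], e[k])
  }
  if (!length(out)) return(.iv_empty)
  m <- do.call(rbind, out)
  m[order(m[, 1L]), , drop = FALSE]
}

.iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  res <- list()
  for (i in seq_len(nrow(a))) {
    segs <- a[i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      if (nrow(segs) == 0L) break
      nxt <- list()
      for (r in seq_len(nrow(segs))) {
        s <- segs[r, 1L]
        e <- segs[r, 2L]
        bs <- b[j, 1L]
        be <- b[j, 2L]
        if (be <= s || bs >= e) {
          nxt[[length(nxt) + 1L]] <- c(s, e)
          next
        }
        if (bs > s) nxt[[length(nxt) + 1L]] <- c(s, bs)
        if (be < e) nxt[[length(nxt) + 1L]] <- c(be, e)
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else .iv_empty
    }
    if (nrow(segs)) res[[length(res) + 1L]] <- segs
  }
  if (!length(res)) return(.iv_empty)
  m <- do.call(rbind, res)
  m[order(m[, 1L]), , drop = FALSE]
}

## merge touching rows (sorted input)
.iv_compact <- function(a) {
  if (nrow(a) <= 1L) return(a)
  out <- list(a[1L, ])
  for (i in seq(2L, nrow(a))) {
    last <- out[[length(out)]]
    if (a[i, 1L] <= last[2L]) {
      out[[length(out)]] <- c(last[1L], max(last[2L], a[i, 2L]))
    } else {
      out[[length(out) + 1L]] <- a[i, ]
    }
  }
  do.call(rbind, out)
}

## Region of [qs,qe) (earlier repeat Q, current owner) ceded to a
## newcomer [rs,re) under the pairwise rules, as 0-based half-open rows;
## the caller restricts the transfer to bases Q currently owns.
.transfer_region <- function(qs, qe, rs, re) {
  if (rs == qs && re == qe) return(.iv_empty)   # duplicate span: drop newcomer
  if (rs >= qs && re <= qe) {                   # newcomer contained, Q larger
    q4 <- (re - rs) %/% 4L
    if (re - q4 <= rs + q4) return(.iv_empty)
    return(matrix(c(rs + q4, re - q4), ncol = 2L))      # middle 50%
  }
  if (qs >= rs && qe <= re) {                   # Q contained, newcomer larger
    q4 <- (qe - qs) %/% 4L
    if (q4 == 0L) return(.iv_empty)
    return(matrix(c(qs, qe - q4, qs + q4, qe), ncol = 2L))
  }
  ov_s <- max(qs, rs)
  ov_e <- min(qe, re)
  mid <- ov_s + (ov_e - ov_s + 1L) %/% 2L       # extra base to the left repeat
  if (qs < rs) {
    if (mid >= ov_e) return(.iv_empty)
    matrix(c(mid, ov_e), ncol = 2L)
  } else {
    if (mid <= ov_s) return(.iv_empty)
    matrix(c(ov_s, mid), ncol = 2L)
  }
}

.resolve_scaffold <- function(df) {
  n <- nrow(df)
  orig_len <- df$end - df$start
  ord <- order(df$start, -orig_len, seq_len(n))
  owned <- rep(list(.iv_empty), n)
  done <- integer(0)
  for (k in ord) {
    remaining <- matrix(c(df$start[k], df$end[k]), ncol = 2L)
    for (j in done) {
      if (nrow(owned[[j]]) == 0L) next
      O <- .iv_intersect(owned[[j]], remaining)
      if (nrow(O) == 0L) next
      tr <- .transfer_region(df$start[j], df$end[j], df$start[k],
                             df$end[k])
      gain <- .iv_intersect(O, tr)
      keepQ <- .iv_setdiff(O, gain)
      owned[[j]] <- .iv_setdiff(owned[[j]], gain)
      remaining <- .iv_setdiff(remaining, keepQ)
    }
    owned[[k]] <- remaining
    done <- c(done, k)
  }
  out <- lapply(seq_len(n), function(k) {
    iv <- .iv_compact(owned[[k]])
    if (nrow(iv) == 0L) return(NULL)
    data.frame(scaffold = df$scaffold[k],
               start = as.integer(iv[, 1L]),
               end = as.integer(iv[, 2L]),
               strand = df$strand[k],
               repeat_id = df$repeat_id[k],
               class_label = df$class_label[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Resolve overlapping repeat annotations
#'
#' Splits overlapping repeat intervals so that the output is pairwise
#' disjoint while covering exactly the union of the input bases: partial
#' overlaps are split 50/50 at the overlap midpoint, full overlaps 25/50/25
#' with the outer quarters of the contained span attributed to the larger
#' repeat (which may therefore be emitted as several segments carrying the
#' same `repeat_id`).
#'
#' @param repeats Data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open), `repeat_id`, `class_label` and optionally
#'   `strand`.
#' @return Data.frame in the same layout, sorted by scaffold and start,
#'   with disjoint intervals.
#' @export
resolve_overlaps <- function(repeats) {
  req <- c("scaffold", "start", "end", "repeat_id", "class_label")
  if (!all(req %in% names(repeats))) {
    stop("repeats must have columns: ", paste(req, collapse = ", "))
  }
  if (!"strand" %in% names(repeats)) repeats$strand <- "."
  if (nrow(repeats) == 0L) return(repeats)
  if (any(repeats$end <= repeats$start)) {
    stop("repeat interval with non-positive length")
  }
  if (any(repeats$start < 0L)) stop("negative repeat coordinate")
  parts <- split(repeats, repeats$scaffold)
  out <- do.call(rbind, lapply(parts, .resolve_scaffold))
  out <- out[order(out$scaffold, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-scaffold repeat composition
#'
#' Fraction of scaffold bases covered by each repeat class. Input repeats
#' must already be overlap-resolved (disjoint); this is checked.
#'
#' @param repeats Overlap-resolved repeat data.frame (see
#'   [resolve_overlaps()]).
#' @param scaffold_lengths Named integer vector of scaffold lengths (bp).
#' @return Data.frame `scaffold`, `class_label`, `bases`, `fraction` with
#'   one row per scaffold x class present, plus zero rows omitted;
#'   fractions are bases / scaffold length.
#' @export
repeat_composition <- function(repeats, scaffold_lengths) {
  if (is.null(names(scaffold_lengths))) {
    stop("scaffold_lengths must be a named vector")
  }
  if (nrow(repeats) == 0L) {
    return(data.frame(scaffold = character(0), class_label = character(0),
                      bases = integer(0), fraction = numeric(0)))
  }
  unknown <- setdiff(unique(repeats$scaffold), names(scaffold_lengths))
  if (length(unknown)) {
    stop("repeat(s) on unknown scaffold(s): ",
         paste(unknown, collapse = ", "))
  }
  for (sc in unique(repeats$scaffold)) {
    r <- repeats[repeats$scaffold == sc, ]
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    if (sum(IRanges::width(IRanges::reduce(ir))) != sum(IRanges::width(ir))) {
      stop("repeats on scaffold ", sc,
           " overlap; run resolve_overlaps() first")
    }
    if (max(r$end) > scaffold_lengths[[sc]]) {
      stop("repeat extends past end of scaffold ", sc)
    }
  }
  agg <- stats::aggregate(
    bases ~ scaffold + class_label,
    data = data.frame(scaffold = repeats$scaffold,
                      class_label = repeats$class_label,
                      bases = repeats$end - repeats$start),
    FUN = sum)
  agg$fraction <- agg$bases / as.numeric(scaffold_lengths[agg$scaffold])
  agg <- agg[order(agg$scaffold, agg$class_label), ]
  rownames(agg) <- NULL
  agg
}

#' Convert repeat intervals to/from BED6
#'
#' Repeat identity and class are packed into the BED name field as
#' `repeat_id|class_label`.
#'
#' @param repeats Repeat data.frame.
#' @param bed BED6 data.frame as returned by [read_bed()].
#' @return `repeats_to_bed()`: a BED6 data.frame; `repeats_from_bed()`:
#'   a repeat data.frame.
#' @export
repeats_to_bed <- function(repeats) {
  data.frame(scaffold = repeats$scaffold, start = repeats$start,
             end = repeats$end,
             name = paste0(repeats$repeat_id, "|", repeats$class_label),
             score = 0L,
             strand = if ("strand" %in% names(repeats)) repeats$strand
                      else ".",
             stringsAsFactors = FALSE)
}

#' @rdname repeats_to_bed
#' @export
repeats_from_bed <- function(bed) {
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  data.frame(scaffold = bed$scaffold, start = bed$start, end = bed$end,
             strand = bed$strand,
             repeat_id = vapply(parts, `[`, character(1), 1L),
             class_label = vapply(parts, function(p) {
               if (length(p) >= 2L) p[[2L]] else NA_character_
             }, character(1)),
             stringsAsFactors = FALSE)
}
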