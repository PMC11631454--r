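## Independent brute-force oracles. These re-derive the published
## semantics with per-base / per-pair arithmetic, deliberately avoiding
## the interval algebra and vectorized chain decomposition used by the
## package, so that agreement is evidence and not tautology.

## ---- per-base painting oracle for repeat-overlap resolution ---------------

## does base b (0-based) transfer from current owner [qs,qe) to the
## newcomer [rs,re)?
.oracle_base_transfers <- function(qs, qe, rs, re, b) {
  if (rs == qs && re == qe) return(FALSE)        # duplicate annotation
  if (rs >= qs && re <= qe) {                    # newcomer contained
    L <- re - rs
    q4 <- L %/% 4
    return(b >= rs + q4 && b < re - q4)          # middle 50% to newcomer
  }
  if (qs >= rs && qe <= re) {                    # owner contained
    q4 <- (qe - qs) %/% 4
    return(b < qs + q4 || b >= qe - q4)          # outer quarters transfer
  }
  ov_s <- max(qs, rs)
  ov_e <- min(qe, re)
  mid <- ov_s + ceiling((ov_e - ov_s) / 2)       # extra base stays left
  if (qs < rs) b >= mid else b < mid
}

## paints every base by applying the pairwise rules in sorted order;
## returns the 1-based owner index per base (0 = unowned)
paint_overlaps_oracle <- function(repeats) {
  L <- max(repeats$end)
  owner <- integer(L)
  lens <- repeats$end - repeats$start
  ord <- order(repeats$start, -lens, seq_len(nrow(repeats)))
  for (i in ord) {
    for (b in seq(repeats$start[i], repeats$end[i] - 1L)) {
      j <- owner[b + 1L]
      if (j == 0L) {
        owner[b + 1L] <- i
      } else if (.oracle_base_transfers(repeats$start[j], repeats$end[j],
                                        repeats$start[i], repeats$end[i],
                                        b)) {
        owner[b + 1L] <- i
      }
    }
  }
  owner
}

## owner-per-base vector implied by a resolved (disjoint) repeat table,
## against the row order of the original input
owner_vector <- function(resolved, original, L) {
  owner <- integer(L)
  key <- paste(original$repeat_id, original$scaffold)
  for (r in seq_len(nrow(resolved))) {
    i <- match(paste(resolved$repeat_id[r], resolved$scaffold[r]), key)
    owner[(resolved$start[r] + 1L):resolved$end[r]] <- i
  }
  owner
}

## ---- exhaustive SSR oracle -------------------------------------------------

.oracle_min_units <- c(`2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

.oracle_canonical <- function(motif) {
  p <- nchar(motif)
  doubled <- paste0(motif, motif)
  min(vapply(seq_len(p), function(i) substr(doubled, i, i + p - 1L),
             character(1)))
}

.oracle_degenerate <- function(motif) {
  p <- nchar(motif)
  any(vapply(seq_len(p - 1L), function(d) {
    p %% d == 0L && strrep(substr(motif, 1L, d), p %/% d) == motif
  }, logical(1)))
}

## enumerates every (period, start) candidate with a plain greedy walk,
## prunes arrays contained in a longer array of the same period, then
## applies the published selection policy
scan_ssrs_oracle <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  ok <- strsplit(s, "")[[1L]] %in% c("A", "C", "G", "T")
  cand <- list()
  for (p in 2:6) {
    if (n < 2L * p) next
    idx <- seq_len(n - 2L * p + 1L)
    ## vectorized precheck: a reportable array (>= 3 units) must continue
    ## from its start by a unit or a bridged unit, so other starts can be
    ## skipped without changing the enumeration result
    mot <- substring(s, idx, idx + p - 1L)
    nxt <- substring(s, idx + p, idx + 2L * p - 1L)
    nxtb <- substring(s, idx + p + 1L, idx + 2L * p)
    for (i in idx[mot == nxt | mot == nxtb]) {
      if (!all(ok[i:(i + p - 1L)])) next
      motif <- substr(s, i, i + p - 1L)
      pos <- i
      units <- 1L
      interr <- 0L
      repeat {
        if (pos + 2L * p - 1L <= n &&
            substr(s, pos + p, pos + 2L * p - 1L) == motif) {
          pos <- pos + p
          units <- units + 1L
        } else if (pos + 2L * p <= n && ok[pos + p] &&
                   substr(s, pos + p + 1L, pos + 2L * p) == motif) {
          pos <- pos + p + 1L
          units <- units + 1L
          interr <- interr + 1L
        } else break
      }
      if (units >= .oracle_min_units[[as.character(p)]]) {
        cand[[length(cand) + 1L]] <-
          list(start = i - 1L, end = pos + p - 1L, period = p,
               motif = motif, n_units = units, n_interruptions = interr)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), motif = character(0),
                      n_units = integer(0), n_interruptions = integer(0)))
  }
  df <- do.call(rbind, lapply(cand, as.data.frame))
  ## drop arrays contained within another array of the same period
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$period == df$period[i] &
      df$start <= df$start[i] & df$end >= df$end[i] &
      !(df$start == df$start[i] & df$end == df$end[i])
    if (any(contained)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[!vapply(df$motif, .oracle_degenerate, logical(1)), ,
           drop = FALSE]
  ## selection: fewest interruptions, then smallest period, earliest
  ## start, most units; greedy non-overlap
  df <- df[order(df$n_interruptions, df$period, df$start, -df$n_units), ,
           drop = FALSE]
  sel <- logical(nrow(df))
  ks <- numeric(0)
  ke <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] < ke & df$end[i] > ks)) {
      sel[i] <- TRUE
      ks <- c(ks, df$start[i])
      ke <- c(ke, df$end[i])
    }
  }
  df <- df[sel, , drop = FALSE]
  df$motif <- vapply(df$motif, .oracle_canonical, character(1))
  df <- df[order(df$start, df$period), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("start", "end", "period", "motif", "n_units",
         "n_interruptions")]
}

## ---- O(n^2) clustering oracle ---------------------------------------------

## pairwise overlap test + breadth-first components; returns a list of
## sorted transcript-id vectors (one per locus), sorted by first member
cluster_oracle <- function(transcripts, mode = "exon", stranded = TRUE) {
  n <- nrow(transcripts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (transcripts$scaffold[i] != transcripts$scaffold[j]) next
      if (stranded && transcripts$strand[i] != transcripts$strand[j]) next
      ov <- FALSE
      if (mode == "exon") {
        ei <- transcripts$exons[[i]]
        ej <- transcripts$exons[[j]]
        for (a in seq_len(nrow(ei))) {
          for (b in seq_len(nrow(ej))) {
            if (ei$start[a] < ej$end[b] && ej$start[b] < ei$end[a]) {
              ov <- TRUE
            }
          }
        }
      } else {
        ov <- transcripts$start[i] < transcripts$end[j] &&
          transcripts$start[j] < transcripts$end[i]
      }
      adj[i, j] <- adj[j, i] <- ov
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  groups <- lapply(split(transcripts$transcript_id, comp), sort)
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

## ---- random-instance generators -------------------------------------------

random_repeats <- function(n, span = 600L, max_len = 120L) {
  start <- sample.int(span - 2L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(scaffold = "s", start = start,
             end = pmin(start + len, span),
             repeat_id = sprintf("r%03d", seq_len(n)),
             class_label = sample(c("DNA", "LTR", "LINE"), n,
                                  replace = TRUE),
             stringsAsFactors = FALSE)
}

## random sequence with planted (possibly interrupted) SSR arrays
random_ssr_sequence <- function(len = 2000L, n_plant = 3L) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  motifs <- c("AT", "AC", "ACG", "AAG", "AAGC", "AACCG", "AACGTG")
  for (k in seq_len(n_plant)) {
    m <- strsplit(sample(motifs, 1L), "")[[1L]]
    units1 <- sample(3:7, 1L)
    arr <- rep(m, units1)
    if (runif(1L) < 0.5) {               # interrupted array
      bridge <- sample(c("A", "C", "G", "T"), 1L)
      arr <- c(arr, bridge, rep(m, sample(2:4, 1L)))
    }
    at <- sample.int(len - length(arr), 1L)
    ch[at:(at + length(arr) - 1L)] <- arr
  }
  paste(ch, collapse = "")
}

random_transcripts <- function(n, scaffolds = c("s1", "s2"),
                               span = 50000L) {
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:4, 1L)
    start <- sample.int(span, 1L) - 1L
    ex_start <- start
    ex <- data.frame(start = integer(0), end = integer(0))
    for (e in seq_len(n_ex)) {
      w <- sample(50:400, 1L)
      ex <- rbind(ex, data.frame(start = ex_start, end = ex_start + w))
      ex_start <- ex_start + w + sample(50:500, 1L)
    }
    len <- sum(ex$end - ex$start)
    transcript_model(sprintf("t%03d", i), sample(scaffolds, 1L), ex,
                     strand = sample(c("+", "-"), 1L),
                     orf_has_start = runif(1L) < 0.7,
                     orf_has_stop = runif(1L) < 0.7,
                     orf_length = sample.int(len, 1L) %/% 3L * 3L)
  })
  do.call(rbind, rows)
}
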