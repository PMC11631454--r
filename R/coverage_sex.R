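## X-chromosome detection from sexed read-coverage tracks.
##
## Under an XY system a male carries one X against two autosomal copies,
## so the X scaffold sits near 0.5 normalized male coverage while the
## female stays near 1. Normalization divides each scaffold's mean depth
## by the sample's length-weighted genome-wide mean over retained
## scaffolds, which makes calls invariant to library size.

.scaffold_mean_depth <- function(depth, scaffold_lengths) {
  windowed <- isTRUE(attr(depth, "windowed")) ||
    all(c("start", "end", "mean_depth") %in% names(depth))
  unknown <- setdiff(unique(depth$scaffold), names(scaffold_lengths))
  if (length(unknown)) {
    stop("depth table scaffold(s) absent from lengths: ",
         paste(unknown, collapse = ", "))
  }
  ## positions/windows absent from the table count as depth 0 over the
  ## full scaffold length (zero-suppressed depth dumps)
  if (windowed) {
    tot <- tapply((depth$end - depth$start) * depth$mean_depth,
                  depth$scaffold, sum)
  } else {
    tot <- tapply(depth$depth, depth$scaffold, sum)
  }
  out <- setNames(numeric(length(scaffold_lengths)),
                  names(scaffold_lengths))
  out[names(tot)] <- as.numeric(tot) /
    as.numeric(scaffold_lengths[names(tot)])
  out
}

#' Normalized per-scaffold read coverage for a female/male sample pair
#'
#' Computes each scaffold's mean depth per sample, normalizes it by the
#' sample's length-weighted genome-wide mean over retained scaffolds
#' (those of at least `min_scaffold_len` bp), and reports the male/female
#' ratio of normalized depths.
#'
#' @param female,male Depth tables (see [read_depth_table()]); each must
#'   cover at least one position.
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param min_scaffold_len Scaffolds shorter than this are excluded from
#'   the genome-wide mean and from X calling (default 100 kb; small
#'   repeat-rich scaffolds distort the normalization).
#' @return Data.frame with one row per scaffold: `scaffold`, `length`,
#'   `retained`, `mean_depth_female`, `mean_depth_male`, `norm_female`,
#'   `norm_male`, `mf_ratio`. The length-weighted mean of normalized depth
#'   over retained scaffolds is 1 per sample.
#' @export
normalize_coverage <- function(female, male, scaffold_lengths,
                               min_scaffold_len = 1e5) {
  if (is.null(names(scaffold_lengths))) {
    stop("scaffold_lengths must be named")
  }
  for (d in list(female, male)) {
    if (is.null(d) || nrow(d) == 0L) stop("empty depth table")
  }
  lens <- as.numeric(scaffold_lengths)
  names(lens) <- names(scaffold_lengths)
  retained <- lens >= min_scaffold_len
  if (!any(retained)) {
    stop("no scaffold reaches min_scaffold_len = ", min_scaffold_len)
  }
  mf <- .scaffold_mean_depth(female, scaffold_lengths)
  mm <- .scaffold_mean_depth(male, scaffold_lengths)
  gw_f <- sum(mf[retained] * lens[retained]) / sum(lens[retained])
  gw_m <- sum(mm[retained] * lens[retained]) / sum(lens[retained])
  if (gw_f == 0 || gw_m == 0) stop("genome-wide mean depth is zero")
  out <- data.frame(
    scaffold = names(lens), length = lens, retained = retained,
    mean_depth_female = as.numeric(mf), mean_depth_male = as.numeric(mm),
    norm_female = as.numeric(mf) / gw_f,
    norm_male = as.numeric(mm) / gw_m,
    stringsAsFactors = FALSE
  )
  out$mf_ratio <- ifelse(out$norm_female > 0,
                         out$norm_male / out$norm_female, NA_real_)
  rownames(out) <- NULL
  out
}

#' Flag X-chromosome candidate scaffolds
#'
#' A retained scaffold is flagged when its male/female normalized-coverage
#' ratio is at most `ratio_max` and its female normalized depth lies in
#' `female_norm_range` (the female check guards against scaffolds whose
#' low male coverage merely reflects poor coverage overall).
#'
#' @param summaries Output of [normalize_coverage()].
#' @param ratio_max Maximum male/female normalized ratio to flag
#'   (default 0.75, the midpoint between the expected X ratio 0.5 and the
#'   autosomal 1).
#' @param female_norm_range Admissible female normalized-depth interval
#'   (default `c(0.8, 1.25)`).
#' @return Character vector of flagged scaffold ids, sorted by ascending
#'   male/female ratio.
#' @export
call_x_candidates <- function(summaries, ratio_max = 0.75,
                              female_norm_range = c(0.8, 1.25)) {
  need <- c("scaffold", "retained", "norm_female", "mf_ratio")
  if (!all(need %in% names(summaries))) {
    stop("summaries must come from normalize_coverage()")
  }
  s <- summaries[summaries$retained & !is.na(summaries$mf_ratio), ,
                 drop = FALSE]
  hit <- s$mf_ratio <= ratio_max &
    s$norm_female >= female_norm_range[1L] &
    s$norm_female <= female_norm_range[2L]
  s <- s[hit, , drop = FALSE]
  s$scaffold[order(s$mf_ratio)]
}
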