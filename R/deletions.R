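#' Filter mtDNA deletion calls by heteroplasmy cutoff
#'
#' Retains calls with heteroplasmy strictly greater than the cutoff
#' (default > 5\%, matching the common reporting threshold; 1\% and other
#' cutoffs are configurable).
#'
#' @param calls data.frame with columns `bp5`, `bp3`, `heteroplasmy`
#'   (fraction in `[0, 1]`), `kind` (`"deletion"`/`"duplication"`), and a
#'   sample/timepoint column.
#' @param cutoff heteroplasmy fraction.
#' @return the retained rows.
#' @export
filter_calls <- function(calls, cutoff = 0.05) {
  h <- calls$heteroplasmy
  if (any(!is.finite(h)) || any(h < 0 | h > 1)) {
    stop("heteroplasmy must be a fraction in [0, 1]")
  }
  calls[h > cutoff, , drop = FALSE]
}

#' Deletion length on the circular mitochondrial genome
#'
#' When the 3' breakpoint precedes the 5' breakpoint the deletion wraps the
#' origin: length = (genome_length - bp5) + bp3.
#'
#' @param bp5,bp3 1-based breakpoint coordinates.
#' @param genome_length mtDNA length (default 16569, human rCRS).
#' @return deleted length in bp (vectorized).
#' @export
deletion_length <- function(bp5, bp3, genome_length = 16569) {
  if (any(bp5 < 1 | bp5 > genome_length | bp3 < 1 | bp3 > genome_length)) {
    stop("breakpoints must lie in [1, genome_length]")
  }
  ifelse(bp3 >= bp5, bp3 - bp5, (genome_length - bp5) + bp3)
}

#' Summarize deletion calls per timepoint and across the lifespan
#'
#' Unique deletions are distinct (bp5, bp3) breakpoint pairs within a
#' timepoint after heteroplasmy filtering. The lifespan total burden is the
#' sum of per-timepoint unique counts. Duplications are counted separately
#' and never added to deletion counts.
#'
#' @param calls data.frame with columns `timepoint_day`, `bp5`, `bp3`,
#'   `heteroplasmy`, `kind`.
#' @param cutoff heteroplasmy cutoff (strictly greater than).
#' @param genome_length mtDNA length in bp.
#' @return list with `per_timepoint` (day, n_deletions, n_duplications,
#'   mean/median length in kb, mean heteroplasmy), `total_burden`,
#'   `mean_heteroplasmy`, `cutoff`.
#' @export
summarize_deletions <- function(calls, cutoff = 0.05,
                                genome_length = 16569) {
  if (length(unique(calls$timepoint_day)) < 1) {
    stop("need at least one timepoint")
  }
  kept <- filter_calls(calls, cutoff)
  days <- sort(unique(calls$timepoint_day))
  per_tp <- lapply(days, function(d) {
    k <- kept[kept$timepoint_day == d, , drop = FALSE]
    del <- unique(k[k$kind == "deletion", c("bp5", "bp3")])
    dup <- unique(k[k$kind == "duplication", c("bp5", "bp3")])
    len_kb <- if (nrow(del) > 0) {
      deletion_length(del$bp5, del$bp3, genome_length) / 1000
    } else {
      numeric(0)
    }
    het <- k$heteroplasmy[k$kind == "deletion"]
    data.frame(
      timepoint_day = d,
      n_deletions = nrow(del),
      n_duplications = nrow(dup),
      mean_length_kb = if (length(len_kb) > 0) mean(len_kb) else NA_real_,
      median_length_kb = if (length(len_kb) > 0) stats::median(len_kb)
                         else NA_real_,
      mean_heteroplasmy = if (length(het) > 0) mean(het) else NA_real_
    )
  })
  per_tp <- do.call(rbind, per_tp)
  het_all <- kept$heteroplasmy[kept$kind == "deletion"]
  list(per_timepoint = per_tp,
       total_burden = sum(per_tp$n_deletions),
       mean_heteroplasmy = if (length(het_all) > 0) mean(het_all)
                           else NA_real_,
       cutoff = cutoff)
}
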