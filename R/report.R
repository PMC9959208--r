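## Summary statistics: category percentages, abundance shares and family
## size tables. All percentages are rounded half-up to 2 decimals.

#' Category tally with percentages
#'
#' @param n_toxin,n_cellular,n_nonmatched EST counts per category
#' @return list of class `category_tally` with the counts and percentages
#'   (`pct_toxin`, `pct_cellular`, `pct_nonmatched`), half-up, 2 decimals
#' @examples
#' category_percentages(554, 357, 177)  # 50.92 / 32.81 / 16.27
#' @export
category_percentages <- function(n_toxin, n_cellular, n_nonmatched) {
  stopifnot(n_toxin >= 0, n_cellular >= 0, n_nonmatched >= 0)
  total <- n_toxin + n_cellular + n_nonmatched
  if (total == 0) stop("empty tally: total is zero")
  structure(list(n_toxin = n_toxin, n_cellular = n_cellular,
                 n_nonmatched = n_nonmatched, total = total,
                 pct_toxin = round_half_up(100 * n_toxin / total),
                 pct_cellular = round_half_up(100 * n_cellular / total),
                 pct_nonmatched = round_half_up(100 * n_nonmatched / total)),
            class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  cat(sprintf("%d ESTs: %d toxin-like (%.2f%%), %d cellular (%.2f%%), %d non-matched (%.2f%%)\n",
              x$total, x$n_toxin, x$pct_toxin, x$n_cellular, x$pct_cellular,
              x$n_nonmatched, x$pct_nonmatched))
  invisible(x)
}

#' Abundance share of a transcript group within its category
#'
#' @param group_size EST count of the group
#' @param category_size EST count of the whole category
#' @return percentage, half-up, 2 decimals
#' @examples
#' abundance_share(356, 554)  # 64.26
#' @export
abundance_share <- function(group_size, category_size) {
  if (category_size == 0) stop("empty category")
  stopifnot(group_size >= 0, group_size <= category_size)
  round_half_up(100 * group_size / category_size)
}

#' Family size table
#'
#' @param families character vector of family letters (one per toxin)
#' @return data.frame `family`, `n` over A-K (plus any other labels seen),
#'   with attribute `total`
#' @export
family_size_table <- function(families) {
  lev <- union(LETTERS[1:11], setdiff(unique(families), NA))
  tab <- table(factor(families, levels = lev))
  out <- data.frame(family = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(out$n)
  out
}
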