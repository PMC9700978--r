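# ABC Dementia Scale (ABC-DS) instrument model.
#
# 13 caregiver-rated items, each scored 1-9 (higher = milder dementia).
# Canonical item-to-subscale assignment used throughout the package:
# items 1-6 ADL, items 7-9 BPSD, items 10-13 cognitive function. The
# instrument defines subscale sizes (6/3/4) but the analysis only ever
# uses subscale sums, so the ordering is a package convention.

#' ABC-DS item-to-subscale assignment
#'
#' Canonical assignment of the 13 ABC-DS items to the three subscales:
#' items 1--6 activities of daily living (ADL), items 7--9 behavioral and
#' psychological symptoms of dementia (BPSD), items 10--13 cognitive
#' function.
#'
#' @return Named list of integer item indices (`adl`, `bpsd`, `cog`).
#' @export
abcds_subscales <- function() {
  list(adl = 1:6, bpsd = 7:9, cog = 10:13)
}

#' Score one ABC-DS assessment occasion
#'
#' Sums the 13 item scores into the three subscale totals and the grand
#' total. Each item is scored 1--9, so the ADL total lies in \[6, 54\],
#' the BPSD total in \[3, 27\], the cognitive total in \[4, 36\] and the
#' grand total in \[13, 117\]. Higher scores indicate milder dementia.
#'
#' @param item_scores Integer vector of length 13, each element in 1..9.
#' @return Named numeric vector `c(adl, bpsd, cog, total)`.
#' @examples
#' score_record(rep(9, 13))  # maximal record, total 117
#' @export
score_record <- function(item_scores) {
  if (length(item_scores) != 13L) {
    stop("expected 13 item scores, got ", length(item_scores), call. = FALSE)
  }
  bad <- which(!is.finite(item_scores) |
                 item_scores != round(item_scores) |
                 item_scores < 1 | item_scores > 9)
  if (length(bad)) {
    stop("item ", bad[1L], " is not an integer in [1, 9]: ",
         item_scores[bad[1L]], call. = FALSE)
  }
  sub <- abcds_subscales()
  adl <- sum(item_scores[sub$adl])
  bpsd <- sum(item_scores[sub$bpsd])
  cog <- sum(item_scores[sub$cog])
  c(adl = adl, bpsd = bpsd, cog = cog, total = adl + bpsd + cog)
}

#' Construct a validated ABC-DS record
#'
#' One assessment occasion: the raw item scores plus derived subscale and
#' grand totals. An optional rater label is carried but not used by any
#' analysis (no rater-reliability adjustment is attempted).
#'
#' @param item_scores Integer vector of length 13, each in 1..9.
#' @param rater Optional character scalar identifying the rater.
#' @return Object of class `abcds_record`.
#' @export
abcds_record <- function(item_scores, rater = NULL) {
  totals <- score_record(item_scores)
  structure(
    list(items = as.integer(item_scores), scores = totals, rater = rater),
    class = "abcds_record"
  )
}

#' @export
print.abcds_record <- function(x, ...) {
  cat("ABC-DS record: total", x$scores[["total"]],
      sprintf("(ADL %d, BPSD %d, cognitive %d)\n",
              x$scores[["adl"]], x$scores[["bpsd"]], x$scores[["cog"]]))
  invisible(x)
}
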