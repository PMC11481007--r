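#' Active/decoy screening counts
#'
#' The four counts a retrospective pharmacophore validation run produces:
#' database size `D`, total actives `A`, total hits `Ht` and active hits
#' `Ha`.
#'
#' @param D database size.
#' @param A number of known actives in the database.
#' @param Ht total hits returned by the screen.
#' @param Ha actives among the hits.
#' @return object of class `screen_counts`.
#' @export
screen_counts <- function(D, A, Ht, Ha) {
  if (A > D || Ht > D) stop("A and Ht cannot exceed D")
  if (Ha > min(A, Ht)) stop("Ha cannot exceed min(A, Ht)")
  if (min(D, A, Ht, Ha) < 0) stop("counts must be nonnegative")
  structure(list(D = D, A = A, Ht = Ht, Ha = Ha), class = "screen_counts")
}

#' Count-based screen validation statistics
#'
#' Percentage yield of actives (precision of the hit list), percentage
#' ratio of actives (recall), enrichment factor and the Guener-Henry
#' goodness-of-hit composite:
#' \deqn{GH = \frac{Ha (3A + Ht)}{4 Ht A}
#'   \left(1 - \frac{Ht - Ha}{D - A}\right)}
#'
#' @param c a [screen_counts()].
#' @return numeric scalar.
#' @export
yield_of_actives <- function(c) {
  if (c$Ht < 1) stop("yield of actives undefined for Ht = 0")
  100 * c$Ha / c$Ht
}

#' @rdname yield_of_actives
#' @export
ratio_of_actives <- function(c) {
  if (c$A < 1) stop("ratio of actives undefined for A = 0")
  100 * c$Ha / c$A
}

#' @rdname yield_of_actives
#' @export
enrichment_factor <- function(c) {
  if (c$Ht < 1 || c$A < 1) stop("enrichment factor undefined for zero counts")
  (c$Ha / c$Ht) / (c$A / c$D)
}

#' @rdname yield_of_actives
#' @export
goodness_of_hit <- function(c) {
  if (c$Ht < 1 || c$A < 1) stop("GH undefined for zero counts")
  if (c$D <= c$A) stop("GH undefined when D = A (no decoys)")
  (c$Ha * (3 * c$A + c$Ht) / (4 * c$Ht * c$A)) *
    (1 - (c$Ht - c$Ha) / (c$D - c$A))
}

#' Summarize screening counts as a validation report
#'
#' @param c a [screen_counts()].
#' @return `screen_stats` list: `yield_pct`, `ratio_pct`, `EF`, `FP`,
#'   `FN`, `GH` (all at full precision; printing rounds half-to-even to
#'   two decimals).
#' @export
summarize_screen <- function(c) {
  structure(list(
    D = c$D, A = c$A, Ht = c$Ht, Ha = c$Ha,
    yield_pct = yield_of_actives(c),
    ratio_pct = ratio_of_actives(c),
    EF = enrichment_factor(c),
    FP = c$Ht - c$Ha,
    FN = c$A - c$Ha,
    GH = goodness_of_hit(c)), class = "screen_stats")
}

#' @export
print.screen_stats <- function(x, ...) {
  fmt <- function(v) formatC(round(v, 2), format = "f", digits = 2)
  cat("Screen validation statistics\n")
  cat(sprintf("  Database size (D)        %6d\n", x$D))
  cat(sprintf("  Total actives (A)        %6d\n", x$A))
  cat(sprintf("  Total hits (Ht)          %6d\n", x$Ht))
  cat(sprintf("  Active hits (Ha)         %6d\n", x$Ha))
  cat(sprintf("  %% yield of actives       %6s\n", fmt(x$yield_pct)))
  cat(sprintf("  %% ratio of actives       %6s\n", fmt(x$ratio_pct)))
  cat(sprintf("  Enrichment factor (EF)   %6s\n", fmt(x$EF)))
  cat(sprintf("  False positives          %6d\n", x$FP))
  cat(sprintf("  False negatives          %6d\n", x$FN))
  cat(sprintf("  Goodness of hit (GH)     %6s\n", fmt(x$GH)))
  invisible(x)
}

#' Screening counts from per-molecule labels
#'
#' @param is_active logical vector over the database.
#' @param is_hit logical vector over the database.
#' @return a [screen_counts()].
#' @export
counts_from_labels <- function(is_active, is_hit) {
  stopifnot(length(is_active) == length(is_hit))
  screen_counts(D = length(is_active), A = sum(is_active),
                Ht = sum(is_hit), Ha = sum(is_active & is_hit))
}
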