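#' Molecular fingerprints
#'
#' Two 2D fingerprint schemes are supported: `maccs` (166 structural keys)
#' and `morgan` (radius-2 circular fingerprint folded to 2048 bits). Both
#' are computed with Open Babel's fingerprint machinery; the circular
#' scheme is Open Babel's ECFP4 (radius 2) OR-folded from 4096 to 2048
#' bits.
#'
#' @param x a [molecule()], a SMILES string, or a list of either.
#' @param scheme `"maccs"` or `"morgan"`.
#' @return a `fingerprint` object (single input) or list thereof, each a
#'   list with `scheme`, `bits` (logical vector) and `popcount`.
#' @export
fingerprint <- function(x, scheme = c("maccs", "morgan")) {
  scheme <- match.arg(scheme)
  single <- inherits(x, "molecule") ||
    (is.character(x) && length(x) == 1L)
  xs <- if (single) list(x) else x
  sdfs <- lapply(xs, function(m) {
    if (inherits(m, "molecule")) molecule_to_sdf(m)
    else molecule_to_sdf(molecules_from_smiles(m)[[1]])
  })
  ids <- vapply(seq_along(xs), function(i) {
    if (inherits(xs[[i]], "molecule")) xs[[i]]$id else paste0("q", i)
  }, character(1))
  sdfset <- methods::new("SDFset", SDF = sdfs, ID = ids)
  obname <- c(maccs = "MACCS", morgan = "ECFP4")[[scheme]]
  fpset <- ChemmineR::fingerprintOB(sdfset, obname)
  mat <- methods::slot(fpset, "fpma")
  fps <- lapply(seq_len(nrow(mat)), function(i) {
    bits <- as.logical(mat[i, ])
    if (scheme == "maccs") {
      bits <- bits[1:166]
    } else {
      half <- length(bits) / 2L
      bits <- bits[seq_len(half)] | bits[half + seq_len(half)]
    }
    structure(list(scheme = scheme, bits = bits, popcount = sum(bits)),
              class = "fingerprint")
  })
  names(fps) <- ids
  if (single) fps[[1]] else fps
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$scheme, "-", length(x$bits), "bits,",
      x$popcount, "set\n")
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `c / (a + b - c)` over set-bit counts, with the empty/empty case
#' defined as 0.
#'
#' @param fp1,fp2 [fingerprint()] objects of the same scheme.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp1, fp2) {
  if (fp1$scheme != fp2$scheme)
    stop("cannot compare fingerprints of different schemes (",
         fp1$scheme, " vs ", fp2$scheme, ")")
  a <- fp1$popcount
  b <- fp2$popcount
  cc <- sum(fp1$bits & fp2$bits)
  denom <- a + b - cc
  if (denom == 0) return(0)
  cc / denom
}

#' Maximum similarity of a query against a reference set
#'
#' @param query a [fingerprint()].
#' @param references non-empty list of fingerprints (same scheme), ideally
#'   named by reference id.
#' @return list with `value` (max Tanimoto) and `id` (best reference; ties
#'   broken lexicographically).
#' @export
max_similarity <- function(query, references) {
  if (length(references) == 0L)
    stop("reference set must be non-empty")
  ids <- names(references)
  if (is.null(ids)) ids <- paste0("ref", seq_along(references))
  vals <- vapply(references, tanimoto, numeric(1), fp1 = query)
  best <- max(vals)
  cand <- sort(ids[vals >= best - 1e-12])
  list(value = best, id = cand[1])
}

#' Novelty flag against known actives
#'
#' A compound counts as known-like when its maximum fingerprint similarity
#' to any reported reference reaches the threshold (inclusive); a maximum
#' similarity of 0.85 or more to a known active implies a substantial
#' chance of shared activity, so only compounds below it are flagged
#' novel.
#'
#' @param values numeric similarity values in \[0, 1\] (can be empty).
#' @param threshold inclusive known-like threshold (default 0.85).
#' @return `"novel"` or `"known-like"`.
#' @export
novelty_flag <- function(values, threshold = 0.85) {
  if (any(values < 0 | values > 1)) stop("similarities must lie in [0, 1]")
  if (length(values) == 0L) return("novel")
  if (max(values) >= threshold) "known-like" else "novel"
}

#' Similarity report of candidates against a reference set
#'
#' MACCS and Morgan Tanimoto values side by side; the novelty flag uses
#' the maximum of the two schemes.
#'
#' @param candidates list of [molecule()]s (or SMILES).
#' @param references list of [molecule()]s (or SMILES) of known actives.
#' @param threshold novelty threshold (default 0.85).
#' @return data.frame (id, tanimoto_maccs, tanimoto_morgan,
#'   nearest_reference, flag).
#' @export
similarity_report <- function(candidates, references, threshold = 0.85) {
  out <- list()
  fps_c_m <- fingerprint(candidates, "maccs")
  fps_c_g <- fingerprint(candidates, "morgan")
  fps_r_m <- fingerprint(references, "maccs")
  fps_r_g <- fingerprint(references, "morgan")
  for (i in seq_along(candidates)) {
    mm <- max_similarity(fps_c_m[[i]], fps_r_m)
    gg <- max_similarity(fps_c_g[[i]], fps_r_g)
    out[[i]] <- data.frame(
      id = names(fps_c_m)[i],
      tanimoto_maccs = mm$value, tanimoto_morgan = gg$value,
      nearest_reference = if (mm$value >= gg$value) mm$id else gg$id,
      flag = novelty_flag(c(mm$value, gg$value), threshold))
  }
  do.call(rbind, out)
}
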